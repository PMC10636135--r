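#' @include active-site.R structio.R
NULL

#' Grid-based pocket (cavity) detection
#'
#' LIGSITE-style buriedness scan: a cubic grid is laid over the structure,
#' grid cells within `probe` of any heavy atom are marked occupied, and
#' each empty cell is scanned along 7 lines (3 axes + 4 cube diagonals) out
#' to `scanRange`; a cell enclosed by protein on both sides of at least
#' `minBuried` lines is a pocket cell. Connected pocket cells (26-
#' neighbourhood) are clustered, clusters below `minCells` are discarded,
#' and clusters are ranked by cell count (the volume proxy). Member
#' positions are the residues with any atom within `lining` of a pocket
#' cell, capped at `maxPositions` nearest the pocket centroid.
#'
#' @param x A [ProteinStructure-class].
#' @param nPockets Number of pockets to return (default 3, fewer with a
#'   warning if fewer exist).
#' @param spacing Grid spacing, angstrom (default 1.0).
#' @param probe Occupancy radius around heavy atoms (default 2.0).
#' @param scanRange Enclosure scan range, angstrom (default 8).
#' @param minBuried Minimum enclosed lines of 7 (default 5).
#' @param minCells Minimum cluster size in cells (default 5).
#' @param lining Residue lining distance from pocket cells (default 4.5).
#' @param maxPositions Cap on member positions per pocket (default 100).
#' @return List of pockets, each a list with `pocketId`, `memberPositions`
#'   (a `data.frame` with `chain`, `resno`, `insert`, `aa`), `centroid`,
#'   `volumeProxy` (angstrom^3) and `nCells`. Ranked by `volumeProxy`
#'   descending; deterministic given the structure.
#' @export
detectPockets <- function(x, nPockets = 3, spacing = 1.0, probe = 2.0,
                          scanRange = 8, minBuried = 5, minCells = 5,
                          lining = 4.5, maxPositions = 100) {
  stopifnot(is(x, "ProteinStructure"), nResidues(x) >= 1L)
  a <- x@atoms[x@atoms$element != "H", , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  lo <- apply(xyz, 2L, min) - 2 * spacing
  hi <- apply(xyz, 2L, max) + 2 * spacing
  nd <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  # occupancy: mark cells within probe of any atom
  occ <- array(FALSE, dim = nd)
  rad <- as.integer(ceiling(probe / spacing))
  off <- expand.grid(dx = -rad:rad, dy = -rad:rad, dz = -rad:rad)
  off <- off[sqrt(off$dx^2 + off$dy^2 + off$dz^2) * spacing <= probe, ]
  idx0 <- sweep(xyz, 2L, lo)
  idx0 <- round(idx0 / spacing) + 1L
  for (k in seq_len(nrow(off))) {
    ii <- cbind(idx0[, 1L] + off$dx[k], idx0[, 2L] + off$dy[k],
                idx0[, 3L] + off$dz[k])
    ok <- ii[, 1L] >= 1L & ii[, 1L] <= nd[1L] &
          ii[, 2L] >= 1L & ii[, 2L] <= nd[2L] &
          ii[, 3L] >= 1L & ii[, 3L] <= nd[3L]
    occ[ii[ok, , drop = FALSE]] <- TRUE
  }
  # buriedness scan along 7 lines
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  steps <- as.integer(ceiling(scanRange / spacing))
  empty <- which(!occ, arr.ind = TRUE)
  if (nrow(empty) == 0L) return(list())
  buried <- integer(nrow(empty))
  for (d in seq_len(nrow(dirs))) {
    hitPos <- rep(FALSE, nrow(empty))
    hitNeg <- rep(FALSE, nrow(empty))
    for (s in seq_len(steps)) {
      for (sgn in c(1L, -1L)) {
        ii <- empty + sgn * s * matrix(dirs[d, ], nrow(empty), 3L, byrow = TRUE)
        ok <- ii[, 1L] >= 1L & ii[, 1L] <= nd[1L] &
              ii[, 2L] >= 1L & ii[, 2L] <= nd[2L] &
              ii[, 3L] >= 1L & ii[, 3L] <= nd[3L]
        hit <- rep(FALSE, nrow(empty))
        hit[ok] <- occ[ii[ok, , drop = FALSE]]
        if (sgn > 0L) hitPos <- hitPos | hit else hitNeg <- hitNeg | hit
      }
    }
    buried <- buried + as.integer(hitPos & hitNeg)
  }
  pocketCells <- empty[buried >= minBuried, , drop = FALSE]
  if (nrow(pocketCells) == 0L) {
    if (nPockets > 0L) warning("no cavities detected")
    return(list())
  }
  # cluster by 26-connectivity via integer cell keys
  key <- function(m) (m[, 1L] - 1L) + nd[1L] * ((m[, 2L] - 1L) +
                     nd[2L] * (m[, 3L] - 1L))
  cellKeys <- key(pocketCells)
  lookup <- new.env(hash = TRUE)
  for (i in seq_along(cellKeys)) assign(as.character(cellKeys[i]), i,
                                        envir = lookup)
  cluster <- integer(length(cellKeys))
  cid <- 0L
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0L, ]
  for (i in seq_along(cellKeys)) {
    if (cluster[i] != 0L) next
    cid <- cid + 1L
    stack <- i
    cluster[i] <- cid
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      nbr <- sweep(nb, 2L, as.integer(pocketCells[cur, ]), `+`)
      nks <- key(nbr)
      for (k in nks) {
        j <- lookup[[as.character(k)]]
        if (!is.null(j) && cluster[j] == 0L) {
          cluster[j] <- cid
          stack <- c(stack, j)
        }
      }
    }
  }
  sizes <- tabulate(cluster)
  keep <- which(sizes >= minCells)
  if (!length(keep)) {
    if (nPockets > 0L) warning("no cavities of at least ", minCells, " cells")
    return(list())
  }
  ordc <- keep[order(sizes[keep], decreasing = TRUE)]
  if (length(ordc) < nPockets)
    warning("only ", length(ordc), " pocket(s) found, ", nPockets,
            " requested")
  rt <- residueTable(x)
  akey <- .residueKey(x@atoms)
  pockets <- list()
  for (p in seq_len(min(nPockets, length(ordc)))) {
    cells <- pocketCells[cluster == ordc[p], , drop = FALSE]
    cc <- sweep((cells - 1L) * spacing, 2L, lo, `+`)
    centroid <- colMeans(cc)
    # residues lining the pocket: any atom within `lining` of a pocket cell
    dmin <- rep(Inf, nrow(xyz))
    for (i in seq_len(nrow(cc)))
      dmin <- pmin(dmin, sqrt(rowSums(sweep(xyz, 2L, cc[i, ])^2)))
    akeyH <- akey[x@atoms$element != "H"]
    resMin <- tapply(dmin, factor(akeyH, levels = unique(akey)), min)
    members <- rt[!is.na(resMin) & resMin <= lining, , drop = FALSE]
    mdist <- resMin[!is.na(resMin) & resMin <= lining]
    if (nrow(members) > maxPositions) {
      ordm <- order(mdist)
      members <- members[ordm[seq_len(maxPositions)], , drop = FALSE]
    }
    pockets[[p]] <- list(
      pocketId = paste0("pocket", p),
      memberPositions = members[, c("chain", "resno", "insert", "aa")],
      centroid = centroid,
      volumeProxy = nrow(cells) * spacing^3,
      nCells = nrow(cells))
  }
  pockets
}

#' Default matcher configuration
#'
#' @param penaltyCutoff Maximum total penalty for reporting a match.
#' @param spinSteps Orientation-grid starts for the TS pose (spins about
#'   the attack axis).
#' @param beam Number of best stage-1 poses refined jointly.
#' @param maxitCoarse,maxitFine Nelder-Mead iteration caps.
#' @param nRandomStarts Additional seeded random restarts (default 0; the
#'   deterministic spin grid is usually sufficient).
#' @param seed Seed for the random restarts.
#' @param anchorAa Named list of allowed native amino acids per role
#'   (one-letter codes); defaults follow identical-type anchoring for
#'   Ser/His, Asp-or-Glu for the acid, Ser/Thr for the carboxylate binder,
#'   and any non-proline backbone for the oxyanion donors.
#' @return A list of matcher settings.
#' @export
matchConfig <- function(penaltyCutoff = 5.0, spinSteps = 8, beam = 2,
                        maxitCoarse = 120, maxitFine = 300,
                        nRandomStarts = 0, seed = 1,
                        anchorAa = list(nucleophile_ser = "S",
                                        base_his = "H",
                                        acid_asp_glu = c("D", "E"),
                                        carboxylate_binder_ser = c("S", "T"))) {
  list(penaltyCutoff = penaltyCutoff, spinSteps = spinSteps, beam = beam,
       maxitCoarse = maxitCoarse, maxitFine = maxitFine,
       nRandomStarts = nRandomStarts, seed = seed, anchorAa = anchorAa)
}

# rotation matrix from a rotation vector (axis * angle, radians)
.rotvec <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3L], -k[2L], -k[3L], 0, k[1L], k[2L], -k[1L], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# compile a fast penalty evaluator for fixed role coordinates; constraints
# whose role has no coordinates are skipped (used for staged optimization)
.compilePenalty <- function(model, roleCoords, tsNames) {
  cons <- list()
  for (con in model@constraints) {
    atomSources <- list()
    ok <- TRUE
    for (at in con$atoms) {
      ref <- at[[1L]]
      nm <- at[[2L]]
      cand <- .atomCandidates(model, ref, nm)
      if (ref == "TS") {
        idx <- match(intersect(cand, tsNames), tsNames)
        if (!length(idx)) { ok <- FALSE; break }
        atomSources[[length(atomSources) + 1L]] <- list(ts = idx)
      } else {
        coords <- roleCoords[[ref]]
        if (is.null(coords)) { ok <- FALSE; break }
        have <- intersect(cand, rownames(coords))
        if (!length(have)) { ok <- FALSE; break }
        atomSources[[length(atomSources) + 1L]] <-
          list(fixed = coords[have, , drop = FALSE])
      }
    }
    if (!ok) next
    combos <- as.matrix(expand.grid(lapply(atomSources, function(s)
      seq_len(if (!is.null(s$ts)) length(s$ts) else nrow(s$fixed)))))
    cons[[length(cons) + 1L]] <- list(kind = con$kind, lo = con$lo,
                                      hi = con$hi, w = con$weight,
                                      src = atomSources, combos = combos)
  }
  function(ts) {
    total <- 0
    for (con in cons) {
      best <- Inf
      for (k in seq_len(nrow(con$combos))) {
        pts <- matrix(0, length(con$src), 3L)
        for (j in seq_along(con$src)) {
          s <- con$src[[j]]
          i <- con$combos[k, j]
          pts[j, ] <- if (!is.null(s$ts)) ts[s$ts[i], ] else s$fixed[i, ]
        }
        val <- switch(con$kind,
          distance = .vdist(pts[1L, ], pts[2L, ]),
          angle    = .vangle(pts[1L, ], pts[2L, ], pts[3L, ]),
          dihedral = .vdihedral(pts[1L, ], pts[2L, ], pts[3L, ], pts[4L, ]))
        exc <- .windowExcess(val, con$lo, con$hi, con$kind)
        pen <- con$w * exc * exc
        if (pen < best) best <- pen
      }
      total <- total + best
    }
    total
  }
}

# anchor-atom coordinates for a role at a given residue; NULL if atoms absent
.roleAnchors <- function(x, model, roleId, chain, resno, insert, aa) {
  role <- NULL
  for (r in model@roles) if (r$roleId == roleId) role <- r
  amap <- role$anchorAtoms[[aa]]
  if (is.null(amap)) amap <- role$anchorAtoms[["*"]]
  if (is.null(amap)) return(NULL)
  wanted <- unique(unlist(amap))
  rc <- .residueCoords(x, chain, resno, insert)
  have <- intersect(wanted, rownames(rc))
  if (!length(have)) return(NULL)
  rc[have, , drop = FALSE]
}

# rotation aligning unit vector a onto unit vector b
.alignRotation <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- .vcross(a, b)
  c_ <- sum(a * b)
  if (sum(v^2) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate 180 deg about any perpendicular axis
    p <- .vcross(a, c(1, 0, 0))
    if (sum(p^2) < 1e-6) p <- .vcross(a, c(0, 1, 0))
    return(.rotvec(pi * p / sqrt(sum(p^2))))
  }
  K <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3) + K + K %*% K * (1 / (1 + c_))
}

#' Place the active-site model against one catalytic triad
#'
#' The single-triad placement routine shared by [matchActiveSite()] and by
#' exhaustive-enumeration oracles: anchors the transition state against the
#' given Ser/His/Asp positions (native side-chain conformations), optimizes
#' the TS pose (orientation-grid starts + local Nelder-Mead refinement of
#' the 6 rigid-body degrees of freedom), selects the two oxyanion backbone-
#' NH donors and the carboxylate-binding hydroxyl greedily from the allowed
#' candidates, and alternates selection/pose refinement to convergence.
#' Fully deterministic for `nRandomStarts = 0` (the default).
#'
#' @param x A [ProteinStructure-class].
#' @param model An [ActiveSiteModel-class].
#' @param triad Named list/vector of residue keys for `nucleophile_ser`,
#'   `base_his`, `acid_asp_glu`, each `c(chain, resno, insert)` or a row
#'   index into [residueTable()].
#' @param config A [matchConfig()] list.
#' @param candidates Optional [residueTable()]-like `data.frame`
#'   restricting donor/binder candidates (default: all residues).
#' @return A [MatchResult-class], or `NULL` when the triad is infeasible
#'   (missing anchor atoms, no donor/binder candidates, or final penalty
#'   above `config$penaltyCutoff`).
#' @export
placeActiveSite <- function(x, model, triad, config = matchConfig(),
                            candidates = NULL) {
  rt <- residueTable(x)
  getRes <- function(spec) {
    if (is.numeric(spec)) rt[spec, ] else
      rt[rt$chain == spec[[1L]] & rt$resno == as.integer(spec[[2L]]) &
         rt$insert == (if (length(spec) > 2L) spec[[3L]] else ""), ]
  }
  roles3 <- c("nucleophile_ser", "base_his", "acid_asp_glu")
  resdf <- do.call(rbind, lapply(roles3, function(r) getRes(triad[[r]])))
  if (nrow(resdf) != 3L || anyNA(resdf$resno)) return(NULL)
  roleCoords <- list()
  for (i in seq_along(roles3)) {
    rc <- .roleAnchors(x, model, roles3[i], resdf$chain[i], resdf$resno[i],
                       resdf$insert[i], resdf$aa[i])
    if (is.null(rc)) return(NULL)
    roleCoords[[roles3[i]]] <- rc
  }
  tsRef <- tsPose(model@ts)
  tsNames <- rownames(tsRef)
  c1 <- tsRef[model@ts@tetrahedralCenter, ]
  tsCtr <- sweep(tsRef, 2L, c1)
  og <- roleCoords$nucleophile_ser["OG", ]
  cb <- if ("CB" %in% rownames(roleCoords$nucleophile_ser))
    roleCoords$nucleophile_ser["CB", ] else og + c(1, 0, 0)

  # fixed (TS-independent) terms must already be affordable
  evalTriad <- .compilePenalty(model, roleCoords, tsNames)
  poseAt <- function(p) {
    R <- .rotvec(p[4:6])
    sweep(tsCtr %*% t(R), 2L, p[1:3], `+`)
  }
  obj <- function(p, evalFn) evalFn(poseAt(p))
  # initial C1 position: continue the CB->OG direction by the attack-distance
  # target; initial orientations: align the nucleophile-side O of the TS back
  # toward OG, then spin about that axis
  u <- og - cb
  u <- u / sqrt(sum(u^2))
  dAtt <- 2.3
  for (con in model@constraints)
    if (con$id == "attack_distance") dAtt <- con$target
  c1pos <- og + dAtt * u
  vONU <- if ("ONU" %in% tsNames) tsCtr["ONU", ] else -u
  R0 <- .alignRotation(vONU / sqrt(sum(vONU^2)), -u)
  w0 <- .rotationToVec(R0)
  spins <- seq(0, 2 * pi, length.out = config$spinSteps + 1L)[-(config$spinSteps + 1L)]
  starts <- lapply(spins, function(s) {
    Rs <- .rotvec(-u * s) %*% R0
    c(c1pos, .rotationToVec(Rs))
  })
  if (config$nRandomStarts > 0L) {
    rs <- local({
      set.seed(config$seed)
      lapply(seq_len(config$nRandomStarts), function(i)
        c(c1pos + stats::rnorm(3L, 0, 0.5), stats::rnorm(3L, 0, 1.5)))
    })
    starts <- c(starts, rs)
  }
  coarse <- lapply(starts, function(p0)
    stats::optim(p0, obj, evalFn = evalTriad, method = "Nelder-Mead",
                 control = list(maxit = config$maxitCoarse,
                                reltol = 1e-10)))
  ordc <- order(vapply(coarse, `[[`, numeric(1), "value"))
  best <- coarse[ordc[seq_len(min(config$beam, length(coarse)))]]

  # donor/binder candidates
  cand <- if (is.null(candidates)) rt else candidates
  usedKey <- paste(resdf$chain, resdf$resno, resdf$insert)
  candKey <- paste(cand$chain, cand$resno, cand$insert)
  donorPool <- cand[cand$aa != "P" & cand$hasBackbone &
                    !(candKey %in% usedKey), , drop = FALSE]
  binderAa <- config$anchorAa$carboxylate_binder_ser
  binderPool <- cand[cand$aa %in% binderAa & !(candKey %in% usedKey), ,
                     drop = FALSE]
  if (nrow(donorPool) < 2L || nrow(binderPool) < 1L) return(NULL)
  donorN <- t(vapply(seq_len(nrow(donorPool)), function(i) {
    rc <- .residueCoords(x, donorPool$chain[i], donorPool$resno[i],
                         donorPool$insert[i])
    if ("N" %in% rownames(rc)) rc["N", ] else c(NA_real_, NA_real_, NA_real_)
  }, numeric(3)))
  okN <- stats::complete.cases(donorN)
  donorPool <- donorPool[okN, , drop = FALSE]
  donorN <- donorN[okN, , drop = FALSE]
  if (nrow(donorPool) < 2L) return(NULL)

  oxyWin <- c(2.0, 4.0, 1.0)
  cbxWin <- c(2.0, 4.0, 1.0)
  for (con in model@constraints) {
    if (con$id == "oxyanion_hbond_1") oxyWin <- c(con$lo, con$hi, con$weight)
    if (con$id == "carboxylate_hbond") cbxWin <- c(con$lo, con$hi, con$weight)
  }
  selectPartners <- function(ts) {
    oxy <- ts["OXY", ]
    dN <- sqrt(rowSums(sweep(donorN, 2L, oxy)^2))
    costN <- oxyWin[3L] * vapply(dN, .windowExcess, numeric(1),
                                 lo = oxyWin[1L], hi = oxyWin[2L],
                                 kind = "distance")^2
    ordN <- order(costN, donorPool$chain, donorPool$resno, donorPool$insert)
    d12 <- ordN[1:2]
    ocNames <- .atomCandidates(model, "TS", "OC")
    ocNames <- intersect(ocNames, rownames(ts))
    costB <- vapply(seq_len(nrow(binderPool)), function(i) {
      rc <- .roleAnchors(x, model, "carboxylate_binder_ser",
                         binderPool$chain[i], binderPool$resno[i],
                         binderPool$insert[i], binderPool$aa[i])
      if (is.null(rc)) return(Inf)
      dmin <- min(apply(rc, 1L, function(p)
        min(vapply(ocNames, function(n) .vdist(p, ts[n, ]), numeric(1)))))
      cbxWin[3L] * .windowExcess(dmin, cbxWin[1L], cbxWin[2L], "distance")^2
    }, numeric(1))
    ordB <- order(costB, binderPool$chain, binderPool$resno, binderPool$insert)
    list(donors = d12, binder = ordB[1L])
  }

  refine <- function(p0) {
    sel <- selectPartners(poseAt(p0))
    for (iter in 1:3) {
      rc <- roleCoords
      for (k in 1:2) {
        i <- sel$donors[k]
        rc[[paste0("oxyanion_nh_", k)]] <-
          matrix(donorN[i, ], 1L, 3L, dimnames = list("N", NULL))
      }
      bi <- sel$binder
      rc$carboxylate_binder_ser <- .roleAnchors(
        x, model, "carboxylate_binder_ser", binderPool$chain[bi],
        binderPool$resno[bi], binderPool$insert[bi], binderPool$aa[bi])
      evalFull <- .compilePenalty(model, rc, tsNames)
      fit <- stats::optim(p0, obj, evalFn = evalFull, method = "Nelder-Mead",
                          control = list(maxit = config$maxitFine,
                                         reltol = 1e-12))
      p0 <- fit$par
      sel2 <- selectPartners(poseAt(p0))
      if (identical(sel2, sel)) return(list(par = p0, value = fit$value,
                                            sel = sel, roleCoords = rc))
      sel <- sel2
    }
    list(par = p0, value = fit$value, sel = sel, roleCoords = rc)
  }
  fits <- lapply(best, function(b) refine(b$par))
  fi <- which.min(vapply(fits, `[[`, numeric(1), "value"))
  fit <- fits[[fi]]
  if (fit$value > config$penaltyCutoff) return(NULL)

  tsFinal <- poseAt(fit$par)
  geometry <- fit$roleCoords
  geometry$TS <- tsFinal
  pen <- constraintPenalty(model, geometry)
  assignment <- data.frame(
    role = c(roles3, "oxyanion_nh_1", "oxyanion_nh_2",
             "carboxylate_binder_ser"),
    chain = c(resdf$chain, donorPool$chain[fit$sel$donors],
              binderPool$chain[fit$sel$binder]),
    resno = c(resdf$resno, donorPool$resno[fit$sel$donors],
              binderPool$resno[fit$sel$binder]),
    insert = c(resdf$insert, donorPool$insert[fit$sel$donors],
               binderPool$insert[fit$sel$binder]),
    aa = c(resdf$aa, donorPool$aa[fit$sel$donors],
           binderPool$aa[fit$sel$binder]),
    stringsAsFactors = FALSE)
  res <- new("MatchResult", scaffoldId = x@id, assignment = assignment,
             placedAtoms = fit$roleCoords, pose = tsFinal,
             penalty = as.numeric(pen),
             breakdown = attr(pen, "breakdown"), triadRmsd = NA_real_)
  tryCatch({ validObject(res); res }, error = function(e) NULL)
}

.rotationToVec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-9) return(c(0, 0, 0))
  ax <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L], R[2L, 1L] - R[1L, 2L])
  nax <- sqrt(sum(ax^2))
  if (nax < 1e-9) {
    # th ~ pi: extract axis from diagonal
    ax <- sqrt(pmax(0, (diag(R) + 1) / 2))
    ax <- ax * sign(c(1, R[1L, 2L], R[1L, 3L]) + 1e-12)
    return(th * ax / sqrt(sum(ax^2)))
  }
  th * ax / nax
}

#' Match an active-site model into a scaffold
#'
#' Enumerates catalytic-triad assignments (nucleophile at native Ser, base
#' at native His, acid at native Asp/Glu -- identical-type anchoring),
#' prunes triads whose fixed side-chain geometry alone already exceeds the
#' penalty cutoff, runs the shared placement routine [placeActiveSite()]
#' on the survivors, and returns all matches with final penalty below the
#' cutoff, ranked by [rankMatches()]. Each returned penalty is reproducible
#' via [constraintPenalty()] on the match's placed geometry.
#'
#' @param x A [ProteinStructure-class].
#' @param model An [ActiveSiteModel-class].
#' @param config A [matchConfig()] list.
#' @param pockets Optional output of [detectPockets()]; when supplied, all
#'   roles are restricted to pocket member positions.
#' @return List of [MatchResult-class] objects (possibly empty), ranked.
#' @export
matchActiveSite <- function(x, model, config = matchConfig(),
                            pockets = NULL) {
  rt <- residueTable(x)
  cand <- rt
  if (!is.null(pockets) && length(pockets)) {
    keys <- unique(unlist(lapply(pockets, function(p)
      paste(p$memberPositions$chain, p$memberPositions$resno,
            p$memberPositions$insert))))
    cand <- rt[paste(rt$chain, rt$resno, rt$insert) %in% keys, , drop = FALSE]
  }
  serPos <- which(cand$aa %in% config$anchorAa$nucleophile_ser)
  hisPos <- which(cand$aa %in% config$anchorAa$base_his)
  aspPos <- which(cand$aa %in% config$anchorAa$acid_asp_glu)
  if (!length(serPos) || !length(hisPos) || !length(aspPos)) return(list())

  anchorOf <- function(roleId, i) {
    .roleAnchors(x, model, roleId, cand$chain[i], cand$resno[i],
                 cand$insert[i], cand$aa[i])
  }
  hsWin <- adWin <- NULL
  for (con in model@constraints) {
    if (con$id == "his_ser_hbond") hsWin <- con
    if (con$id == "asp_his_hbond") adWin <- con
  }
  matches <- list()
  for (is_ in serPos) {
    ogc <- anchorOf("nucleophile_ser", is_)
    if (is.null(ogc) || !"OG" %in% rownames(ogc)) next
    for (ih in hisPos) {
      hc <- anchorOf("base_his", ih)
      if (is.null(hc) || !all(c("NE2", "ND1") %in% rownames(hc))) next
      if (!is.null(hsWin)) {
        exc <- .windowExcess(.vdist(ogc["OG", ], hc["NE2", ]),
                             hsWin$lo, hsWin$hi, "distance")
        if (hsWin$weight * exc^2 > config$penaltyCutoff) next
      }
      for (ia in aspPos) {
        ac <- anchorOf("acid_asp_glu", ia)
        if (is.null(ac)) next
        if (!is.null(adWin)) {
          dmin <- min(apply(ac, 1L, function(p) .vdist(p, hc["ND1", ])))
          exc <- .windowExcess(dmin, adWin$lo, adWin$hi, "distance")
          if (adWin$weight * exc^2 > config$penaltyCutoff) next
        }
        m <- placeActiveSite(
          x, model,
          triad = list(nucleophile_ser = cand$index0[is_] + 1L,
                       base_his = cand$index0[ih] + 1L,
                       acid_asp_glu = cand$index0[ia] + 1L),
          config = config, candidates = cand)
        if (!is.null(m)) matches[[length(matches) + 1L]] <- m
      }
    }
  }
  rankMatches(matches)
}

#' Rank matches by penalty with deterministic tie-breaking
#'
#' Ascending by penalty; ties broken by triad compactness (sum of pairwise
#' CA distances of the three triad residues, smaller first) and finally by
#' the lexicographic (chain, resno) of the assignment -- so the ranking is
#' invariant under permutation of the input list.
#'
#' @param matches List of [MatchResult-class] objects.
#' @return The same matches, ordered.
#' @export
rankMatches <- function(matches) {
  if (length(matches) <= 1L) return(matches)
  keyOf <- function(m) {
    a <- m@assignment
    paste(sprintf("%s%06d%s", a$chain, a$resno, a$insert), collapse = "|")
  }
  compact <- vapply(matches, function(m) {
    if (is.null(m@placedAtoms$triadCA)) 0 else m@placedAtoms$triadCA
  }, numeric(1))
  ord <- order(vapply(matches, penaltyScore, numeric(1)), compact,
               vapply(matches, keyOf, character(1)))
  matches[ord]
}

#' RMSD of placed catalytic side chains versus the native conformation
#'
#' Computed over the declared anchor atoms of the triad roles, in the same
#' frame (no re-superposition): placed rotamer coordinates against the
#' crystal/native coordinates at the matched positions.
#'
#' @param match A [MatchResult-class].
#' @param x The scaffold [ProteinStructure-class].
#' @return RMSD in angstroms.
#' @export
triadRmsdVsNative <- function(match, x) {
  roles3 <- c("nucleophile_ser", "base_his", "acid_asp_glu")
  placed <- native <- NULL
  missing <- character(0)
  a <- match@assignment
  for (r in roles3) {
    row <- a[a$role == r, ]
    pm <- match@placedAtoms[[r]]
    if (is.null(pm)) stop("match carries no placed atoms for role ", r)
    nat <- .residueCoords(x, row$chain, row$resno, row$insert)
    miss <- setdiff(rownames(pm), rownames(nat))
    if (length(miss)) {
      missing <- c(missing, paste0(row$chain, row$resno, ":", miss))
      next
    }
    placed <- rbind(placed, pm)
    native <- rbind(native, nat[rownames(pm), , drop = FALSE])
  }
  if (length(missing))
    stop("native atoms missing: ", paste(missing, collapse = ", "))
  as.numeric(kabschRmsd(native, placed, superpose = FALSE))
}
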