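#' @include matcher.R
NULL

.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.10, P = 1.80)

.vdwRadius <- function(element) {
  r <- .VDW_RADII[toupper(substr(element, 1L, 1L))]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Default placing rules for TS conformer generation
#'
#' Three rules mirror the screening used when building a transition-state
#' rotamer library inside a matched active site: (i) `clash` -- no TS heavy
#' atom may sit closer to a scaffold heavy atom than `clashFactor` times
#' the sum of their van der Waals radii (catalytic-triad side chains and
#' the scaffold atoms of matched positions are exempt, since the TS is
#' intentionally close to them); (ii) `penalty` -- the catalytic constraint
#' penalty of the pose must not exceed `penaltyCutoff`; (iii)
#' `oxyanion_partner` -- the pose's oxyanion O must have a backbone-N
#' hydrogen-bond partner within the model's oxyanion window.
#'
#' @param model An [ActiveSiteModel-class].
#' @param match The [MatchResult-class] the library is generated in.
#' @param x The scaffold [ProteinStructure-class].
#' @param penaltyCutoff Maximum constraint penalty (default 1.0).
#' @param clashFactor Fraction of summed vdW radii counting as clash
#'   (default 0.8).
#' @return List of placing rules; each has `id`, `description` and a
#'   predicate `fn(pose)` returning `TRUE` when the pose passes.
#' @export
defaultPlacingRules <- function(model, match, x, penaltyCutoff = 1.0,
                                clashFactor = 0.8) {
  a <- x@atoms[x@atoms$element != "H", , drop = FALSE]
  matched <- paste(match@assignment$chain, match@assignment$resno,
                   match@assignment$insert)
  akey <- paste(a$chain, a$resno, a$insert)
  scaff <- a[!(akey %in% matched), , drop = FALSE]
  scaffXyz <- as.matrix(scaff[, c("x", "y", "z")])
  scaffRad <- .vdwRadius(scaff$element)
  evalPen <- .compilePenalty(model, match@placedAtoms,
                             model@ts@atoms$name)
  tsRad <- .vdwRadius(model@ts@atoms$element)
  tsHeavy <- model@ts@atoms$element != "H"
  oxyWin <- c(2.0, 4.0)
  for (con in model@constraints)
    if (con$id == "oxyanion_hbond_1") oxyWin <- c(con$lo, con$hi)
  donorsN <- match@placedAtoms[c("oxyanion_nh_1", "oxyanion_nh_2")]
  list(
    list(id = "clash",
         description = sprintf(
           "no TS heavy atom within %.2f x (vdW_i + vdW_j) of a scaffold heavy atom",
           clashFactor),
         fn = function(pose) {
           if (nrow(scaffXyz) == 0L) return(TRUE)
           for (i in which(tsHeavy)) {
             d2 <- rowSums(sweep(scaffXyz, 2L, pose[i, ])^2)
             lim <- (clashFactor * (tsRad[i] + scaffRad))^2
             if (any(d2 < lim)) return(FALSE)
           }
           TRUE
         }),
    list(id = "penalty",
         description = sprintf("constraint penalty <= %.3g", penaltyCutoff),
         fn = function(pose) evalPen(pose) <= penaltyCutoff),
    list(id = "oxyanion_partner",
         description = sprintf(
           "a matched backbone N within [%.1f, %.1f] A of the oxyanion O",
           oxyWin[1L], oxyWin[2L]),
         fn = function(pose) {
           oxy <- pose["OXY", ]
           for (dn in donorsN) {
             if (is.null(dn) || !"N" %in% rownames(dn)) next
             d <- .vdist(dn["N", ], oxy)
             if (d >= oxyWin[1L] && d <= oxyWin[2L]) return(TRUE)
           }
           FALSE
         })
  )
}

# atoms downstream of bond b-c (on the d side), for torsion rotation
.torsionMovers <- function(ts, torsion) {
  nm <- ts@atoms$name
  adj <- lapply(nm, function(n) character(0))
  names(adj) <- nm
  for (k in seq_len(nrow(ts@bonds))) {
    i <- ts@bonds[k, 1L]; j <- ts@bonds[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  b <- torsion[2L]; cc <- torsion[3L]
  seen <- cc
  stack <- setdiff(adj[[cc]], b)
  while (length(stack)) {
    n <- stack[[1L]]; stack <- stack[-1L]
    if (n %in% seen) next
    seen <- c(seen, n)
    stack <- c(stack, setdiff(adj[[n]], seen))
  }
  setdiff(seen, cc)
}

.applyTorsion <- function(pose, torsion, movers, deltaDeg) {
  b <- pose[torsion[2L], ]; cc <- pose[torsion[3L], ]
  axis <- cc - b
  axis <- axis / sqrt(sum(axis^2))
  R <- .rotvec(axis * deltaDeg * pi / 180)
  pose[movers, ] <- sweep(sweep(pose[movers, , drop = FALSE], 2L, cc) %*% t(R),
                          2L, cc, `+`)
  pose
}

#' Generate a transition-state conformer library in a matched site
#'
#' Enumerates a torsion grid (times optional seeded rigid-body jitter)
#' around the constraint-anchored TS pose of a match, screens every pose
#' against the placing rules, and de-duplicates survivors by heavy-atom
#' RMSD. De-duplication is canonical and order-independent: survivors are
#' sorted by (penalty, torsion vector lexicographic) and kept greedily at
#' `dedupeTol` separation, so a shuffled enumeration yields the identical
#' library.
#'
#' @param x Scaffold [ProteinStructure-class].
#' @param match A [MatchResult-class] providing the anchored pose.
#' @param model The [ActiveSiteModel-class].
#' @param params List: `torsionIds` (indices into the model TS's rotatable
#'   torsions, default 1:2), `steps` (grid steps per torsion, default 12),
#'   `nJitter` (rigid-body perturbations per grid point incl. the
#'   unperturbed one, default 1), `jitterT`/`jitterR` (SDs: angstrom,
#'   radians).
#' @param rules Placing rules, default [defaultPlacingRules()].
#' @param seed Integer seed for the jitter (unused when `nJitter = 1`).
#' @param dedupeTol Heavy-atom RMSD threshold for de-duplication
#'   (default 0.3 angstrom).
#' @return A [TSConformerLibrary-class]. `provenance` records
#'   `nGenerated`, `nSurvivors` (before de-dup) and the parameters;
#'   `diagnostics` counts rejections per rule (a pose failing several
#'   rules counts once per rule).
#' @export
generateTSLibrary <- function(x, match, model,
                              params = list(), rules = NULL, seed = 1,
                              dedupeTol = 0.3) {
  p <- utils::modifyList(list(torsionIds = 1:2, steps = 12, nJitter = 1,
                              jitterT = 0.15, jitterR = 0.1), params)
  if (is.null(rules)) rules <- defaultPlacingRules(model, match, x)
  base <- match@pose
  torsions <- model@ts@torsions[p$torsionIds]
  movers <- lapply(torsions, .torsionMovers, ts = model@ts)
  grid <- do.call(expand.grid,
                  rep(list(seq(0, 360, length.out = p$steps + 1L)[seq_len(p$steps)]),
                      length(torsions)))
  set.seed(seed)
  jitters <- lapply(seq_len(p$nJitter), function(i) {
    if (i == 1L) list(t = c(0, 0, 0), r = c(0, 0, 0))
    else list(t = stats::rnorm(3L, 0, p$jitterT),
              r = stats::rnorm(3L, 0, p$jitterR))
  })
  evalPen <- .compilePenalty(model, match@placedAtoms, rownames(base))
  heavy <- model@ts@atoms$element != "H"
  poses <- list(); tvecs <- list(); pens <- numeric(0)
  reject <- stats::setNames(integer(length(rules)),
                            vapply(rules, `[[`, character(1), "id"))
  nGen <- 0L
  ctr <- colMeans(base)
  for (g in seq_len(nrow(grid))) {
    poseG <- base
    for (ti in seq_along(torsions))
      poseG <- .applyTorsion(poseG, torsions[[ti]], movers[[ti]],
                             grid[g, ti])
    for (jit in jitters) {
      nGen <- nGen + 1L
      R <- .rotvec(jit$r)
      pose <- sweep(sweep(poseG, 2L, ctr) %*% t(R), 2L, ctr + jit$t, `+`)
      ok <- TRUE
      for (ri in seq_along(rules)) {
        if (!rules[[ri]]$fn(pose)) {
          reject[ri] <- reject[ri] + 1L
          ok <- FALSE
        }
      }
      if (ok) {
        poses[[length(poses) + 1L]] <- pose
        tvecs[[length(tvecs) + 1L]] <- as.numeric(grid[g, ])
        pens <- c(pens, evalPen(pose))
      }
    }
  }
  nSurv <- length(poses)
  if (nSurv == 0L) {
    worst <- names(reject)[which.max(reject)]
    message("no TS conformers survived; most rejections by rule '",
            worst, "' (", max(reject), " of ", nGen, " poses)")
    return(new("TSConformerLibrary", conformers = list(),
               torsions = matrix(numeric(0), 0L, length(torsions)),
               penalty = numeric(0), clash = numeric(0),
               provenance = list(seed = seed, params = p, nGenerated = nGen,
                                 nSurvivors = 0L),
               diagnostics = reject))
  }
  # canonical order: penalty, then torsion vector lexicographic
  tmat <- do.call(rbind, tvecs)
  ord <- do.call(order, c(list(round(pens, 9)),
                          lapply(seq_len(ncol(tmat)), function(j) tmat[, j])))
  kept <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (k in kept) {
      r <- kabschRmsd(poses[[k]][heavy, , drop = FALSE],
                      poses[[i]][heavy, , drop = FALSE], superpose = FALSE)
      if (r < dedupeTol) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, i)
  }
  new("TSConformerLibrary",
      conformers = poses[kept],
      torsions = tmat[kept, , drop = FALSE],
      penalty = pens[kept],
      clash = rep(0, length(kept)),
      provenance = list(seed = seed, params = p, nGenerated = nGen,
                        nSurvivors = nSurv, nAfterDedupe = length(kept)),
      diagnostics = reject)
}
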