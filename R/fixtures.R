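#' @include matcher.R md-screen.R sidechain.R
NULL

# unit vector
.unit <- function(v) v / sqrt(sum(v^2))

# a vector perpendicular to v (deterministic)
.perp <- function(v) {
  p <- .vcross(v, c(1, 0, 0))
  if (sum(p^2) < 1e-8) p <- .vcross(v, c(0, 1, 0))
  .unit(p)
}

# imidazole ring coordinates (CG, ND1, CE1, NE2, CD2) as a regular pentagon
# placed so NE2 lands at `ne2` with the ring plane normal `normal` and ND1
# on the far side from `toward`
.imidazoleAt <- function(ne2, normal, toward) {
  bond <- 1.37
  R <- bond / (2 * sin(pi / 5))
  e1 <- .unit(toward - ne2 - sum((toward - ne2) * normal) * normal)
  e2 <- .vcross(normal, e1)
  # pentagon in local coords, NE2 at angle 0 pointing along +e1 is wrong --
  # we want ND1 (2 vertices away) on the -e1 side
  ang <- seq(0, by = 2 * pi / 5, length.out = 5)
  names(ang) <- c("NE2", "CE1", "ND1", "CG", "CD2")
  ctr <- ne2 - R * e1              # ring center opposite `toward`
  out <- t(vapply(names(ang), function(nm)
    ctr + R * (cos(ang[[nm]]) * e1 + sin(ang[[nm]]) * e2), numeric(3)))
  rownames(out) <- names(ang)
  out[c("CG", "ND1", "CE1", "NE2", "CD2"), , drop = FALSE]
}

.mkAtoms <- function(resno, resid, coords, chain = "A") {
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = rownames(coords),
             element = substr(rownames(coords), 1L, 1L),
             x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
             stringsAsFactors = FALSE)
}

#' Synthetic toy scaffold with a planted active site
#'
#' Builds a small single-chain structure containing a Ser-His-Asp triad,
#' two backbone-NH oxyanion donors (Ala) and a carboxylate-binding Ser,
#' all placed exactly at the geometric targets of the active-site model
#' (or displaced beyond a tolerance edge via `offsets`), plus seeded decoy
#' residues scattered in a 12-25 angstrom shell. The planted-truth record
#' names the planted positions, carries the planted geometry and the
#' expected constraint penalty, so the generator serves as an end-to-end
#' oracle for matching and penalty scoring.
#'
#' @param seed Integer seed (fixes decoy placement).
#' @param nDecoys Number of decoy residues (default 15).
#' @param extraCatalytic Named counts of additional decoy Ser/His/Asp
#'   residues, e.g. `c(S = 1, H = 1, D = 1)`, to enlarge the triad
#'   enumeration space (default none).
#' @param offsets Named numeric: for a supported distance constraint
#'   (`attack_distance`, `his_ser_hbond`, `asp_his_hbond`,
#'   `oxyanion_hbond_1`, `oxyanion_hbond_2`, `carboxylate_hbond`), the
#'   planted geometry is displaced so the measured value sits that far
#'   beyond the upper tolerance; the expected penalty rises by
#'   `weight * offset^2`.
#' @param model The [ActiveSiteModel-class] (default: shipped config).
#' @return List: `structure` (a [ProteinStructure-class]) and `truth`
#'   (list with `positions`, `geometry`, `expectedPenalty`).
#' @export
makeToyScaffold <- function(seed = 1, nDecoys = 15,
                            extraCatalytic = c(S = 0, H = 0, D = 0),
                            offsets = numeric(0),
                            model = loadActiveSiteConfig()) {
  set.seed(seed)
  tgt <- list()
  for (con in model@constraints)
    tgt[[con$id]] <- c(target = con$target, lo = con$lo, hi = con$hi,
                       w = con$weight)
  off <- function(id) {
    if (id %in% names(offsets)) tgt[[id]][["hi"]] + offsets[[id]]
    else tgt[[id]][["target"]]
  }
  ts <- tsPose(model@ts)
  c1 <- ts["C1", ]; oxy <- ts["OXY", ]; onu <- ts["ONU", ]
  w <- .unit(onu - c1)
  og <- c1 + off("attack_distance") * w
  cb <- og + 1.417 * w
  # tilt the CA direction off the CB-OG axis (real side chains are bent)
  wTilt <- .unit(w + 0.7 * .perp(w))
  serBB <- idealBackbone(cb + 1.53 * wTilt, direction = wTilt, up = .perp(w))
  # base His: NE2 at the his_ser target from OG, at the target angle to C1
  axis <- .perp(w)
  dirNE2 <- as.numeric(.rotvec(axis * tgt$his_ser_attack_angle[["target"]] *
                               pi / 180) %*% (-w))
  ne2 <- og + off("his_ser_hbond") * dirNE2
  ring <- .imidazoleAt(ne2, normal = .unit(.vcross(dirNE2, axis)),
                       toward = og)
  nd1 <- ring["ND1", ]
  hisCB <- ring["CG", ] + 1.50 * .unit(ring["CG", ] - ne2)
  hisBB <- idealBackbone(hisCB + 1.53 * .unit(hisCB - ring["CG", ]),
                         direction = .unit(hisCB - ring["CG", ]))
  # acid Asp: OD1 at the asp_his target from ND1, pointing away from the ring
  dirOD <- .unit(nd1 - ring["CE1", ])
  od1 <- nd1 + off("asp_his_hbond") * dirOD
  aspCG <- od1 + 1.25 * dirOD
  od2 <- aspCG + 1.25 * .unit(dirOD + .perp(dirOD))
  aspCB <- aspCG + 1.52 * .unit(dirOD - .perp(dirOD) * 0.8)
  aspBB <- idealBackbone(aspCB + 1.53 * .unit(aspCB - aspCG),
                         direction = .unit(aspCB - aspCG))
  # oxyanion donors: backbone N at target distance from OXY, at the
  # approach-angle target off the OXY->C1 axis, two different azimuths
  vCO <- .unit(c1 - oxy)
  aAng <- tgt$oxyanion_approach_angle[["target"]]
  p1 <- .perp(vCO)
  p2 <- .unit(.vcross(vCO, p1))
  donorN <- function(azimuthDeg, dist) {
    az <- azimuthDeg * pi / 180
    axisA <- cos(az) * p1 + sin(az) * p2
    d <- as.numeric(.rotvec(axisA * aAng * pi / 180) %*% vCO)
    oxy + dist * d
  }
  n1 <- donorN(0, off("oxyanion_hbond_1"))
  n2 <- donorN(130, off("oxyanion_hbond_2"))
  mkAla <- function(npos) {
    dirAway <- .unit(npos - oxy)
    ca <- npos + 1.458 * dirAway
    bb <- rbind(N = npos, CA = ca, C = ca + 1.525 * .unit(dirAway + .perp(dirAway)),
                O = ca + 1.525 * .unit(dirAway + .perp(dirAway)) +
                  1.231 * .perp(dirAway))
    cbA <- ca + 1.53 * .unit(dirAway - 0.5 * .perp(dirAway))
    rbind(bb, CB = cbA)
  }
  ala1 <- mkAla(n1)
  ala2 <- mkAla(n2)
  # carboxylate binder Ser: OG at target from O3, away from the carboxylate
  o3 <- ts["O3", ]
  dirB <- .unit(o3 - ts["C7", ])
  ogB <- o3 + off("carboxylate_hbond") * dirB
  cbB <- ogB + 1.417 * dirB
  dirBT <- .unit(dirB + 0.7 * .perp(dirB))
  binderBB <- idealBackbone(cbB + 1.53 * dirBT, direction = dirBT)

  res <- list(
    list(resid = "SER", coords = rbind(serBB, CB = cb, OG = og)),
    list(resid = "HIS", coords = rbind(hisBB, CB = hisCB, ring)),
    list(resid = "ASP", coords = rbind(aspBB, CB = aspCB, CG = aspCG,
                                       OD1 = od1, OD2 = od2)),
    list(resid = "ALA", coords = ala1),
    list(resid = "ALA", coords = ala2),
    list(resid = "SER", coords = rbind(binderBB, CB = cbB, OG = ogB)))

  # decoys in a 12-25 A shell around the TS centroid, min 3.5 A apart
  ctr <- colMeans(ts)
  placed <- rbind(ts, do.call(rbind, lapply(res, `[[`, "coords")))
  decoyTypes <- c(rep(c("GLY", "ALA", "LEU", "VAL"),
                      length.out = max(0, nDecoys)),
                  rep("SER", extraCatalytic[["S"]] %||% 0),
                  rep("HIS", extraCatalytic[["H"]] %||% 0),
                  rep("ASP", extraCatalytic[["D"]] %||% 0))
  for (ty in decoyTypes) {
    for (try_ in 1:200) {
      u <- .unit(stats::rnorm(3))
      r <- stats::runif(1, 12, 25)
      ca <- ctr + r * u
      if (min(sqrt(rowSums(sweep(placed, 2L, ca)^2))) < 3.5) next
      bb <- idealBackbone(ca, direction = .unit(stats::rnorm(3)),
                          up = .unit(stats::rnorm(3)))
      aa1 <- .AA3TO1[[ty]]
      sc <- if (aa1 %in% c("G")) NULL else {
        nchi <- chiCount(aa1)
        chi <- stats::runif(max(nchi, 1L), -180, 180)[seq_len(nchi)]
        buildSideChain(aa1, bb, chi,
                       hydroxylH = if (aa1 %in% c("S", "T", "Y")) 180 else NA)
      }
      co <- rbind(bb, sc)
      res[[length(res) + 1L]] <- list(resid = ty, coords = co)
      placed <- rbind(placed, co)
      break
    }
  }
  atoms <- do.call(rbind, lapply(seq_along(res), function(i)
    .mkAtoms(i, res[[i]]$resid, res[[i]]$coords)))
  structure_ <- proteinStructure(atoms, id = sprintf("toy-%d", seed))

  geometry <- list(
    nucleophile_ser = rbind(OG = og, CB = cb),
    base_his = ring[c("NE2", "ND1"), ],
    acid_asp_glu = rbind(OD1 = od1, OD2 = od2),
    oxyanion_nh_1 = rbind(N = n1),
    oxyanion_nh_2 = rbind(N = n2),
    carboxylate_binder_ser = rbind(OG = ogB),
    TS = ts)
  expected <- 0
  for (id in names(offsets))
    expected <- expected + tgt[[id]][["w"]] * offsets[[id]]^2
  truth <- list(
    positions = data.frame(
      role = c("nucleophile_ser", "base_his", "acid_asp_glu",
               "oxyanion_nh_1", "oxyanion_nh_2", "carboxylate_binder_ser"),
      chain = "A", resno = 1:6, stringsAsFactors = FALSE),
    geometry = geometry,
    expectedPenalty = expected)
  list(structure = structure_, truth = truth)
}

# shared atom roster for synthetic indicator frames; all event toggles move
# only side-chain/TS/H atoms so the protein backbone is rigorously static
.frameRoster <- function() {
  c1 <- c(0, 0, 0)
  oxy <- c(0, 0, 1.3)
  d <- .unit(c(1, 0, -0.3))
  ogIn <- c1 + 2.6 * d
  ogOut <- c1 + 3.4 * d
  serCB <- ogIn + 1.4 * d
  serBB <- idealBackbone(serCB + 1.53 * d, direction = d)
  vCO <- .unit(c1 - oxy)
  p1 <- .perp(vCO); p2 <- .unit(.vcross(vCO, p1))
  dn <- function(az) {
    axisA <- cos(az * pi / 180) * p1 + sin(az * pi / 180) * p2
    oxy + 2.9 * as.numeric(.rotvec(axisA * 120 * pi / 180) %*% vCO)
  }
  n1 <- dn(0); n2 <- dn(130)
  mkAla <- function(npos) {
    dirAway <- .unit(npos - oxy)
    ca <- npos + 1.458 * dirAway
    rbind(N = npos, CA = ca,
          C = ca + 1.525 * .unit(dirAway + .perp(dirAway)),
          O = ca + 1.525 * .unit(dirAway + .perp(dirAway)) + 1.231 * .perp(dirAway))
  }
  hIn <- function(npos) npos + 1.0 * .unit(oxy - npos)
  hOut <- function(npos) npos + 1.0 * .perp(oxy - npos)
  list(
    serBB = serBB, serCB = serCB, ogIn = ogIn, ogOut = ogOut,
    ala1 = mkAla(n1), ala2 = mkAla(n2), n1 = n1, n2 = n2,
    h1In = hIn(n1), h1Out = hOut(n1), h2In = hIn(n2), h2Out = hOut(n2),
    tsBase = rbind(C1 = c1, O1 = oxy, C2 = c(-1.2, 0.8, -0.5),
                   C3 = c(-2.0, 1.9, -1.0)),
    tsShift = c(0, 0, 6))
}

.eventPattern <- function(p, n, mode, forceFirst = FALSE) {
  if (mode == "deterministic") {
    k <- round(p * n)
    if (forceFirst && k < 1L)
      stop("the TS-RMSD indicator always counts the reference frame; ",
           "round(p*n) must be >= 1")
    pat <- rep(FALSE, n)
    ord <- sample.int(n)
    pat[ord[seq_len(k)]] <- TRUE
    if (forceFirst && !pat[1L]) {
      iSwap <- which(pat)[1L]
      pat[iSwap] <- FALSE
      pat[1L] <- TRUE
    }
    pat
  } else {
    pat <- stats::runif(n) < p
    if (forceFirst) pat[1L] <- TRUE
    pat
  }
}

#' Synthetic trajectory frames with prescribed indicator statistics
#'
#' Builds replicate [FrameSet-class] ensembles over a minimal active-site
#' roster (nucleophile Ser, two amide donors with explicit H, a 4-atom TS)
#' in which each catalytic indicator's defining geometric event occurs in
#' a controlled number of frames: exactly `round(p * n)` in
#' `"deterministic"` mode (randomized order), or per-frame Bernoulli
#' draws in `"bernoulli"` mode. Event toggles move only side-chain,
#' hydrogen or TS atoms, so the protein backbone is static and the
#' realized fractions are exact by construction. The first frame is the
#' TS-RMSD reference and always counts toward that indicator.
#'
#' @param probabilities Named numeric: `rmsd`, `attack`, `hbond1`,
#'   `hbond2`, each in \[0, 1\].
#' @param nFrames Frames per replicate.
#' @param nReplicates Number of replicates (default 1).
#' @param seed Integer seed.
#' @param mode `"deterministic"` (exact counts) or `"bernoulli"`.
#' @param designId Identifier stored on the frame sets.
#' @return List of [FrameSet-class]; attribute `"truth"` holds the
#'   realized per-replicate event fractions.
#' @export
synthFrames <- function(probabilities, nFrames, nReplicates = 1, seed = 1,
                        mode = c("deterministic", "bernoulli"),
                        designId = "design") {
  mode <- match.arg(mode)
  p <- probabilities
  stopifnot(all(c("rmsd", "attack", "hbond1", "hbond2") %in% names(p)),
            all(unlist(p) >= 0 & unlist(p) <= 1), nFrames >= 2L)
  ro <- .frameRoster()
  atomInfo <- data.frame(
    chain = "A",
    resno = c(rep(1L, 6L), rep(2L, 5L), rep(3L, 5L), rep(90L, 4L)),
    resid = c(rep("SER", 6L), rep("ALA", 5L), rep("ALA", 5L),
              rep("TSM", 4L)),
    elety = c("N", "CA", "C", "O", "CB", "OG",
              "N", "H", "CA", "C", "O",
              "N", "H", "CA", "C", "O",
              "C1", "O1", "C2", "C3"),
    stringsAsFactors = FALSE)
  atomInfo$element <- substr(atomInfo$elety, 1L, 1L)
  atomInfo$isTS <- atomInfo$resid == "TSM"
  atomInfo$backbone <- atomInfo$elety %in% .BACKBONE_ATOMS & !atomInfo$isTS
  labels <- c(serOG = 6L, tsC = 17L, tsOxy = 18L,
              donor1N = 7L, donor1H = 8L, donor2N = 12L, donor2H = 13L)
  base <- rbind(ro$serBB, CB = ro$serCB, OG = ro$ogIn,
                ro$ala1[c("N"), , drop = FALSE], H = ro$h1In,
                ro$ala1[c("CA", "C", "O"), ],
                ro$ala2[c("N"), , drop = FALSE], H = ro$h2In,
                ro$ala2[c("CA", "C", "O"), ],
                ro$tsBase)
  out <- vector("list", nReplicates)
  truth <- list()
  for (rep_ in seq_len(nReplicates)) {
    set.seed(seed + 7919L * rep_)
    pats <- list(
      rmsd = .eventPattern(p[["rmsd"]], nFrames, mode, forceFirst = TRUE),
      attack = .eventPattern(p[["attack"]], nFrames, mode),
      hbond1 = .eventPattern(p[["hbond1"]], nFrames, mode),
      hbond2 = .eventPattern(p[["hbond2"]], nFrames, mode))
    frames <- vector("list", nFrames)
    for (f in seq_len(nFrames)) {
      co <- base
      if (!pats$attack[f]) co["OG", ] <- ro$ogOut
      if (!pats$hbond1[f]) co[8L, ] <- ro$h1Out
      if (!pats$hbond2[f]) co[13L, ] <- ro$h2Out
      if (!pats$rmsd[f]) {
        co["C2", ] <- co["C2", ] + ro$tsShift
        co["C3", ] <- co["C3", ] + ro$tsShift
      }
      rownames(co) <- NULL
      frames[[f]] <- co
    }
    out[[rep_]] <- new("FrameSet", designId = designId,
                       replicateId = paste0("r", rep_),
                       frames = frames, atomInfo = atomInfo,
                       labels = labels, frameIntervalPs = 10)
    truth[[rep_]] <- vapply(pats, mean, numeric(1))
  }
  attr(out, "truth") <- truth
  out
}

#' Synthetic planted-truth screening cohort
#'
#' Generates the inputs for a funnel round: `nDesigns` designs of which a
#' planted subset strictly improves all four catalytic indicators over the
#' wild type, while every other design ties the wild type on exactly one
#' indicator (failing the strict test). Indicator levels are realized by
#' [synthFrames()] in deterministic mode, so with equal frame counts the
#' planted truth is recovered exactly.
#'
#' @param nDesigns Cohort size.
#' @param nImprove Number of planted improvers.
#' @param nFrames,nReplicates Per-design trajectory shape.
#' @param seed Integer seed.
#' @param wtP Wild-type indicator fractions.
#' @param delta Improvement margin added to `wtP` (default 0.2).
#' @return List: `provider` (function id -> list of FrameSet), `ids`,
#'   `wt` (list of wild-type FrameSets), `planted` (ids of the planted
#'   improvers).
#' @export
makeFunnelCohort <- function(nDesigns = 237, nImprove = 118,
                             nFrames = 100, nReplicates = 10, seed = 1,
                             wtP = c(rmsd = 0.50, attack = 0.40,
                                     hbond1 = 0.50, hbond2 = 0.45),
                             delta = 0.2) {
  stopifnot(nImprove <= nDesigns)
  ids <- sprintf("D%03d", seq_len(nDesigns))
  set.seed(seed)
  planted <- sort(sample(ids, nImprove))
  keys <- c("rmsd", "attack", "hbond1", "hbond2")
  pOf <- function(id) {
    i <- match(id, ids)
    p <- wtP + delta
    if (!(id %in% planted)) {
      tie <- keys[(i %% 4L) + 1L]
      p[tie] <- wtP[tie]
    }
    p
  }
  provider <- function(id) {
    i <- match(id, ids)
    synthFrames(pOf(id), nFrames = nFrames, nReplicates = nReplicates,
                seed = seed + 97L * i, mode = "deterministic",
                designId = id)
  }
  wt <- synthFrames(wtP, nFrames = nFrames, nReplicates = nReplicates,
                    seed = seed + 13L, mode = "deterministic",
                    designId = "WT")
  list(provider = provider, ids = ids, wt = wt, planted = planted)
}

#' Synthetic Michaelis-Menten initial-rate data
#'
#' Rates follow `v0/[E] = kcat [S] / (Km + [S])` with multiplicative
#' log-normal noise of the stated coefficient of variation; deterministic
#' given the seed. The default substrate grid emulates a 2-20 mM assay
#' series.
#'
#' @param kcat Turnover number, s-1.
#' @param Km Michaelis constant, mM.
#' @param substrate_mM Substrate grid (default 6 levels, 2-20 mM).
#' @param noiseCv Coefficient of variation of the multiplicative noise
#'   (0 = exact).
#' @param nRep Replicates per substrate level.
#' @param seed Integer seed.
#' @return `data.frame`: `substrate_mM`, `v0_over_E`, `replicate`.
#' @export
synthKinetics <- function(kcat, Km, substrate_mM = c(2, 4, 6, 10, 15, 20),
                          noiseCv = 0.05, nRep = 3, seed = 1) {
  stopifnot(kcat > 0, Km > 0, all(substrate_mM > 0), noiseCv >= 0)
  set.seed(seed)
  s <- rep(substrate_mM, each = nRep)
  mu <- kcat * s / (Km + s)
  if (noiseCv > 0) {
    sdlog <- sqrt(log(1 + noiseCv^2))
    mu <- mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  data.frame(substrate_mM = s, v0_over_E = mu,
             replicate = rep(seq_len(nRep), times = length(substrate_mM)))
}

#' Synthetic sequence-design table with randomized energy fields
#'
#' Emulates the output of design enumeration for testing the selection
#' filter at scale: unique mutation labels with a single/double/triple
#' mutation mix and randomized `ddG_bind`/`ddG_fold` fields
#' (`ddG_total` is their sum).
#'
#' @param n Number of designs (default 704: 104 singles, 400 doubles,
#'   200 triples when divisible accordingly).
#' @param seed Integer seed.
#' @return `data.frame` with `mutations`, `nMut`, `ddG_bind`, `ddG_fold`,
#'   `ddG_total`.
#' @export
synthDesignTable <- function(n = 704, seed = 1) {
  set.seed(seed)
  nMut <- if (n == 704L) rep(1:3, times = c(104L, 400L, 200L)) else
    sample(1:3, n, replace = TRUE)
  aa <- names(.AA1TO3)
  muts <- vapply(seq_len(n), function(i)
    paste0(sample(aa, nMut[i], replace = TRUE),
           sample(20:220, nMut[i]),
           sample(aa, nMut[i], replace = TRUE), collapse = "/"),
    character(1))
  muts <- make.unique(muts, sep = "_")
  data.frame(mutations = muts, nMut = nMut,
             ddG_bind = stats::rnorm(n, -1, 3),
             ddG_fold = stats::rnorm(n, 3, 4),
             ddG_total = NA_real_, stringsAsFactors = FALSE) ->
    df
  df$ddG_total <- df$ddG_bind + df$ddG_fold
  df
}
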