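#' @include AllClasses.R geometry.R
NULL

#' Load trajectory frames from a multi-model PDB
#'
#' Reads every MODEL of a multi-model PDB into a [FrameSet-class] and
#' resolves the catalytic atoms (Ser Ogamma, the TS tetrahedral carbon and
#' oxyanion oxygen, and the two oxyanion-hole donor N-H pairs) from a
#' label map. A labelled atom that is absent (non-finite) in any frame
#' raises an error naming the frame and the atom.
#'
#' @param path Multi-model PDB file.
#' @param labeling Named list mapping each required label (`serOG`, `tsC`,
#'   `tsOxy`, `donor1N`, `donor2N`; optionally `donor1H`, `donor2H`) to a
#'   `list(chain, resno, elety)` selector.
#' @param designId,replicateId Identifiers stored on the result.
#' @param frameIntervalPs Frame spacing in picoseconds (default 10).
#' @return A [FrameSet-class].
#' @export
loadFrames <- function(path, labeling, designId = "design",
                       replicateId = "r1", frameIntervalPs = 10) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  nFrames <- nrow(pdb$xyz)
  if (is.null(nFrames) || nFrames < 2L) stop("need at least 2 models")
  atomInfo <- data.frame(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    resid = trimws(a$resid), elety = trimws(a$elety),
    element = {
      e <- trimws(as.character(a$elesy))
      bad <- is.na(e) | !nzchar(e)
      e[bad] <- substr(trimws(a$elety)[bad], 1L, 1L)
      e
    },
    stringsAsFactors = FALSE)
  atomInfo$isTS <- !(atomInfo$resid %in% names(.AA3TO1))
  atomInfo$backbone <- atomInfo$elety %in% .BACKBONE_ATOMS & !atomInfo$isTS
  resolve <- function(lab, sel, required = TRUE) {
    i <- which(atomInfo$chain == sel$chain & atomInfo$resno == sel$resno &
               atomInfo$elety == sel$elety)
    if (length(i) != 1L) {
      if (required)
        stop("label '", lab, "': atom ", sel$elety, " of ", sel$chain,
             sel$resno, " not found uniquely")
      return(NA_integer_)
    }
    i
  }
  need <- c("serOG", "tsC", "tsOxy", "donor1N", "donor2N")
  opt <- c("donor1H", "donor2H")
  labels <- integer(0)
  for (lab in need) {
    if (is.null(labeling[[lab]])) stop("labeling missing '", lab, "'")
    labels[lab] <- resolve(lab, labeling[[lab]])
  }
  for (lab in opt)
    labels[lab] <- if (is.null(labeling[[lab]])) NA_integer_ else
      resolve(lab, labeling[[lab]], required = FALSE)
  frames <- lapply(seq_len(nFrames), function(f)
    matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE))
  # verify the labelled atoms exist in every frame
  for (f in seq_len(nFrames)) {
    for (lab in need) {
      if (!all(is.finite(frames[[f]][labels[[lab]], ])))
        stop("atom for label '", lab, "' (",
             atomInfo$elety[labels[[lab]]], ") absent in model ", f)
    }
  }
  new("FrameSet", designId = designId, replicateId = replicateId,
      frames = frames, atomInfo = atomInfo, labels = labels,
      frameIntervalPs = frameIntervalPs)
}

#' Write a FrameSet as a multi-model PDB
#'
#' @param x A [FrameSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFrames <- function(x, path) {
  stopifnot(is(x, "FrameSet"))
  con <- file(path, "w")
  on.exit(close(con))
  ai <- x@atomInfo
  fmtName <- function(n) {
    n <- substr(n, 1L, 4L)
    if (nchar(n) < 4L) formatC(paste0(" ", n), width = -4L) else n
  }
  for (f in seq_along(x@frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    co <- x@frames[[f]]
    for (i in seq_len(nrow(ai))) {
      writeLines(sprintf(
        "%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        if (ai$isTS[i]) "HETATM" else "ATOM", i, fmtName(ai$elety[i]),
        ai$resid[i], ai$chain[i], ai$resno[i],
        co[i, 1L], co[i, 2L], co[i, 3L], 1.0, 0.0, ai$element[i]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Compute the four catalytic indicators from a frame set
#'
#' Per frame: (i) the TS heavy-atom RMSD against the first frame, after
#' superposing the protein backbone of the frame onto the first frame's
#' backbone; (ii) the nucleophilic attack distance Ser Ogamma -- ester C;
#' (iii, iv) each oxyanion-hole hydrogen bond, evaluated with
#' [isHydrogenBond()] (explicit donor H when labelled, otherwise an
#' idealized amide H constructed from the donor's bonded neighbours).
#' Fractions are over all frames (the first frame trivially counts toward
#' the RMSD indicator).
#'
#' @param x A [FrameSet-class].
#' @param criteria [hbondCriteria()] for the oxyanion H-bonds.
#' @param rmsdCut TS RMSD cutoff, angstrom (default 2.5).
#' @param attackCut Attack-distance cutoff, angstrom (default 3.0).
#' @return A [CatalyticIndicatorSet-class].
#' @export
catalyticIndicators <- function(x, criteria = hbondCriteria(),
                                rmsdCut = 2.5, attackCut = 3.0) {
  stopifnot(is(x, "FrameSet"))
  ai <- x@atomInfo
  bb <- which(ai$backbone)
  tsIdx <- which(ai$isTS & toupper(ai$element) != "H")
  lb <- x@labels
  ref <- x@frames[[1L]]
  refBB <- ref[bb, , drop = FALSE]
  refTS <- ref[tsIdx, , drop = FALSE]
  n <- length(x@frames)
  rmsdOk <- attackOk <- hb1Ok <- hb2Ok <- logical(n)
  attackD <- numeric(n)
  donorH <- function(co, nIdx, hIdx) {
    if (!is.na(hIdx)) return(co[hIdx, ])
    # idealized amide H: bonded heavy neighbours of the donor N
    d2 <- rowSums(sweep(co, 2L, co[nIdx, ])^2)
    nbr <- which(d2 > 1e-6 & d2 < 1.7^2 & toupper(ai$element) != "H")
    if (!length(nbr)) stop("cannot idealize H: donor N has no neighbours")
    idealPolarHydrogen(co[nIdx, ], co[nbr, , drop = FALSE])
  }
  for (f in seq_len(n)) {
    co <- x@frames[[f]]
    # superpose protein backbone onto the reference, apply to TS atoms
    # (identity shortcut when the backbone has not moved)
    coBB <- co[bb, , drop = FALSE]
    if (max(abs(coBB - refBB)) < 1e-9) {
      tsAligned <- co[tsIdx, , drop = FALSE]
    } else {
      r <- kabschRmsd(refBB, coBB, superpose = TRUE)
      R <- attr(r, "rotation"); tr <- attr(r, "translation")
      tsAligned <- sweep(co[tsIdx, , drop = FALSE] %*% R, 2L, tr, `+`)
    }
    rmsdOk[f] <- sqrt(sum((refTS - tsAligned)^2) / nrow(refTS)) < rmsdCut
    attackD[f] <- .vdist(co[lb[["serOG"]], ], co[lb[["tsC"]], ])
    attackOk[f] <- attackD[f] < attackCut
    oxy <- co[lb[["tsOxy"]], ]
    h1 <- isHydrogenBond(co[lb[["donor1N"]], ],
                         donorH(co, lb[["donor1N"]], lb[["donor1H"]]),
                         oxy, criteria)
    h2 <- isHydrogenBond(co[lb[["donor2N"]], ],
                         donorH(co, lb[["donor2N"]], lb[["donor2H"]]),
                         oxy, criteria)
    hb1Ok[f] <- h1$bonded
    hb2Ok[f] <- h2$bonded
  }
  new("CatalyticIndicatorSet", designId = x@designId,
      freqRmsdTs = mean(rmsdOk), attackDistMean = mean(attackD),
      attackFrac3A = mean(attackOk), hbondFreq1 = mean(hb1Ok),
      hbondFreq2 = mean(hb2Ok), nFramesTotal = n)
}

#' Pool replicate indicators and compare against the wild type
#'
#' Pooling is frame-weighted: each fraction is the total event count over
#' all replicate frames divided by the total frame count (identical to the
#' mean of per-replicate fractions when frame counts are equal).
#' Improvement is strict on all four indicators -- higher `freqRmsdTs`,
#' higher `attackFrac3A` (the reported operationalization of a better
#' attack distance), and higher both H-bond frequencies; the pooled mean
#' attack distance is carried as a diagnostic only.
#'
#' @param perReplicate List of [CatalyticIndicatorSet-class] objects.
#' @param wt Pooled wild-type [CatalyticIndicatorSet-class], or `NULL` to
#'   skip the comparison.
#' @return List: `pooled` (a [CatalyticIndicatorSet-class]) and `improved`
#'   (logical verdict, `NA` when `wt` is `NULL`).
#' @export
aggregateAndCompare <- function(perReplicate, wt = NULL) {
  stopifnot(length(perReplicate) >= 1L)
  nf <- vapply(perReplicate, function(s) s@nFramesTotal, integer(1))
  wsum <- function(get) sum(vapply(perReplicate, get, numeric(1)) * nf) / sum(nf)
  pooled <- new("CatalyticIndicatorSet",
                designId = perReplicate[[1L]]@designId,
                freqRmsdTs = wsum(function(s) s@freqRmsdTs),
                attackDistMean = wsum(function(s) s@attackDistMean),
                attackFrac3A = wsum(function(s) s@attackFrac3A),
                hbondFreq1 = wsum(function(s) s@hbondFreq1),
                hbondFreq2 = wsum(function(s) s@hbondFreq2),
                nFramesTotal = sum(nf))
  improved <- NA
  if (!is.null(wt)) {
    pv <- indicatorVector(pooled)
    wv <- indicatorVector(wt)
    improved <- all(pv > wv)
  }
  list(pooled = pooled, improved = improved)
}

#' Default two-round screening funnel configuration
#'
#' Round 1: 10 replicate 1-ns trajectories (100 frames at 10 ps);
#' round 2: 5 replicate 5-ns trajectories (500 frames). A design survives
#' a round iff all four pooled catalytic indicators are strictly better
#' than the wild type's.
#'
#' @param round1,round2 Lists with `replicates` and `nFrames`.
#' @param rankKeys Indicator names (in order) used for the final ranking
#'   of round-2 survivors, best-first by decreasing value.
#' @return Funnel configuration list.
#' @export
funnelConfig <- function(round1 = list(replicates = 10, nFrames = 100),
                         round2 = list(replicates = 5, nFrames = 500),
                         rankKeys = c("attackFrac3A", "freqRmsdTs",
                                      "hbondFreq1", "hbondFreq2")) {
  list(round1 = round1, round2 = round2, rankKeys = rankKeys)
}

#' Run the two-round virtual-screening funnel
#'
#' Round 1 pools each design's replicate trajectories and keeps designs
#' strictly improving all four catalytic indicators over the wild type;
#' round-2 frame sets are then obtained for the survivors (from
#' `round2Provider`) and the same strict-improvement test is applied
#' against the round-2 wild type. Survivors missing round-2 data are
#' listed as `"pending"` and excluded from the final ranking. The report
#' is fully deterministic and invariant to the order of `designs`.
#'
#' @param designs Named list (design id -> list of [FrameSet-class]
#'   round-1 replicates), or a function `(id) -> list of FrameSet` in
#'   which case `designIds` must be given.
#' @param wtR1 List of wild-type round-1 [FrameSet-class] replicates (or a
#'   pooled [CatalyticIndicatorSet-class]).
#' @param round2Provider Function `(id) -> list of FrameSet` or `NULL`
#'   (no round-2 data; all survivors pending).
#' @param wtR2 As `wtR1`, for round 2.
#' @param config A [funnelConfig()].
#' @param designIds Design ids (required when `designs` is a function).
#' @return A `ScreeningReport` list: `round1` / `round2` indicator tables
#'   (`data.frame`), `round1Survivors`, `round2Survivors`, `pending`,
#'   `shortlist` (ranked round-2 survivors).
#' @export
twoRoundFunnel <- function(designs, wtR1, round2Provider = NULL, wtR2 = NULL,
                           config = funnelConfig(), designIds = NULL) {
  getFrames <- if (is.function(designs)) designs else function(id) designs[[id]]
  ids <- if (is.function(designs)) designIds else names(designs)
  if (is.null(ids)) stop("design ids are required")
  ids <- sort(ids)
  poolOf <- function(x) {
    if (is(x, "CatalyticIndicatorSet")) return(x)
    aggregateAndCompare(lapply(x, catalyticIndicators))$pooled
  }
  wt1 <- poolOf(wtR1)
  indRow <- function(id, pooled, improved) {
    v <- indicatorVector(pooled)
    data.frame(designId = id, freqRmsdTs = v[["freqRmsdTs"]],
               attackFrac3A = v[["attackFrac3A"]],
               hbondFreq1 = v[["hbondFreq1"]], hbondFreq2 = v[["hbondFreq2"]],
               attackDistMean = pooled@attackDistMean,
               nFrames = pooled@nFramesTotal, improved = improved,
               stringsAsFactors = FALSE)
  }
  r1rows <- lapply(ids, function(id) {
    agg <- aggregateAndCompare(lapply(getFrames(id), catalyticIndicators),
                               wt = wt1)
    indRow(id, agg$pooled, agg$improved)
  })
  round1 <- do.call(rbind, r1rows)
  survivors1 <- round1$designId[round1$improved]
  round2 <- NULL
  survivors2 <- character(0)
  pending <- character(0)
  if (length(survivors1)) {
    wt2 <- if (is.null(wtR2)) NULL else poolOf(wtR2)
    r2rows <- list()
    for (id in survivors1) {
      fr <- if (is.null(round2Provider)) NULL else round2Provider(id)
      if (is.null(fr)) {
        pending <- c(pending, id)
        next
      }
      agg <- aggregateAndCompare(lapply(fr, catalyticIndicators), wt = wt2)
      r2rows[[id]] <- indRow(id, agg$pooled, agg$improved)
    }
    if (length(r2rows)) {
      round2 <- do.call(rbind, r2rows)
      rownames(round2) <- NULL
      survivors2 <- round2$designId[round2$improved]
    }
  }
  shortlist <- character(0)
  if (length(survivors2)) {
    sub <- round2[round2$designId %in% survivors2, , drop = FALSE]
    ord <- do.call(order, c(lapply(config$rankKeys,
                                   function(k) -sub[[k]]),
                            list(sub$designId)))
    shortlist <- sub$designId[ord]
  }
  structure(list(round1 = round1, round2 = round2,
                 round1Survivors = survivors1, round2Survivors = survivors2,
                 pending = pending, shortlist = shortlist,
                 config = config),
            class = "ScreeningReport")
}

#' @export
print.ScreeningReport <- function(x, ...) {
  cat("ScreeningReport:", nrow(x$round1), "designs ->",
      length(x$round1Survivors), "round-1 survivors ->",
      length(x$round2Survivors), "round-2 survivors",
      if (length(x$pending)) paste0("(", length(x$pending), " pending)"),
      "\n")
  invisible(x)
}
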