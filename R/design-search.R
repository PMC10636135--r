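#' @include design-energy.R
NULL

# effective singles for a state; bound = template + TS terms, unbound = apo
.stateSingles <- function(tables, state = c("bound", "unbound")) {
  state <- match.arg(state)
  n <- nrow(tables@positions)
  lapply(seq_len(n), function(i) {
    s <- tables@singlesTmpl[[i]]
    if (state == "bound" && length(tables@singlesTS[[i]]) == length(s))
      s <- s + tables@singlesTS[[i]]
    s
  })
}

.pairMat <- function(tables, i, j) {
  if (i < j) tables@pairs[[paste(i, j)]]
  else if (i > j) {
    m <- tables@pairs[[paste(j, i)]]
    if (is.null(m)) NULL else t(m)
  } else NULL
}

# Goldstein singles dead-end elimination; returns logical list of live
# rotamers per position (restricted to `allowed` rotamer index sets)
.deeGoldstein <- function(tables, singles, allowed) {
  n <- length(singles)
  live <- lapply(allowed, function(a) a)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      if (length(live[[i]]) <= 1L) next
      drop <- logical(length(live[[i]]))
      for (ri in seq_along(live[[i]])) {
        r <- live[[i]][ri]
        for (t in live[[i]]) {
          if (t == r) next
          lhs <- singles[[i]][r] - singles[[i]][t]
          for (j in seq_len(n)) {
            if (j == i) next
            m <- .pairMat(tables, i, j)
            if (is.null(m)) next
            diff <- m[r, live[[j]]] - m[t, live[[j]]]
            lhs <- lhs + min(diff)
          }
          if (lhs > 1e-12) { drop[ri] <- TRUE; break }
        }
      }
      if (any(drop)) {
        live[[i]] <- live[[i]][!drop]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  live
}

# exact branch-and-bound over live rotamer sets; returns assignment + energy
.branchBound <- function(tables, singles, live) {
  n <- length(singles)
  ord <- order(vapply(live, length, integer(1)))
  # greedy incumbent
  assign <- integer(n)
  for (i in ord) {
    best <- Inf; bestR <- live[[i]][1L]
    for (r in live[[i]]) {
      e <- singles[[i]][r]
      for (j in ord) {
        if (j == i || assign[j] == 0L) next
        m <- .pairMat(tables, i, j)
        if (!is.null(m)) e <- e + m[r, assign[j]]
      }
      if (e < best) { best <- e; bestR <- r }
    }
    assign[i] <- bestR
  }
  energyOf <- function(asg) {
    e <- sum(vapply(seq_len(n), function(i) singles[[i]][asg[i]], numeric(1)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      m <- .pairMat(tables, i, j)
      if (!is.null(m)) e <- e + m[asg[i], asg[j]]
    }
    e
  }
  incumbent <- energyOf(assign)
  bestAssign <- assign
  # precomputed pairwise minima for the bound
  minPair <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    m <- .pairMat(tables, i, j)
    if (!is.null(m))
      minPair[i, j] <- minPair[j, i] <- min(m[live[[i]], live[[j]], drop = FALSE])
  }
  cur <- integer(n)
  recurse <- function(k, eSoFar) {
    if (k > n) {
      if (eSoFar < incumbent - 1e-12) {
        incumbent <<- eSoFar
        bestAssign <<- cur
      }
      return(invisible())
    }
    i <- ord[k]
    rest <- if (k < n) ord[(k + 1L):n] else integer(0)
    for (r in live[[i]]) {
      e <- eSoFar + singles[[i]][r]
      for (kk in seq_len(k - 1L)) {
        j <- ord[kk]
        m <- .pairMat(tables, i, j)
        if (!is.null(m)) e <- e + m[r, cur[j]]
      }
      # admissible bound over the unassigned tail
      lb <- e
      for (j in rest) {
        bj <- Inf
        for (s in live[[j]]) {
          ej <- singles[[j]][s]
          for (kk in seq_len(k)) {
            jj <- if (kk < k) ord[kk] else i
            m <- .pairMat(tables, j, jj)
            if (!is.null(m)) ej <- ej + m[s, if (jj == i) r else cur[jj]]
          }
          if (ej < bj) bj <- ej
        }
        lb <- lb + bj
      }
      for (a in seq_along(rest)) for (b in seq_along(rest)) {
        if (a < b) lb <- lb + minPair[rest[a], rest[b]]
      }
      if (lb > incumbent + 1e-12) next
      cur[i] <<- r
      recurse(k + 1L, e)
      cur[i] <<- 0L
    }
  }
  recurse(1L, 0)
  list(assignment = bestAssign, energy = incumbent)
}

#' Certified global-minimum rotamer/sequence search
#'
#' Dead-end elimination (Goldstein singles criterion, iterated to a fixed
#' point) followed by exact branch-and-bound over the surviving rotamers.
#' The returned assignment is the certified global minimum of the
#' pairwise-decomposed energy; no heuristics are applied silently, and an
#' unprunable search space beyond `maxSpace` raises an error instead.
#'
#' @param tables An `EnergyTables` object ([computeEnergyTables()]).
#' @param state `"bound"` (with TS terms) or `"unbound"` (apo).
#' @param restrictAa Optional list (per position) of allowed amino-acid
#'   vectors; `NULL` allows every non-`wtOnly` rotamer.
#' @param includeWtOnly Allow `wtOnly` (wild-type reference) rotamers.
#' @param maxSpace Error out if the post-DEE assignment space exceeds this
#'   (default 1e8).
#' @return List: `assignment` (rotamer index per position), `sequence`
#'   (one-letter aa per position), `energy`, `nLive` (rotamers surviving
#'   DEE per position), `certified = TRUE`.
#' @export
searchGmec <- function(tables, state = c("bound", "unbound"),
                       restrictAa = NULL, includeWtOnly = FALSE,
                       maxSpace = 1e8) {
  state <- match.arg(state)
  singles <- .stateSingles(tables, state)
  n <- nrow(tables@positions)
  allowed <- lapply(seq_len(n), function(i) {
    rots <- tables@rotamers[[i]]
    ok <- vapply(rots, function(r)
      includeWtOnly || !isTRUE(r$wtOnly), logical(1))
    if (!is.null(restrictAa) && !is.null(restrictAa[[i]]))
      ok <- ok & vapply(rots, function(r) r$aa %in% restrictAa[[i]],
                        logical(1))
    which(ok)
  })
  if (any(vapply(allowed, length, integer(1)) == 0L))
    stop("a design position has no allowed rotamers")
  live <- .deeGoldstein(tables, singles, allowed)
  space <- prod(vapply(live, length, numeric(1)))
  if (space > maxSpace)
    stop("unpruned search space too large after DEE: ",
         format(space, scientific = TRUE), " assignments")
  sol <- .branchBound(tables, singles, live)
  list(assignment = sol$assignment,
       sequence = vapply(seq_len(n), function(i)
         tables@rotamers[[i]][[sol$assignment[i]]]$aa, character(1)),
       energy = sol$energy,
       nLive = vapply(live, length, integer(1)),
       certified = TRUE)
}

# best rotamer assignment for a fixed amino-acid sequence
.sequenceOptimum <- function(tables, seqAa, state, includeWtOnly = TRUE) {
  searchGmec(tables, state = state,
             restrictAa = as.list(seqAa), includeWtOnly = includeWtOnly)
}

#' Mutation labels of a sequence relative to the wild type
#' @param tables An `EnergyTables` object.
#' @param seqAa Character vector, one aa per design position.
#' @return Character scalar like `"I171K/G130L"` (`"WT"` if identical).
#' @export
mutationString <- function(tables, seqAa) {
  pos <- tables@positions
  d <- which(seqAa != pos$nativeAa)
  if (!length(d)) return("WT")
  paste0(pos$nativeAa[d], pos$resno[d], seqAa[d], collapse = "/")
}

#' Enumerate low-energy sequence designs with full energy accounting
#'
#' Enumerates amino-acid sequences over the mutable positions, finds each
#' sequence's optimal rotamer assignment in the bound (enzyme-TS complex)
#' and unbound (apo) states, and reports the thermodynamic bookkeeping
#' used for candidate selection: `G_bind = G_bound - G_unbound`,
#' `G_fold = G_unbound`, and the mutant-minus-wild-type differences
#' `ddG_bind`, `ddG_fold`, `ddG_total = ddG_bind + ddG_fold`. Returned
#' designs are sorted by bound-state energy; every returned pair of
#' sequences differs in at least `diversity` amino-acid types (greedy
#' selection down the energy ranking, equivalent to successive exact
#' solves with exclusion constraints).
#'
#' @param tables An `EnergyTables` object.
#' @param count Maximum number of designs to return.
#' @param diversity Minimum number of differing positions between any two
#'   returned designs (default 1 = all distinct sequences).
#' @param maxMutations Optional cap on mutations per design (e.g. 3 for a
#'   single/double/triple scheme); `NULL` = no cap.
#' @param maxSequences Enumeration guard (default 2e4).
#' @return `data.frame` with columns `mutations`, `nMut`, `G_bound`,
#'   `G_unbound`, `G_bind`, `G_fold`, `ddG_bind`, `ddG_fold`, `ddG_total`.
#'   The wild-type reference row is attached as attribute `"wt"`.
#' @export
enumerateDesigns <- function(tables, count = 10, diversity = 1,
                             maxMutations = NULL, maxSequences = 2e4) {
  pos <- tables@positions
  n <- nrow(pos)
  aaSets <- lapply(seq_len(n), function(i) {
    if (pos$type[i] == "mutable")
      unique(vapply(Filter(function(r) !isTRUE(r$wtOnly),
                           tables@rotamers[[i]]), `[[`, character(1), "aa"))
    else pos$nativeAa[i]
  })
  space <- prod(vapply(aaSets, length, numeric(1)))
  if (space > maxSequences)
    stop("sequence space too large to enumerate: ", format(space))
  seqs <- expand.grid(aaSets, stringsAsFactors = FALSE)
  nMut <- rowSums(t(t(as.matrix(seqs)) != pos$nativeAa) != 0)
  nMut <- as.integer(nMut)
  if (!is.null(maxMutations)) {
    keep <- nMut <= maxMutations
    seqs <- seqs[keep, , drop = FALSE]
    nMut <- nMut[keep]
  }
  # wild-type reference (native aa everywhere, rotamers re-optimized)
  wtB <- .sequenceOptimum(tables, pos$nativeAa, "bound")
  wtU <- .sequenceOptimum(tables, pos$nativeAa, "unbound")
  wtBind <- wtB$energy - wtU$energy
  wtFold <- wtU$energy
  rows <- lapply(seq_len(nrow(seqs)), function(k) {
    sq <- as.character(seqs[k, ])
    b <- .sequenceOptimum(tables, sq, "bound", includeWtOnly = FALSE)
    u <- .sequenceOptimum(tables, sq, "unbound", includeWtOnly = FALSE)
    gBind <- b$energy - u$energy
    data.frame(mutations = mutationString(tables, sq), nMut = nMut[k],
               G_bound = b$energy, G_unbound = u$energy,
               G_bind = gBind, G_fold = u$energy,
               ddG_bind = gBind - wtBind, ddG_fold = u$energy - wtFold,
               ddG_total = (gBind - wtBind) + (u$energy - wtFold),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$G_bound, df$mutations), , drop = FALSE]
  # greedy diversity filter down the energy ranking
  sel <- integer(0)
  seqMat <- as.matrix(seqs)[order(do.call(rbind, rows)$G_bound,
                                  do.call(rbind, rows)$mutations), ,
                            drop = FALSE]
  for (k in seq_len(nrow(df))) {
    ok <- TRUE
    for (s in sel) {
      if (sum(seqMat[k, ] != seqMat[s, ]) < diversity) { ok <- FALSE; break }
    }
    if (ok) sel <- c(sel, k)
    if (length(sel) >= count) break
  }
  if (length(sel) < count)
    warning("only ", length(sel), " designs satisfy the diversity ",
            "constraint (", count, " requested)")
  out <- df[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "wt") <- data.frame(mutations = "WT", nMut = 0L,
                                G_bound = wtB$energy, G_unbound = wtU$energy,
                                G_bind = wtBind, G_fold = wtFold,
                                ddG_bind = 0, ddG_fold = 0, ddG_total = 0)
  out
}

#' Select designs for virtual screening
#'
#' Applies the published two-clause admission rule: a design is kept iff
#' (`ddG_bind < bindMax` AND `ddG_fold < foldMax`) OR its `ddG_total` rank
#' is within the top `topTotal` of the input set. Rank ties are broken by
#' mutation-string lexicographic order, making the selection deterministic,
#' order-invariant and idempotent. Additional criteria (mutation diversity,
#' manual inspection) can be plugged in via `extraFilters`.
#'
#' @param designs `data.frame` with at least `mutations`, `ddG_bind`,
#'   `ddG_fold`, `ddG_total`.
#' @param criteria List: `bindMax` (default 0 kcal/mol), `foldMax`
#'   (default 8 kcal/mol), `topTotal` (default 30).
#' @param extraFilters Optional list of `function(designs) -> logical`
#'   vectors combined with AND after the admission rule.
#' @return The selected rows, with an `admittedBy` audit column
#'   (`"energy"`, `"rank"` or `"energy+rank"`); attribute `"audit"` holds
#'   the full per-design log including rejected rows.
#' @export
selectCandidates <- function(designs,
                             criteria = list(bindMax = 0, foldMax = 8,
                                             topTotal = 30),
                             extraFilters = NULL) {
  crit <- utils::modifyList(list(bindMax = 0, foldMax = 8, topTotal = 30),
                            criteria)
  ord <- order(designs$ddG_total, designs$mutations)
  rank <- integer(nrow(designs))
  rank[ord] <- seq_len(nrow(designs))
  clauseE <- designs$ddG_bind < crit$bindMax & designs$ddG_fold < crit$foldMax
  clauseR <- rank <= crit$topTotal
  admitted <- clauseE | clauseR
  tag <- ifelse(clauseE & clauseR, "energy+rank",
                ifelse(clauseE, "energy", ifelse(clauseR, "rank", "")))
  if (!is.null(extraFilters)) {
    for (f in extraFilters) admitted <- admitted & f(designs)
  }
  audit <- data.frame(mutations = designs$mutations, rank_total = rank,
                      clause_energy = clauseE, clause_rank = clauseR,
                      admitted = admitted, stringsAsFactors = FALSE)
  out <- designs[admitted, , drop = FALSE]
  out$admittedBy <- tag[admitted]
  out <- out[order(rank[admitted]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}
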