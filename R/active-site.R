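#' @include AllClasses.R geometry.R
NULL

#' Load an active-site model from a YAML config
#'
#' Reads a YAML description of catalytic roles, geometric constraints and
#' the transition-state (TS) pseudo-molecule into an
#' [ActiveSiteModel-class]. With `path = NULL` the shipped default model
#' for MHET hydrolysis by a Ser-His-Asp serine hydrolase is loaded: 6
#' catalytic roles (triad, two backbone-NH oxyanion donors, carboxylate-
#' binding hydroxyl) and 9 distance/angle constraints encoding canonical
#' serine-hydrolase geometry. All cross-references are validated; a
#' dangling role or TS atom reference raises an error naming the offending
#' constraint.
#'
#' @param path YAML config path, or `NULL` for the shipped default.
#' @return A validated [ActiveSiteModel-class].
#' @export
loadActiveSiteConfig <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "active_site_mhet.yaml", package = "enzdes",
                        mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 scans bare N/Y as booleans; those are legitimate amino-acid
  # codes and atom names here, so map them back
  unbool <- function(v) {
    if (is.atomic(v) && !is.logical(v)) return(as.character(v))
    unlist(lapply(v, function(x)
      if (is.logical(x)) ifelse(x, "Y", "N") else as.character(x)))
  }
  for (field in c("roles", "constraints", "ts"))
    if (is.null(cfg[[field]]))
      stop("active-site config missing '", field, "' section")
  roles <- lapply(cfg$roles, function(r) {
    if (is.null(r$role_id) || is.null(r$allowed_aa))
      stop("each role needs 'role_id' and 'allowed_aa'")
    list(roleId = r$role_id,
         allowedAa = unbool(r$allowed_aa),
         anchorAtoms = lapply(r$anchor_atoms, function(am)
           lapply(am, unbool)))
  })
  ids <- vapply(roles, `[[`, character(1), "roleId")
  required <- c("nucleophile_ser", "base_his", "acid_asp_glu")
  missing <- setdiff(required, ids)
  if (length(missing))
    stop("active-site config missing required role(s): ",
         paste(missing, collapse = ", "))
  constraints <- lapply(cfg$constraints, function(con) {
    if (is.null(con$id) || is.null(con$kind) || is.null(con$atoms))
      stop("each constraint needs 'id', 'kind' and 'atoms'")
    if (is.null(con$lo) || is.null(con$hi) || is.null(con$target))
      stop("constraint ", con$id, ": needs 'target', 'lo', 'hi'")
    if (con$lo > con$hi)
      stop("constraint ", con$id, ": tol_lo > tol_hi")
    list(id = con$id, kind = con$kind,
         atoms = lapply(con$atoms, function(a)
           c(unbool(a[[1L]]), unbool(a[[2L]]))),
         target = as.numeric(con$target), lo = as.numeric(con$lo),
         hi = as.numeric(con$hi),
         weight = if (is.null(con$weight)) 1 else as.numeric(con$weight))
  })
  tsc <- cfg$ts
  atoms <- do.call(rbind, lapply(tsc$atoms, function(a)
    data.frame(name = trimws(a$name), element = a$element,
               charge = as.numeric(a$charge),
               x = a$xyz[[1L]], y = a$xyz[[2L]], z = a$xyz[[3L]],
               stringsAsFactors = FALSE)))
  bonds <- do.call(rbind, lapply(tsc$bonds, function(b)
    matrix(trimws(c(b[[1L]], b[[2L]])), nrow = 1L)))
  torsions <- lapply(tsc$rotatable_torsions, function(t) trimws(unlist(t)))
  ts <- new("TSMolecule", atoms = atoms, bonds = bonds,
            tetrahedralCenter = trimws(tsc$tetrahedral_center),
            torsions = torsions)
  aliases <- if (is.null(tsc$atom_aliases)) list() else
    lapply(tsc$atom_aliases, function(a) trimws(unlist(a)))
  model <- new("ActiveSiteModel", roles = roles, constraints = constraints,
               ts = ts, tsAliases = aliases)
  validObject(model)
  model
}

# candidate atom names for a constraint atom reference c(ref, name) given the
# model's aliases; role-side aliases come from the union of per-aa anchor maps
.atomCandidates <- function(model, ref, name) {
  if (ref == "TS") {
    if (name %in% names(model@tsAliases)) return(model@tsAliases[[name]])
    return(name)
  }
  role <- NULL
  for (r in model@roles) if (r$roleId == ref) role <- r
  cand <- character(0)
  for (aaMap in role$anchorAtoms)
    if (name %in% names(aaMap)) cand <- c(cand, unlist(aaMap[[name]]))
  if (length(cand)) unique(cand) else name
}

# out-of-window excess; dihedrals compared on the circle
.windowExcess <- function(value, lo, hi, kind) {
  if (kind == "dihedral") {
    # shortest signed angular distance into [lo, hi]
    wrap <- function(a) ((a + 180) %% 360) - 180
    if (value >= lo && value <= hi) return(0)
    return(min(abs(wrap(value - lo)), abs(wrap(value - hi))))
  }
  if (value < lo) lo - value else if (value > hi) value - hi else 0
}

#' Score placed active-site geometry against a model
#'
#' Computes the total geometric penalty of a placed active site:
#' `sum_i weight_i * excess_i^2`, where `excess_i` is the distance of the
#' measured value of constraint `i` outside its tolerance window
#' (0 inside). Distances contribute in squared angstroms, angles in squared
#' degrees (scaled by their typically much smaller weights). Where a
#' constraint atom is an alias over several physical atoms (e.g. either
#' carboxylate oxygen), the candidate minimizing that constraint's penalty
#' is used.
#'
#' @param model An [ActiveSiteModel-class].
#' @param geometry Named list mapping each role id to a coordinate matrix
#'   with rownames = atom names, plus element `TS` holding the TS pose.
#' @return Total penalty (single non-negative number) with attribute
#'   `"breakdown"`: a `data.frame` with columns `id`, `kind`, `measured`,
#'   `excess`, `penalty`.
#' @export
constraintPenalty <- function(model, geometry) {
  stopifnot(is(model, "ActiveSiteModel"))
  rows <- lapply(model@constraints, function(con) {
    cand <- lapply(con$atoms, function(at) {
      ref <- at[[1L]]; nm <- at[[2L]]
      coords <- geometry[[ref]]
      if (is.null(coords))
        stop("constraint ", con$id, ": no geometry for '", ref, "'")
      nms <- intersect(.atomCandidates(model, ref, nm), rownames(coords))
      if (!length(nms))
        stop("constraint ", con$id, ": atom '", nm, "' of '", ref,
             "' not resolvable in placed geometry")
      lapply(nms, function(n) coords[n, ])
    })
    combos <- expand.grid(lapply(cand, seq_along))
    best <- NULL
    for (k in seq_len(nrow(combos))) {
      pts <- do.call(rbind, Map(function(opts, i) opts[[i]],
                                cand, as.integer(combos[k, ])))
      val <- measureGeometry(con$kind, pts)
      exc <- .windowExcess(val, con$lo, con$hi, con$kind)
      pen <- con$weight * exc^2
      if (is.null(best) || pen < best$pen) best <- list(val = val, exc = exc,
                                                        pen = pen)
    }
    data.frame(id = con$id, kind = con$kind, measured = best$val,
               excess = best$exc, penalty = best$pen,
               stringsAsFactors = FALSE)
  })
  breakdown <- do.call(rbind, rows)
  total <- sum(breakdown$penalty)
  attr(total, "breakdown") <- breakdown
  total
}
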