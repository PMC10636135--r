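#' @include AllClasses.R
NULL

.WATER_RESID <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "DOD")
.ION_RESID <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "NI",
                "CO", "CD", "SO4", "PO4", "IOD", "BR")

#' Read a protein structure from a PDB file
#'
#' Parses a PDB file (via \pkg{bio3d}) into a [ProteinStructure-class].
#' Dialect rules: waters are always removed; other hetero records (ions,
#' ligands) are dropped unless `keepHet = TRUE`; for alternate locations
#' only the first altLoc is kept; hydrogens are read if present but never
#' required; insertion codes are preserved. Standard residues missing any
#' backbone atom (N, CA, C, O) produce a warning and are flagged in
#' [residueTable()] (`hasBackbone = FALSE`), not dropped.
#'
#' @param path Path to a PDB file.
#' @param keepHet Keep non-water hetero residues? Default `FALSE`.
#' @param id Scaffold identifier; defaults to the file base name.
#' @return A [ProteinStructure-class].
#' @export
readStructure <- function(path, keepHet = FALSE, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  # first altLoc only: PDB convention lists altLoc A before B, so keeping the
  # first record per (chain, resno, insert, atom name) implements the rule
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety)), ,
         drop = FALSE]
  resid <- trimws(a$resid)
  is_water <- resid %in% .WATER_RESID
  a <- a[!is_water, , drop = FALSE]
  resid <- trimws(a$resid)
  het <- !(resid %in% names(.AA3TO1))
  if (!keepHet) {
    a <- a[!het, , drop = FALSE]
    het <- het[!het]
  }
  if (nrow(a) == 0L) stop("no atoms left after filtering in '", path, "'")
  ins <- trimws(as.character(a$insert))
  ins[is.na(ins)] <- ""
  elesy <- trimws(as.character(a$elesy))
  elesy[is.na(elesy) | !nzchar(elesy)] <-
    substr(trimws(a$elety[is.na(elesy) | !nzchar(elesy)]), 1L, 1L)
  atoms <- data.frame(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    insert = ins, resid = trimws(a$resid), elety = trimws(a$elety),
    element = elesy, x = a$x, y = a$y, z = a$z,
    backbone = trimws(a$elety) %in% .BACKBONE_ATOMS & !het,
    het = het, stringsAsFactors = FALSE)
  s <- new("ProteinStructure",
           id = if (is.null(id)) sub("\\.(pdb|ent)$", "", basename(path)) else id,
           atoms = atoms, meta = list(source = path))
  rt <- residueTable(s)
  bad <- rt[!rt$het & !rt$hasBackbone, , drop = FALSE]
  if (nrow(bad))
    warning("residues with incomplete backbone (flagged, not dropped): ",
            paste0(bad$chain, bad$resno, bad$insert, collapse = ", "))
  s
}

#' Write a ProteinStructure to a PDB file
#'
#' Coordinates are written at the standard PDB precision (1e-3 angstrom),
#' so `readStructure(writeStructure(s))` round-trips coordinates to that
#' precision and preserves residue count and ordering.
#'
#' @param x A [ProteinStructure-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(x, path) {
  stopifnot(is(x, "ProteinStructure"))
  a <- x@atoms
  bio3d::write.pdb(file = path,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   insert = ifelse(nzchar(a$insert), a$insert, ""),
                   elety = a$elety, elesy = a$element)
  invisible(path)
}

#' Construct a ProteinStructure from an atom table
#'
#' Programmatic constructor used by the synthetic-scaffold generator and
#' tests. See [ProteinStructure-class] for the required columns; `backbone`
#' and `het` are inferred when absent.
#'
#' @param atoms `data.frame` of atoms.
#' @param id Scaffold identifier.
#' @param meta Optional provenance list.
#' @return A [ProteinStructure-class].
#' @export
proteinStructure <- function(atoms, id = "synthetic", meta = list()) {
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$element)) atoms$element <- substr(atoms$elety, 1L, 1L)
  if (is.null(atoms$het)) atoms$het <- !(atoms$resid %in% names(.AA3TO1))
  if (is.null(atoms$backbone))
    atoms$backbone <- atoms$elety %in% .BACKBONE_ATOMS & !atoms$het
  new("ProteinStructure", id = id,
      atoms = as.data.frame(atoms, stringsAsFactors = FALSE), meta = meta)
}

#' Residues within a radius of a point
#'
#' A residue is included iff any of its atoms lies within `radius` of
#' `center` (all-atom test). The typical use is selecting design shells
#' around a bound ligand (e.g. every residue with an atom inside 10
#' angstroms of the substrate).
#'
#' @param x A [ProteinStructure-class].
#' @param center Length-3 numeric center (angstrom).
#' @param radius Positive radius (angstrom).
#' @return [residueTable()] rows of the included residues with an extra
#'   `minDist` column, sorted by increasing minimal atom distance.
#' @export
neighborsWithin <- function(x, center, radius) {
  stopifnot(is(x, "ProteinStructure"), radius > 0)
  center <- as.numeric(center)
  stopifnot(length(center) == 3L)
  a <- x@atoms
  if (nrow(a) == 0L) return(residueTable(x)[0, ])
  d <- sqrt((a$x - center[1L])^2 + (a$y - center[2L])^2 + (a$z - center[3L])^2)
  key <- .residueKey(a)
  dmin <- tapply(d, factor(key, levels = unique(key)), min)
  rt <- residueTable(x)
  rt$minDist <- as.numeric(dmin)
  rt <- rt[rt$minDist <= radius, , drop = FALSE]
  rt <- rt[order(rt$minDist, rt$index0), , drop = FALSE]
  rownames(rt) <- NULL
  rt
}

#' Filter a scaffold-metadata library
#'
#' Applies the library assembly filters used when collecting thermophilic
#' hydrolase scaffolds from the PDB: expressibility, crystallographic
#' resolution cutoff, sequence-length bounds, keyword list, and enzyme
#' class; optionally a greedy keep-first sequence-identity de-duplication
#' when a pairwise identity matrix is supplied. Records with missing fields
#' fail that filter and are logged, not errored.
#'
#' @param records `data.frame` with columns `id`, `resolution` (angstrom),
#'   `length` (residues), `keywords` (semicolon-separated string), `ec`
#'   (class name), optionally `expressible` (logical).
#' @param criteria list with elements `maxResolution` (default 3.0),
#'   `minLength` (200), `maxLength` (800), `keywords` (character vector, a
#'   record passes if any matches, case-insensitive; `NULL` disables),
#'   `ecClass` (string matched against `ec`, `NULL` disables),
#'   `maxIdentity` (default 0.95, used only with `identity`),
#'   `requireExpressible` (default `TRUE` when the column is present).
#' @param identity Optional symmetric pairwise fractional-identity matrix
#'   with dimnames = record ids. Greedy keep-first: records are scanned in
#'   input order and dropped if their identity to any already-kept record
#'   is `>= maxIdentity`.
#' @return Filtered `data.frame`; attribute `"log"` holds a `data.frame`
#'   (`id`, `reason`) for every rejected record.
#' @export
filterScaffoldLibrary <- function(records, criteria = list(), identity = NULL) {
  crit <- utils::modifyList(
    list(maxResolution = 3.0, minLength = 200, maxLength = 800,
         keywords = NULL, ecClass = NULL, maxIdentity = 0.95,
         requireExpressible = TRUE), criteria)
  if (nrow(records) == 0L) {
    attr(records, "log") <- data.frame(id = character(0), reason = character(0))
    return(records)
  }
  reasons <- rep(NA_character_, nrow(records))
  fail <- function(i, why) if (is.na(reasons[i])) reasons[i] <<- why
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (crit$requireExpressible && !is.null(records$expressible)) {
      if (is.na(r$expressible) || !isTRUE(r$expressible))
        fail(i, "not expressible")
    }
    if (is.na(r$resolution)) fail(i, "missing resolution")
    else if (r$resolution > crit$maxResolution)
      fail(i, sprintf("resolution %.2f > %.2f", r$resolution, crit$maxResolution))
    if (is.na(r$length)) fail(i, "missing length")
    else if (r$length < crit$minLength || r$length > crit$maxLength)
      fail(i, sprintf("length %d outside [%d, %d]", as.integer(r$length),
                      as.integer(crit$minLength), as.integer(crit$maxLength)))
    if (!is.null(crit$keywords)) {
      kw <- if (is.null(records$keywords) || is.na(r$keywords)) "" else r$keywords
      hit <- any(vapply(crit$keywords,
                        function(k) grepl(k, kw, ignore.case = TRUE),
                        logical(1)))
      if (!hit) fail(i, "no keyword match")
    }
    if (!is.null(crit$ecClass)) {
      ec <- if (is.null(records$ec) || is.na(r$ec)) "" else r$ec
      if (!grepl(crit$ecClass, ec, ignore.case = TRUE))
        fail(i, "enzyme class mismatch")
    }
  }
  if (!is.null(identity)) {
    kept_ids <- character(0)
    for (i in seq_len(nrow(records))) {
      if (!is.na(reasons[i])) next
      idv <- records$id[i]
      if (length(kept_ids) && idv %in% rownames(identity)) {
        prev <- intersect(kept_ids, colnames(identity))
        if (length(prev) && any(identity[idv, prev] >= crit$maxIdentity)) {
          fail(i, sprintf("identity >= %.0f%% with kept record",
                          100 * crit$maxIdentity))
          next
        }
      }
      kept_ids <- c(kept_ids, idv)
    }
  }
  out <- records[is.na(reasons), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "log") <- data.frame(id = records$id[!is.na(reasons)],
                                 reason = reasons[!is.na(reasons)],
                                 stringsAsFactors = FALSE)
  out
}

# coordinates of one residue as a named matrix (rownames = atom names)
.residueCoords <- function(x, chain, resno, insert = "") {
  a <- x@atoms
  sel <- a$chain == chain & a$resno == resno & a$insert == insert
  m <- as.matrix(a[sel, c("x", "y", "z")])
  rownames(m) <- a$elety[sel]
  m
}
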