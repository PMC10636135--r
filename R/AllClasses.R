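#' @include AllGenerics.R
NULL

# three-letter -> one-letter amino acid codes, standard 20 plus common His
# protonation variants
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  HID = "H", HIE = "H", HIP = "H", MSE = "M"
)
.AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN", E = "GLU",
  G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS", M = "MET", F = "PHE",
  P = "PRO", S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)
.BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' ProteinStructure: atoms and residues of a scaffold
#'
#' Holds the atoms of a protein scaffold as a flat table with residue
#' bookkeeping. Author residue numbering (`resno` plus insertion code) is
#' authoritative; a 0-based internal residue index is carried alongside in
#' [residueTable()]. Coordinates are in angstroms.
#'
#' @slot id Scaffold identifier.
#' @slot atoms `data.frame` with columns `chain`, `resno` (integer author
#'   numbering), `insert` (insertion code, `""` if none), `resid` (3-letter
#'   residue name), `elety` (atom name), `element`, `x`, `y`, `z`,
#'   `backbone` (logical), `het` (logical, non-amino-acid record).
#' @slot meta List of free-form provenance (e.g. `resolution`, `source`).
#' @export
setClass("ProteinStructure",
  representation(id = "character", atoms = "data.frame", meta = "list"),
  prototype(id = "unnamed", atoms = data.frame(), meta = list())
)

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "x", "y", "z", "backbone", "het")
  if (!all(need %in% names(a)))
    return(paste("atoms table missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) == 0L) return("structure has no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (any(!nzchar(a$elety))) return("empty atom names")
  TRUE
})

.residueKey <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
}

#' @describeIn ProteinStructure-class the raw atom table.
#' @param x,object A `ProteinStructure`.
#' @export
setMethod("atomTable", "ProteinStructure", function(x) x@atoms)

#' @describeIn ProteinStructure-class one row per residue with columns
#'   `index0` (0-based internal index), `chain`, `resno`, `insert`, `resid`,
#'   `aa` (one-letter, `X` for unknown hetero codes), `het`, `hasBackbone`.
#' @export
setMethod("residueTable", "ProteinStructure", function(x) {
  a <- x@atoms
  key <- .residueKey(a)
  first <- !duplicated(key)
  res <- a[first, c("chain", "resno", "insert", "resid", "het")]
  rownames(res) <- NULL
  res$aa <- unname(.AA3TO1[res$resid])
  res$aa[is.na(res$aa)] <- "X"
  hb <- vapply(split(a$elety[a$backbone], key[a$backbone])[unique(key)],
               function(e) all(.BACKBONE_ATOMS %in% e), logical(1))
  hb[is.na(hb)] <- FALSE
  res$hasBackbone <- unname(hb)
  res$index0 <- seq_len(nrow(res)) - 1L
  res[, c("index0", "chain", "resno", "insert", "resid", "aa", "het",
          "hasBackbone")]
})

#' @describeIn ProteinStructure-class number of residues.
#' @export
setMethod("nResidues", "ProteinStructure",
          function(x) sum(!duplicated(.residueKey(x@atoms))))

#' @describeIn ProteinStructure-class scaffold identifier.
#' @export
setMethod("structureId", "ProteinStructure", function(x) x@id)

setMethod("show", "ProteinStructure", function(object) {
  rt <- residueTable(object)
  cat("ProteinStructure '", object@id, "': ",
      nrow(rt), " residues, ", nrow(object@atoms), " atoms",
      if (sum(rt$het)) paste0(" (", sum(rt$het), " hetero)") else "",
      "\n", sep = "")
  if (!is.null(object@meta$resolution))
    cat("  resolution:", object@meta$resolution, "A\n")
})

#' TSMolecule: transition-state small molecule definition
#'
#' Atom names, elements, partial-charge-like weights, coordinates of a
#' reference conformation, bond list, the tetrahedral (attacked ester)
#' carbon and the rotatable torsions used for conformer enumeration.
#'
#' @slot atoms `data.frame` with columns `name`, `element`, `charge`,
#'   `x`, `y`, `z`.
#' @slot bonds character matrix, 2 columns of atom names.
#' @slot tetrahedralCenter name of the sp3 ester carbon.
#' @slot torsions list of character(4) atom-name tuples.
#' @export
setClass("TSMolecule",
  representation(atoms = "data.frame", bonds = "matrix",
                 tetrahedralCenter = "character", torsions = "list")
)

setValidity("TSMolecule", function(object) {
  a <- object@atoms
  need <- c("name", "element", "charge", "x", "y", "z")
  if (!all(need %in% names(a))) return("atoms table incomplete")
  if (anyDuplicated(a$name)) return("duplicate atom names")
  if (!all(object@bonds %in% a$name)) return("bond references unknown atom")
  nb <- sum(object@bonds == object@tetrahedralCenter)
  if (nb != 4L)
    return(sprintf("tetrahedral center '%s' has %d bonded neighbours, needs 4",
                   object@tetrahedralCenter, nb))
  # connectivity of the bond graph
  adj <- lapply(seq_len(nrow(a)), function(i) integer(0))
  names(adj) <- a$name
  for (k in seq_len(nrow(object@bonds))) {
    i <- object@bonds[k, 1L]; j <- object@bonds[k, 2L]
    adj[[i]] <- c(adj[[i]], match(j, a$name))
    adj[[j]] <- c(adj[[j]], match(i, a$name))
  }
  seen <- logical(nrow(a)); stack <- 1L; seen[1L] <- TRUE
  while (length(stack)) {
    i <- stack[[1L]]; stack <- stack[-1L]
    for (j in adj[[i]]) if (!seen[j]) { seen[j] <- TRUE; stack <- c(stack, j) }
  }
  if (!all(seen)) return("bond graph not connected")
  for (tor in object@torsions)
    if (length(tor) != 4L || !all(tor %in% a$name))
      return("torsion must name 4 known atoms")
  TRUE
})

#' @describeIn TSMolecule-class reference coordinates as a named matrix.
#' @param x,object A `TSMolecule`.
#' @export
setMethod("tsPose", "TSMolecule", function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  rownames(m) <- x@atoms$name
  m
})

setMethod("show", "TSMolecule", function(object) {
  cat("TSMolecule: ", nrow(object@atoms), " atoms, ",
      nrow(object@bonds), " bonds, tetrahedral center ",
      object@tetrahedralCenter, ", ", length(object@torsions),
      " rotatable torsions\n", sep = "")
})

#' ActiveSiteModel: catalytic roles plus the geometric constraint table
#'
#' Declares the catalytic machinery of the target reaction (for the shipped
#' default: serine-hydrolase MHET hydrolysis -- nucleophile Ser, base His,
#' acid Asp/Glu, two backbone-NH oxyanion donors and a carboxylate-binding
#' Ser) and the table of distance/angle constraints between catalytic atoms
#' and transition-state atoms used for matching and penalty scoring.
#'
#' @slot roles list; each element a list with `roleId`, `allowedAa`
#'   (one-letter codes), `anchorAtoms` (named list: aa -> atom names used in
#'   constraints; name `"*"` applies to all allowed aa).
#' @slot constraints list; each element a list with `id`, `kind`
#'   (`distance`/`angle`/`dihedral`), `atoms` (list of `c(ref, atomName)`
#'   where ref is a roleId or `"TS"`), `target`, `lo`, `hi`, `weight`.
#' @slot ts A [TSMolecule-class].
#' @slot tsAliases named list: alias -> candidate TS atom names (an aliased
#'   constraint atom resolves to whichever candidate scores best).
#' @export
setClass("ActiveSiteModel",
  representation(roles = "list", constraints = "list", ts = "TSMolecule",
                 tsAliases = "list"),
  prototype(tsAliases = list())
)

setValidity("ActiveSiteModel", function(object) {
  ids <- vapply(object@roles, `[[`, character(1), "roleId")
  if (anyDuplicated(ids)) return("duplicate role ids")
  for (r in object@roles) {
    if (!length(r$allowedAa)) return(paste0("role ", r$roleId, ": allowedAa empty"))
  }
  for (con in object@constraints) {
    if (!con$kind %in% c("distance", "angle", "dihedral"))
      return(paste0("constraint ", con$id, ": bad kind"))
    nat <- c(distance = 2L, angle = 3L, dihedral = 4L)[[con$kind]]
    if (length(con$atoms) != nat)
      return(paste0("constraint ", con$id, ": needs ", nat, " atoms"))
    for (at in con$atoms) {
      ref <- at[[1L]]
      if (ref != "TS" && !ref %in% ids)
        return(paste0("constraint ", con$id, ": unknown role '", ref, "'"))
      if (ref == "TS" &&
          !at[[2L]] %in% c(object@ts@atoms$name, names(object@tsAliases)))
        return(paste0("constraint ", con$id, ": unknown TS atom '", at[[2L]], "'"))
    }
    if (!(con$lo <= con$target && con$target <= con$hi))
      return(paste0("constraint ", con$id, ": require lo <= target <= hi"))
    if (con$weight < 0) return(paste0("constraint ", con$id, ": negative weight"))
  }
  TRUE
})

setMethod("show", "ActiveSiteModel", function(object) {
  cat("ActiveSiteModel: ", length(object@roles), " catalytic roles, ",
      length(object@constraints), " geometric constraints\n", sep = "")
  for (r in object@roles)
    cat("  ", r$roleId, " [", paste(r$allowedAa, collapse = ""), "]\n", sep = "")
})

#' MatchResult: an active-site model anchored in a scaffold
#'
#' @slot scaffoldId Scaffold identifier.
#' @slot assignment `data.frame` with columns `role`, `chain`, `resno`,
#'   `insert`, `aa`.
#' @slot placedAtoms named list role -> matrix of anchor-atom coordinates
#'   (rownames = atom names).
#' @slot pose Optimized TS coordinates (rownames = TS atom names).
#' @slot penalty Total constraint penalty (>= 0).
#' @slot breakdown per-constraint `data.frame` (`id`, `measured`, `excess`,
#'   `penalty`).
#' @slot triadRmsd RMSD of placed catalytic side chains vs the native
#'   conformations, `NA_real_` until computed.
#' @export
setClass("MatchResult",
  representation(scaffoldId = "character", assignment = "data.frame",
                 placedAtoms = "list", pose = "matrix", penalty = "numeric",
                 breakdown = "data.frame", triadRmsd = "numeric"),
  prototype(triadRmsd = NA_real_)
)

setValidity("MatchResult", function(object) {
  if (length(object@penalty) != 1L || object@penalty < 0)
    return("penalty must be a single non-negative number")
  key <- paste(object@assignment$chain, object@assignment$resno,
               object@assignment$insert)
  # oxyanion donors may share a residue with nothing else; assignment must be
  # injective over positions
  if (anyDuplicated(key)) return("role assignment not injective over positions")
  TRUE
})

#' @describeIn MatchResult-class total constraint penalty.
#' @param x,object A `MatchResult`.
#' @export
setMethod("penaltyScore", "MatchResult", function(x) x@penalty)

#' @describeIn MatchResult-class role-to-position table.
#' @export
setMethod("roleAssignment", "MatchResult", function(x) x@assignment)

#' @describeIn MatchResult-class optimized TS coordinates.
#' @export
setMethod("tsPose", "MatchResult", function(x) x@pose)

setMethod("show", "MatchResult", function(object) {
  cat("MatchResult in '", object@scaffoldId, "' penalty ",
      format(object@penalty, digits = 4), "\n", sep = "")
  a <- object@assignment
  cat(paste0("  ", a$role, " -> ", a$chain, a$resno, " (", a$aa, ")",
             collapse = "\n"), "\n")
})

#' TSConformerLibrary: retained transition-state poses
#'
#' @slot conformers list of coordinate matrices (rownames = TS atom names).
#' @slot torsions numeric matrix, one row per conformer (degrees).
#' @slot penalty numeric vector of constraint penalties.
#' @slot clash numeric vector of clash scores (overlap count).
#' @slot provenance list: generation parameters incl. `seed`.
#' @slot diagnostics named integer vector: poses rejected per rule.
#' @export
setClass("TSConformerLibrary",
  representation(conformers = "list", torsions = "matrix",
                 penalty = "numeric", clash = "numeric",
                 provenance = "list", diagnostics = "integer")
)

#' @describeIn TSConformerLibrary-class number of retained conformers.
#' @param x,object A `TSConformerLibrary`.
#' @export
setMethod("conformerCount", "TSConformerLibrary",
          function(x) length(x@conformers))

setMethod("show", "TSConformerLibrary", function(object) {
  cat("TSConformerLibrary: ", length(object@conformers),
      " conformers retained\n", sep = "")
  if (length(object@diagnostics))
    cat("  rejected:", paste(names(object@diagnostics), object@diagnostics,
                             sep = "=", collapse = ", "), "\n")
})

#' FrameSet: trajectory snapshots with catalytic-atom labelling
#'
#' @slot designId,replicateId identifiers.
#' @slot frames list of n_atoms x 3 coordinate matrices.
#' @slot atomInfo `data.frame` describing the shared atom roster (`chain`,
#'   `resno`, `resid`, `elety`, `element`, `backbone`, `isTS`).
#' @slot labels named integer vector of atom-row indices for the catalytic
#'   atoms: `serOG`, `tsC`, `tsOxy`, `donor1N`, `donor1H`, `donor2N`,
#'   `donor2H` (H entries may be `NA`; an idealized H is constructed).
#' @slot frameIntervalPs time between frames, picoseconds.
#' @export
setClass("FrameSet",
  representation(designId = "character", replicateId = "character",
                 frames = "list", atomInfo = "data.frame",
                 labels = "integer", frameIntervalPs = "numeric"),
  prototype(frameIntervalPs = 10)
)

setValidity("FrameSet", function(object) {
  if (length(object@frames) < 2L) return("need at least 2 frames")
  na <- nrow(object@atomInfo)
  for (f in object@frames)
    if (!is.matrix(f) || nrow(f) != na || ncol(f) != 3L)
      return("all frames must share the atom roster (n_atoms x 3)")
  need <- c("serOG", "tsC", "tsOxy", "donor1N", "donor2N")
  if (!all(need %in% names(object@labels)))
    return(paste("labels missing:",
                 paste(setdiff(need, names(object@labels)), collapse = ", ")))
  idx <- object@labels[need]
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > na))
    return("required catalytic-atom labels must be valid atom indices")
  TRUE
})

#' @describeIn FrameSet-class number of frames.
#' @param x,object A `FrameSet`.
#' @export
setMethod("nFrames", "FrameSet", function(x) length(x@frames))

setMethod("show", "FrameSet", function(object) {
  cat("FrameSet '", object@designId, "' replicate '", object@replicateId,
      "': ", length(object@frames), " frames x ", nrow(object@atomInfo),
      " atoms, dt = ", object@frameIntervalPs, " ps\n", sep = "")
})

#' CatalyticIndicatorSet: the four per-design screening statistics
#'
#' Fractions over all frames of: transition-state RMSD below the cutoff
#' (reference = first frame, after backbone superposition), nucleophilic
#' attack distance below the cutoff, and each of the two oxyanion-hole
#' hydrogen bonds being formed. `attackDistMean` is diagnostic only.
#'
#' @slot designId identifier.
#' @slot freqRmsdTs,attackFrac3A,hbondFreq1,hbondFreq2 fractions in \[0, 1\].
#' @slot attackDistMean mean Ser Ogamma -- ester C distance (angstrom).
#' @slot nFramesTotal frames aggregated.
#' @export
setClass("CatalyticIndicatorSet",
  representation(designId = "character", freqRmsdTs = "numeric",
                 attackDistMean = "numeric", attackFrac3A = "numeric",
                 hbondFreq1 = "numeric", hbondFreq2 = "numeric",
                 nFramesTotal = "integer")
)

setValidity("CatalyticIndicatorSet", function(object) {
  fr <- c(object@freqRmsdTs, object@attackFrac3A,
          object@hbondFreq1, object@hbondFreq2)
  if (any(fr < 0 | fr > 1)) return("indicator fractions must lie in [0, 1]")
  if (object@nFramesTotal < 1L) return("nFramesTotal must be >= 1")
  TRUE
})

#' @describeIn CatalyticIndicatorSet-class the four screening indicators as
#'   a named numeric vector (`freqRmsdTs`, `attackFrac3A`, `hbondFreq1`,
#'   `hbondFreq2`).
#' @param x,object A `CatalyticIndicatorSet`.
#' @export
setMethod("indicatorVector", "CatalyticIndicatorSet", function(x) {
  c(freqRmsdTs = x@freqRmsdTs, attackFrac3A = x@attackFrac3A,
    hbondFreq1 = x@hbondFreq1, hbondFreq2 = x@hbondFreq2)
})

setMethod("show", "CatalyticIndicatorSet", function(object) {
  v <- indicatorVector(object)
  cat("CatalyticIndicatorSet '", object@designId, "' (",
      object@nFramesTotal, " frames)\n", sep = "")
  cat(sprintf("  freq(RMSD_TS < cut) = %.3f  attack frac = %.3f  (mean %.2f A)\n",
              v[["freqRmsdTs"]], v[["attackFrac3A"]], object@attackDistMean))
  cat(sprintf("  oxyanion H-bond freqs = %.3f / %.3f\n",
              v[["hbondFreq1"]], v[["hbondFreq2"]]))
})
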