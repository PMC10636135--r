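#' @include sidechain.R structio.R geometry.R
NULL

#' Define a redesign problem
#'
#' Declares which scaffold positions may change amino-acid type (mutable),
#' which keep their type but repack their side chain, and (implicitly)
#' that everything else stays rigid. The shipped example scheme for the
#' Est30 scaffold varies 8 positions among 16 amino-acid types while 18
#' further positions (including the catalytic residues) repack.
#'
#' @param mutable List of `list(chain, resno, insert = "", allowed)` where
#'   `allowed` is a character vector of one-letter codes.
#' @param repack List of `list(chain, resno, insert = "")` positions.
#' @param x The scaffold [ProteinStructure-class].
#' @return A `DesignSpec` list with a resolved position table.
#' @export
designSpec <- function(mutable, repack = list(), x) {
  rt <- residueTable(x)
  resolve <- function(p, type, allowed = NULL) {
    ins <- if (is.null(p$insert)) "" else p$insert
    row <- rt[rt$chain == p$chain & rt$resno == p$resno & rt$insert == ins, ]
    if (nrow(row) != 1L)
      stop("position ", p$chain, p$resno, ins, " not found in structure")
    data.frame(chain = p$chain, resno = p$resno, insert = ins,
               nativeAa = row$aa, type = type,
               allowed = I(list(if (is.null(allowed)) row$aa else allowed)),
               stringsAsFactors = FALSE)
  }
  pos <- rbind(
    do.call(rbind, lapply(mutable, function(p) resolve(p, "mutable", p$allowed))),
    if (length(repack)) do.call(rbind, lapply(repack, resolve, type = "repack")))
  key <- paste(pos$chain, pos$resno, pos$insert)
  if (anyDuplicated(key)) stop("mutable and repack position sets overlap")
  bad <- setdiff(unique(unlist(pos$allowed)), names(.AA1TO3))
  if (length(bad)) stop("unknown amino acids in allowed sets: ",
                        paste(bad, collapse = ", "))
  structure(list(positions = pos, structureId = x@id), class = "DesignSpec")
}

#' Build the design rotamer library
#'
#' For every design position and allowed amino acid, side-chain rotamers
#' are built on the position's native backbone from a backbone-independent
#' chi-angle table (the shipped coarse table by default). The crystal
#' (native) side-chain conformation is appended for the position's native
#' amino acid -- also when that type is not in the allowed set, flagged
#' `wtOnly` so it serves only as the wild-type reference. Ser/Thr/Tyr
#' entries are expanded over the hydroxyl-hydrogen dihedral grid
#' (default 60/180/-60 degrees). Gly and Ala get a single (null) rotamer.
#'
#' @param spec A [designSpec()].
#' @param x The scaffold [ProteinStructure-class].
#' @param baseLibrary `data.frame` with columns `aa`, `chi1`..`chi4`
#'   (degrees, NA where undefined); default: shipped table.
#' @param hydroxylGrid Hydroxyl-H dihedrals for S/T/Y expansion.
#' @return A `RotamerLibrary`: list with `positions` (the resolved
#'   position table) and
#'   `rotamers`, a list (per position) of lists with fields `aa`, `chi`,
#'   `source` (`"lib"`/`"crystal"`), `wtOnly`, `coords` (matrix incl. CB
#'   and any hydroxyl H).
#' @export
buildRotamerLibrary <- function(spec, x,
                                baseLibrary = NULL,
                                hydroxylGrid = c(60, 180, -60)) {
  if (is.null(baseLibrary)) {
    baseLibrary <- utils::read.csv(
      system.file("extdata", "rotamers_bbindep.csv", package = "enzdes"),
      stringsAsFactors = FALSE)
  }
  pos <- spec$positions
  rotamers <- vector("list", nrow(pos))
  for (i in seq_len(nrow(pos))) {
    bb <- .residueCoords(x, pos$chain[i], pos$resno[i], pos$insert[i])
    if (!all(c("N", "CA", "C") %in% rownames(bb)))
      stop("position ", pos$chain[i], pos$resno[i], ": incomplete backbone")
    aaSet <- unique(c(pos$allowed[[i]], pos$nativeAa[i]))
    out <- list()
    for (aa in aaSet) {
      wtOnly <- !(aa %in% pos$allowed[[i]])
      isNative <- aa == pos$nativeAa[i]
      hGrid <- if (aa %in% c("S", "T", "Y")) hydroxylGrid else NA
      if (aa %in% c("G", "A")) {
        coords <- if (aa == "A") buildSideChain("A", bb) else
          matrix(numeric(0), 0L, 3L)
        out[[length(out) + 1L]] <- list(aa = aa, chi = numeric(0),
                                        source = "lib", wtOnly = wtOnly,
                                        coords = coords)
      } else {
        rows <- baseLibrary[baseLibrary$aa == aa, , drop = FALSE]
        if (nrow(rows) == 0L)
          stop("no base-library rotamers for amino acid '", aa, "'")
        nchi <- chiCount(aa)
        for (k in seq_len(nrow(rows))) {
          chi <- as.numeric(rows[k, paste0("chi", seq_len(nchi))])
          for (h in hGrid) {
            coords <- buildSideChain(aa, bb, chi, hydroxylH = h)
            out[[length(out) + 1L]] <- list(aa = aa, chi = chi,
                                            source = "lib", wtOnly = wtOnly,
                                            coords = coords)
          }
        }
      }
      if (isNative && !aa %in% c("G", "A")) {
        nat <- .residueCoords(x, pos$chain[i], pos$resno[i], pos$insert[i])
        sc <- nat[!(rownames(nat) %in% c("N", "CA", "C", "O")), ,
                  drop = FALSE]
        if (nrow(sc)) {
          for (h in hGrid) {
            coords <- sc
            if (!is.na(h) && aa %in% names(.HYDROXYL_H)) {
              hs <- .HYDROXYL_H[[aa]]
              refs <- hs[[2L]]
              allc <- rbind(nat[intersect(c("N", "CA", "C"), rownames(nat)), ,
                                drop = FALSE], sc)
              if (all(refs %in% rownames(allc))) {
                hp <- .nerf(allc[refs[1L], ], allc[refs[2L], ],
                            allc[refs[3L], ], hs[[3L]], hs[[4L]], h)
                coords <- rbind(coords, matrix(hp, 1L, 3L,
                                               dimnames = list(hs[[1L]], NULL)))
              }
            }
            out[[length(out) + 1L]] <- list(aa = aa, chi = NA_real_,
                                            source = "crystal",
                                            wtOnly = wtOnly, coords = coords)
          }
        }
      }
    }
    rotamers[[i]] <- out
  }
  structure(list(positions = pos, rotamers = rotamers),
            class = "RotamerLibrary")
}

#' Control parameters of the packing energy model
#'
#' A deliberately simple, fully documented decomposable energy: 12-6
#' Lennard-Jones (`4 eps ((sigma/r)^12 - (sigma/r)^6)`, per-pair sigma =
#' arithmetic mean of per-element diameters, repulsion capped at
#' `clashCap`), screened Coulomb with distance-dependent dielectric
#' (`k q_i q_j / (dielectricFactor r^2)`), a geometric hydrogen-bond bonus
#' applied once per donor/acceptor pair satisfying [isHydrogenBond()], and
#' an optional per-amino-acid reference energy.
#'
#' @param ljEps Named per-element well depths (kcal/mol).
#' @param ljSigma Named per-element diameters (angstrom).
#' @param coulombK Electrostatic constant (kcal mol-1 A e-2).
#' @param dielectricFactor Epsilon = factor * r.
#' @param hbondBonus Bonus per satisfied H-bond (kcal/mol, negative).
#' @param hbond An [hbondCriteria()] object.
#' @param clashCap Pairwise repulsion cap (kcal/mol).
#' @param refEnergies Named per-aa reference energies (default all zero).
#' @param pairCutoff Skip position pairs with CB-CB distance above this.
#' @return List of energy-model settings.
#' @export
energyModelControl <- function(ljEps = c(C = 0.07, N = 0.17, O = 0.16,
                                         S = 0.25, H = 0.03),
                               ljSigma = c(C = 3.40, N = 3.10, O = 3.04,
                                           S = 3.60, H = 2.20),
                               coulombK = 332.0637, dielectricFactor = 4,
                               hbondBonus = -2.0, hbond = hbondCriteria(),
                               clashCap = 50,
                               refEnergies = stats::setNames(
                                 rep(0, 20), names(.AA1TO3)),
                               pairCutoff = 12) {
  list(ljEps = ljEps, ljSigma = ljSigma, coulombK = coulombK,
       dielectricFactor = dielectricFactor, hbondBonus = hbondBonus,
       hbond = hbond, clashCap = clashCap, refEnergies = refEnergies,
       pairCutoff = pairCutoff)
}

# crude per-atom partial charges for protein atoms (element-based with a
# few name overrides); TS atoms carry their own charge-like weights
.atomCharge <- function(elety, element) {
  q <- c(C = 0.0, N = 0.25, O = -0.40, S = -0.10, H = 0.10)[
    toupper(substr(element, 1L, 1L))]
  q[is.na(q)] <- 0
  q[elety %in% c("OD1", "OD2", "OE1", "OE2")] <- -0.55
  q[elety == "NZ"] <- 0.45
  q[elety %in% c("NH1", "NH2", "NE")] <- 0.35
  q[elety %in% c("HG", "HG1", "HH")] <- 0.35
  unname(q)
}

# pairwise nonbonded energy between coordinate/metadata blocks a and b
.nbEnergy <- function(ax, ae, aq, bx, be, bq, ctl) {
  if (nrow(ax) == 0L || nrow(bx) == 0L) return(0)
  total <- 0
  sigA <- ctl$ljSigma[toupper(substr(ae, 1L, 1L))]
  sigA[is.na(sigA)] <- 3.4
  epsA <- ctl$ljEps[toupper(substr(ae, 1L, 1L))]
  epsA[is.na(epsA)] <- 0.07
  sigB <- ctl$ljSigma[toupper(substr(be, 1L, 1L))]
  sigB[is.na(sigB)] <- 3.4
  epsB <- ctl$ljEps[toupper(substr(be, 1L, 1L))]
  epsB[is.na(epsB)] <- 0.07
  for (i in seq_len(nrow(ax))) {
    d2 <- rowSums(sweep(bx, 2L, ax[i, ])^2)
    d2 <- pmax(d2, 0.01)
    sig <- (sigA[i] + sigB) / 2
    eps <- sqrt(epsA[i] * epsB)
    sr6 <- (sig * sig / d2)^3
    lj <- pmin(4 * eps * (sr6 * sr6 - sr6), ctl$clashCap)
    coul <- ctl$coulombK * aq[i] * bq / (ctl$dielectricFactor * d2)
    total <- total + sum(lj + coul)
  }
  total
}

setClass("EnergyTables",
  representation(positions = "data.frame", rotamers = "list",
                 singlesTmpl = "list", singlesTS = "list",
                 pairs = "list", control = "list"))

setValidity("EnergyTables", function(object) {
  n <- nrow(object@positions)
  if (length(object@rotamers) != n) return("rotamers/positions mismatch")
  for (i in seq_len(n)) {
    if (length(object@singlesTmpl[[i]]) != length(object@rotamers[[i]]))
      return("singles length mismatch")
    if (!all(is.finite(object@singlesTmpl[[i]])))
      return("non-finite template singles")
  }
  TRUE
})

setMethod("show", "EnergyTables", function(object) {
  nr <- vapply(object@rotamers, length, integer(1))
  cat("EnergyTables: ", nrow(object@positions), " design positions, ",
      sum(nr), " rotamers (", paste(nr, collapse = "/"), ")\n", sep = "")
})

#' Pairwise rotamer-rotamer energy lookup
#'
#' @param tables An `EnergyTables` object.
#' @param i,j Position indices.
#' @param ri,rj Rotamer indices at those positions.
#' @return Symmetric pair energy in kcal/mol (0 for `i == j`).
#' @export
pairEnergy <- function(tables, i, ri, j, rj) {
  if (i == j) return(0)
  if (i > j) { tmp <- i; i <- j; j <- tmp; tmp <- ri; ri <- rj; rj <- tmp }
  m <- tables@pairs[[paste(i, j)]]
  if (is.null(m)) return(0)
  m[ri, rj]
}

#' Compute singles and pairwise energy tables for a design problem
#'
#' Rotamer-template singles cover each rotamer against all rigid scaffold
#' atoms (the design positions' own side chains removed; a rotamer's own
#' residue and its two peptide neighbours are excluded from its
#' non-bonded sums). Rotamer-TS singles are kept separately so the
#' unbound (apo) state is obtained by simply dropping them. Hydrogen-bond
#' bonuses are added once per donor/acceptor pair passing the geometric
#' test, with idealized polar hydrogens where explicit ones are absent.
#'
#' @param x Scaffold [ProteinStructure-class].
#' @param library A [buildRotamerLibrary()] result.
#' @param ts TS pose matrix (rownames = atom names) with attribute-free
#'   coordinates, or a [TSConformerLibrary-class] (its lowest-penalty
#'   conformer is used), or `NULL` for an apo-only table.
#' @param tsCharges Named charge vector for TS atoms (default: taken from
#'   `model`).
#' @param model Optional [ActiveSiteModel-class] supplying TS atom
#'   elements/charges.
#' @param control [energyModelControl()] settings.
#' @return An `EnergyTables` S4 object.
#' @export
computeEnergyTables <- function(x, library, ts = NULL, tsCharges = NULL,
                                model = NULL,
                                control = energyModelControl()) {
  pos <- library$positions
  n <- nrow(pos)
  posKey <- paste(pos$chain, pos$resno, pos$insert)
  a <- x@atoms
  akey <- .residueKey(a)
  # template: everything except design-position side chains
  scMask <- akey %in% posKey & !(a$elety %in% c("N", "CA", "C", "O"))
  tmpl <- a[!scMask, , drop = FALSE]
  tmplKey <- akey[!scMask]
  tmplXyz <- as.matrix(tmpl[, c("x", "y", "z")])
  tmplQ <- .atomCharge(tmpl$elety, tmpl$element)

  if (is(ts, "TSConformerLibrary"))
    ts <- if (conformerCount(ts)) ts@conformers[[which.min(ts@penalty)]] else NULL
  tsQ <- NULL; tsE <- NULL
  if (!is.null(ts)) {
    if (!is.null(model)) {
      tsQ <- stats::setNames(model@ts@atoms$charge, model@ts@atoms$name)[rownames(ts)]
      tsE <- stats::setNames(model@ts@atoms$element, model@ts@atoms$name)[rownames(ts)]
    } else {
      tsQ <- if (is.null(tsCharges)) rep(0, nrow(ts)) else tsCharges[rownames(ts)]
      tsE <- substr(rownames(ts), 1L, 1L)
    }
  }

  # neighbour keys (same residue + peptide neighbours) excluded per position
  rt <- residueTable(x)
  rtKey <- paste(rt$chain, rt$resno, rt$insert)
  exclKeys <- lapply(seq_len(n), function(i) {
    idx <- match(posKey[i], rtKey)
    k <- rtKey[max(1L, idx - 1L):min(nrow(rt), idx + 1L)]
    k
  })

  hbPairsOnce <- function(coords, aa, tsM) {
    # donor atoms on the rotamer vs acceptor O on the TS; returns bonus sum
    if (is.null(tsM)) return(0)
    acc <- rownames(tsM)[tsE == "O" & tsQ < 0]
    if (!length(acc)) return(0)
    bonus <- 0
    hn <- intersect(rownames(coords), c("HG", "HG1", "HH"))
    donors <- list()
    if (length(hn)) {
      dAtom <- c(HG = "OG", HG1 = "OG1", HH = "OH")[hn]
      for (k in seq_along(hn))
        donors[[length(donors) + 1L]] <- list(d = coords[dAtom[k], ],
                                              h = coords[hn[k], ])
    }
    nDon <- intersect(rownames(coords),
                      c("NZ", "NE", "NH1", "NH2", "ND2", "NE2", "ND1", "NE1"))
    for (nm in nDon) {
      nbrs <- coords[setdiff(rownames(coords), nm), , drop = FALSE]
      if (!nrow(nbrs)) next
      d2 <- rowSums(sweep(nbrs, 2L, coords[nm, ])^2)
      nb <- nbrs[d2 < 1.8^2, , drop = FALSE]
      if (!nrow(nb)) next
      donors[[length(donors) + 1L]] <-
        list(d = coords[nm, ], h = idealPolarHydrogen(coords[nm, ], nb))
    }
    for (don in donors) {
      for (an in acc) {
        hb <- isHydrogenBond(don$d, don$h, tsM[an, ], control$hbond)
        if (hb$bonded) bonus <- bonus + control$hbondBonus
      }
    }
    bonus
  }

  singlesTmpl <- vector("list", n)
  singlesTS <- vector("list", n)
  for (i in seq_len(n)) {
    rots <- library$rotamers[[i]]
    keep <- !(tmplKey %in% exclKeys[[i]])
    bx <- tmplXyz[keep, , drop = FALSE]
    be <- tmpl$element[keep]
    bq <- tmplQ[keep]
    eT <- eS <- numeric(length(rots))
    for (r in seq_along(rots)) {
      co <- rots[[r]]$coords
      refE <- control$refEnergies[rots[[r]]$aa]
      if (is.na(refE)) refE <- 0
      if (nrow(co) == 0L) {
        eT[r] <- refE
        next
      }
      eT[r] <- .nbEnergy(co, substr(rownames(co), 1L, 1L),
                         .atomCharge(rownames(co), substr(rownames(co), 1L, 1L)),
                         bx, be, bq, control) + refE
      if (!is.null(ts)) {
        eS[r] <- .nbEnergy(co, substr(rownames(co), 1L, 1L),
                           .atomCharge(rownames(co), substr(rownames(co), 1L, 1L)),
                           ts, tsE, tsQ, control) +
                 hbPairsOnce(co, rots[[r]]$aa, ts)
      }
    }
    singlesTmpl[[i]] <- eT
    singlesTS[[i]] <- eS
  }

  # pairs for positions within the CB cutoff
  caOf <- function(i) {
    rc <- .residueCoords(x, pos$chain[i], pos$resno[i], pos$insert[i])
    rc["CA", ]
  }
  cas <- t(vapply(seq_len(n), caOf, numeric(3)))
  pairs <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (.vdist(cas[i, ], cas[j, ]) > control$pairCutoff) next
        ri <- library$rotamers[[i]]
        rj <- library$rotamers[[j]]
        m <- matrix(0, length(ri), length(rj))
        for (u in seq_along(ri)) {
          cu <- ri[[u]]$coords
          if (nrow(cu) == 0L) next
          eu <- substr(rownames(cu), 1L, 1L)
          qu <- .atomCharge(rownames(cu), eu)
          for (v in seq_along(rj)) {
            cv <- rj[[v]]$coords
            if (nrow(cv) == 0L) next
            m[u, v] <- .nbEnergy(cu, eu, qu, cv,
                                 substr(rownames(cv), 1L, 1L),
                                 .atomCharge(rownames(cv),
                                             substr(rownames(cv), 1L, 1L)),
                                 control)
          }
        }
        pairs[[paste(i, j)]] <- m
      }
    }
  }
  new("EnergyTables", positions = pos, rotamers = library$rotamers,
      singlesTmpl = singlesTmpl, singlesTS = singlesTS, pairs = pairs,
      control = control)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
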