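#' @include geometry.R
NULL

# NeRF (natural extension reference frame): place atom D given three placed
# atoms A, B, C with bond length |C-D|, bond angle B-C-D (deg) and dihedral
# A-B-C-D (deg, IUPAC sign convention matching measureGeometry).
.nerf <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- .vcross(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9) stop("collinear reference atoms in NeRF placement")
  n <- n / nn
  m <- .vcross(n, bc)
  C + (-r * cos(th)) * bc + (r * sin(th) * cos(ph)) * m +
    (r * sin(th) * sin(ph)) * n
}

# Side-chain topology per amino acid: each atom placed by NeRF from three
# previously placed atoms. dihedral spec: chiK (the K-th chi angle), a
# number (fixed), or "chiK+offset". Bond lengths/angles follow standard
# ideal amino-acid geometry (Engh & Huber-like values).
# CB is placed from (N, C, CA) with fixed dihedral -122.6 deg (L-chirality).
.SC_TOPO <- list(
  G = list(),
  A = list(),
  S = list(list("OG",  c("N","CA","CB"),  1.417, 110.8, "chi1")),
  C = list(list("SG",  c("N","CA","CB"),  1.808, 113.8, "chi1")),
  T = list(list("OG1", c("N","CA","CB"),  1.433, 109.6, "chi1"),
           list("CG2", c("N","CA","CB"),  1.521, 110.5, "chi1-122")),
  V = list(list("CG1", c("N","CA","CB"),  1.521, 110.5, "chi1"),
           list("CG2", c("N","CA","CB"),  1.521, 110.5, "chi1+122")),
  I = list(list("CG1", c("N","CA","CB"),  1.530, 110.4, "chi1"),
           list("CG2", c("N","CA","CB"),  1.521, 110.5, "chi1-122"),
           list("CD1", c("CA","CB","CG1"),1.513, 113.8, "chi2")),
  L = list(list("CG",  c("N","CA","CB"),  1.530, 116.3, "chi1"),
           list("CD1", c("CA","CB","CG"), 1.521, 110.7, "chi2"),
           list("CD2", c("CA","CB","CG"), 1.521, 110.7, "chi2+122")),
  M = list(list("CG",  c("N","CA","CB"),  1.520, 114.1, "chi1"),
           list("SD",  c("CA","CB","CG"), 1.803, 112.7, "chi2"),
           list("CE",  c("CB","CG","SD"), 1.791, 100.9, "chi3")),
  F = list(list("CG",  c("N","CA","CB"),  1.502, 113.8, "chi1"),
           list("CD1", c("CA","CB","CG"), 1.384, 120.8, "chi2"),
           list("CD2", c("CA","CB","CG"), 1.384, 120.8, "chi2+180"),
           list("CE1", c("CB","CG","CD1"),1.382, 121.0, 180),
           list("CE2", c("CB","CG","CD2"),1.382, 121.0, 180),
           list("CZ",  c("CG","CD1","CE1"),1.382, 120.0, 0)),
  Y = list(list("CG",  c("N","CA","CB"),  1.502, 113.8, "chi1"),
           list("CD1", c("CA","CB","CG"), 1.384, 120.8, "chi2"),
           list("CD2", c("CA","CB","CG"), 1.384, 120.8, "chi2+180"),
           list("CE1", c("CB","CG","CD1"),1.382, 121.0, 180),
           list("CE2", c("CB","CG","CD2"),1.382, 121.0, 180),
           list("CZ",  c("CG","CD1","CE1"),1.382, 120.0, 0),
           list("OH",  c("CD1","CE1","CZ"),1.376, 119.9, 180)),
  W = list(list("CG",  c("N","CA","CB"),  1.498, 113.6, "chi1"),
           list("CD1", c("CA","CB","CG"), 1.365, 126.9, "chi2"),
           list("CD2", c("CA","CB","CG"), 1.433, 126.7, "chi2+180"),
           list("NE1", c("CB","CG","CD1"),1.374, 110.2, 180),
           list("CE2", c("CG","CD1","NE1"),1.409, 109.0, 0),
           list("CE3", c("CB","CG","CD2"),1.398, 133.9, 180),
           list("CZ2", c("CG","CD2","CE2"),1.394, 122.4, 180),
           list("CZ3", c("CG","CD2","CE3"),1.382, 118.6, 180),
           list("CH2", c("CD2","CE3","CZ3"),1.368, 121.1, 0)),
  D = list(list("CG",  c("N","CA","CB"),  1.516, 113.1, "chi1"),
           list("OD1", c("CA","CB","CG"), 1.249, 118.4, "chi2"),
           list("OD2", c("CA","CB","CG"), 1.249, 118.4, "chi2+180")),
  N = list(list("CG",  c("N","CA","CB"),  1.516, 113.1, "chi1"),
           list("OD1", c("CA","CB","CG"), 1.231, 120.8, "chi2"),
           list("ND2", c("CA","CB","CG"), 1.328, 116.4, "chi2+180")),
  E = list(list("CG",  c("N","CA","CB"),  1.520, 114.1, "chi1"),
           list("CD",  c("CA","CB","CG"), 1.516, 112.6, "chi2"),
           list("OE1", c("CB","CG","CD"), 1.249, 118.4, "chi3"),
           list("OE2", c("CB","CG","CD"), 1.249, 118.4, "chi3+180")),
  Q = list(list("CG",  c("N","CA","CB"),  1.520, 114.1, "chi1"),
           list("CD",  c("CA","CB","CG"), 1.516, 112.6, "chi2"),
           list("OE1", c("CB","CG","CD"), 1.231, 120.8, "chi3"),
           list("NE2", c("CB","CG","CD"), 1.328, 116.4, "chi3+180")),
  K = list(list("CG",  c("N","CA","CB"),  1.520, 114.1, "chi1"),
           list("CD",  c("CA","CB","CG"), 1.520, 111.3, "chi2"),
           list("CE",  c("CB","CG","CD"), 1.508, 111.3, "chi3"),
           list("NZ",  c("CG","CD","CE"), 1.489, 111.9, "chi4")),
  R = list(list("CG",  c("N","CA","CB"),  1.520, 114.1, "chi1"),
           list("CD",  c("CA","CB","CG"), 1.520, 111.3, "chi2"),
           list("NE",  c("CB","CG","CD"), 1.461, 112.0, "chi3"),
           list("CZ",  c("CG","CD","NE"), 1.329, 124.2, "chi4"),
           list("NH1", c("CD","NE","CZ"), 1.326, 120.0, 0),
           list("NH2", c("CD","NE","CZ"), 1.326, 120.0, 180)),
  H = list(list("CG",  c("N","CA","CB"),  1.497, 113.8, "chi1"),
           list("ND1", c("CA","CB","CG"), 1.371, 122.7, "chi2"),
           list("CD2", c("CA","CB","CG"), 1.356, 131.2, "chi2+180"),
           list("CE1", c("CB","CG","ND1"),1.319, 109.3, 180),
           list("NE2", c("CG","ND1","CE1"),1.374, 111.7, 0)),
  P = list(list("CG",  c("N","CA","CB"),  1.492, 104.5, "chi1"),
           list("CD",  c("CA","CB","CG"), 1.503, 106.1, "chi2"))
)

# hydroxyl hydrogens added on request for S/T/Y
.HYDROXYL_H <- list(
  S = list("HG",  c("CA","CB","OG"),  0.96, 109.5),
  T = list("HG1", c("CA","CB","OG1"), 0.96, 109.5),
  Y = list("HH",  c("CE1","CZ","OH"), 0.96, 109.5)
)

#' Number of chi angles per amino acid (as modelled here)
#' @param aa One-letter code(s).
#' @return Integer vector.
#' @export
chiCount <- function(aa) {
  n <- vapply(.SC_TOPO[aa], function(top) {
    ks <- unlist(lapply(top, function(a)
      if (is.character(a[[5L]])) as.integer(sub("^chi(\\d).*$", "\\1", a[[5L]]))
      else NA_integer_))
    if (length(ks) == 0L || all(is.na(ks))) 0L else max(ks, na.rm = TRUE)
  }, integer(1))
  unname(n)
}

#' Build ideal side-chain coordinates for a residue
#'
#' Places side-chain heavy atoms (and optionally the hydroxyl hydrogen for
#' Ser/Thr/Tyr) onto a given backbone using ideal internal coordinates and
#' the supplied chi angles. CB is placed with L-amino-acid chirality.
#'
#' @param aa One-letter amino-acid code.
#' @param backbone 3 x 3 (or more) coordinate matrix with rownames
#'   containing `N`, `CA`, `C`.
#' @param chi Numeric chi angles in degrees (`chiCount(aa)` values).
#' @param hydroxylH For S/T/Y: the H-O-C-C dihedral (degrees) at which to
#'   place the hydroxyl hydrogen, or `NA` to omit it.
#' @return Coordinate matrix of the placed atoms (rownames = atom names,
#'   starting with CB for non-Gly residues).
#' @export
buildSideChain <- function(aa, backbone, chi = numeric(0), hydroxylH = NA) {
  if (!aa %in% names(.SC_TOPO)) stop("unknown amino acid '", aa, "'")
  need <- chiCount(aa)
  if (length(chi) < need)
    stop(aa, " needs ", need, " chi angles, got ", length(chi))
  pos <- list(N = backbone["N", ], CA = backbone["CA", ], C = backbone["C", ])
  out <- list()
  if (aa != "G") {
    cb <- .nerf(pos$N, pos$C, pos$CA, 1.530, 110.5, -122.6)
    pos$CB <- cb
    out$CB <- cb
  }
  for (spec in .SC_TOPO[[aa]]) {
    dspec <- spec[[5L]]
    dih <- if (is.numeric(dspec)) dspec else {
      k <- as.integer(sub("^chi(\\d).*$", "\\1", dspec))
      off <- sub("^chi\\d", "", dspec)
      chi[k] + if (nzchar(off)) as.numeric(off) else 0
    }
    refs <- spec[[2L]]
    p <- .nerf(pos[[refs[1L]]], pos[[refs[2L]]], pos[[refs[3L]]],
               spec[[3L]], spec[[4L]], dih)
    pos[[spec[[1L]]]] <- p
    out[[spec[[1L]]]] <- p
  }
  if (!is.na(hydroxylH) && aa %in% names(.HYDROXYL_H)) {
    h <- .HYDROXYL_H[[aa]]
    p <- .nerf(pos[[h[[2L]][1L]]], pos[[h[[2L]][2L]]], pos[[h[[2L]][3L]]],
               h[[3L]], h[[4L]], hydroxylH)
    out[[h[[1L]]]] <- p
  }
  m <- do.call(rbind, out)
  rownames(m) <- names(out)
  m
}

#' Build an ideal backbone fragment at a given location
#'
#' Constructs N, CA, C, O coordinates of a single residue with ideal
#' geometry, positioned so that CA sits at `caPos` and the N->CA direction
#' follows `direction`. Used by the synthetic-scaffold generator.
#'
#' @param caPos Length-3 CA position.
#' @param direction Length-3 direction (need not be normalized).
#' @param up Length-3 vector fixing the backbone plane (default z).
#' @return 4 x 3 matrix with rownames N, CA, C, O.
#' @export
idealBackbone <- function(caPos, direction = c(1, 0, 0), up = c(0, 0, 1)) {
  caPos <- as.numeric(caPos)
  d <- as.numeric(direction)
  d <- d / sqrt(sum(d^2))
  u <- as.numeric(up)
  u <- u - sum(u * d) * d
  if (sqrt(sum(u^2)) < 1e-6) u <- .vcross(d, c(1, 0, 0) + 1e-3)
  u <- u / sqrt(sum(u^2))
  N <- caPos - 1.458 * d
  # C at tetrahedral-ish angle from N-CA in the d/u plane
  ang <- (180 - 111.2) * pi / 180
  C <- caPos + 1.525 * (cos(ang) * d + sin(ang) * u)
  O <- C + 1.231 * u
  m <- rbind(N = N, CA = caPos, C = C, O = O)
  m
}
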