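#' Geometric measurements on 3D points
#'
#' Measure a distance, bond angle or dihedral (torsion) angle from 2, 3 or 4
#' points given as rows of a numeric matrix.
#'
#' Distances are in the units of the input coordinates (angstroms throughout
#' this package); angles and dihedrals are in degrees. Angles lie in
#' \[0, 180\], dihedrals in (-180, 180\] following the IUPAC sign convention.
#'
#' @param kind One of `"distance"`, `"angle"`, `"dihedral"`.
#' @param points Numeric matrix with 3 columns and 2, 3 or 4 rows matching
#'   `kind`.
#' @return A single numeric value.
#' @examples
#' measureGeometry("distance", rbind(c(0, 0, 0), c(3, 4, 0)))  # 5
#' measureGeometry("angle", rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)))  # 90
#' @export
measureGeometry <- function(kind = c("distance", "angle", "dihedral"), points) {
  kind <- match.arg(kind)
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("'points' must have 3 columns (x, y, z)")
  need <- c(distance = 2L, angle = 3L, dihedral = 4L)[[kind]]
  if (nrow(points) != need)
    stop(sprintf("'%s' needs %d points, got %d", kind, need, nrow(points)))
  if (!all(is.finite(points)))
    stop("coordinates must be finite")
  switch(kind,
    distance = .vdist(points[1L, ], points[2L, ]),
    angle    = .vangle(points[1L, ], points[2L, ], points[3L, ]),
    dihedral = .vdihedral(points[1L, ], points[2L, ], points[3L, ], points[4L, ])
  )
}

.vdist <- function(a, b) sqrt(sum((a - b)^2))

.vangle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    stop("degenerate angle: coincident points")
  ct <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, ct))) * 180 / pi
}

.vdihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12)
    stop("degenerate dihedral: collinear points")
  m1 <- .vcross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.vcross <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Least-squares superposition (Kabsch) RMSD
#'
#' Computes the root-mean-square deviation between two coordinate sets in
#' 1:1 correspondence. With `superpose = TRUE` the mobile set is first
#' optimally rotated/translated onto the reference (Kabsch algorithm via
#' singular value decomposition, with the usual reflection correction), so
#' the returned RMSD is the least-squares minimum over all rigid motions.
#' With `superpose = FALSE` the raw RMSD in the given frame is returned.
#'
#' @param ref,mobile Numeric n x 3 matrices, n >= 1 (n >= 3 for a unique
#'   superposition).
#' @param superpose Superpose before measuring? Default `TRUE`.
#' @return Numeric RMSD in angstroms, with attributes `rotation` (3 x 3
#'   matrix) and `translation` (length-3 vector) when `superpose = TRUE`,
#'   such that `mobile %*% rotation + translation` superposes onto `ref`
#'   (rows as points).
#' @export
kabschRmsd <- function(ref, mobile, superpose = TRUE) {
  ref <- as.matrix(ref)
  mobile <- as.matrix(mobile)
  if (!identical(dim(ref), dim(mobile)))
    stop("'ref' and 'mobile' must have identical dimensions")
  if (ncol(ref) != 3L) stop("coordinate sets must have 3 columns")
  n <- nrow(ref)
  if (n < 1L) stop("need at least one point")
  if (!superpose) {
    return(sqrt(sum((ref - mobile)^2) / n))
  }
  cr <- colMeans(ref)
  cm <- colMeans(mobile)
  A <- sweep(ref, 2L, cr)
  B <- sweep(mobile, 2L, cm)
  H <- crossprod(B, A)            # 3x3 covariance t(B) %*% A
  sv <- svd(H)
  # rotated = B %*% R maximizes tr(t(R) H); R = U D t(V) with the usual
  # reflection guard so det(R) = +1
  D <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% D %*% t(sv$v)
  rot <- B %*% R
  rmsd <- sqrt(sum((A - rot)^2) / n)
  out <- rmsd
  attr(out, "rotation") <- R
  attr(out, "translation") <- cr - as.numeric(cm %*% R)
  out
}

#' Hydrogen-bond acceptance criteria
#'
#' Geometric criteria used throughout for counting hydrogen bonds: the
#' donor--acceptor distance must be strictly less than `maxDistance` and the
#' donor-H-acceptor angle strictly greater than `minAngle`. Defaults follow
#' standard practice for trajectory analysis of serine hydrolases
#' (3.5 angstrom / 120 degrees).
#'
#' @param maxDistance Maximum donor-acceptor distance in angstroms (> 0).
#' @param minAngle Minimum donor-H-acceptor angle in degrees, in (0, 180).
#' @return A list of class `"HBondCriteria"`.
#' @export
hbondCriteria <- function(maxDistance = 3.5, minAngle = 120) {
  stopifnot(is.numeric(maxDistance), length(maxDistance) == 1L, maxDistance > 0,
            is.numeric(minAngle), length(minAngle) == 1L,
            minAngle > 0, minAngle < 180)
  structure(list(maxDistance = maxDistance, minAngle = minAngle),
            class = "HBondCriteria")
}

#' Test a donor/hydrogen/acceptor triple for a hydrogen bond
#'
#' Strictly-inequality test: TRUE iff donor-acceptor distance <
#' `criteria$maxDistance` AND donor-H-acceptor angle > `criteria$minAngle`.
#'
#' @param donor,hydrogen,acceptor Length-3 numeric coordinates (angstroms).
#' @param criteria An [hbondCriteria()] object.
#' @return List with elements `bonded` (logical), `distance` (angstroms,
#'   donor-acceptor) and `angle` (degrees, donor-H-acceptor).
#' @export
isHydrogenBond <- function(donor, hydrogen, acceptor,
                           criteria = hbondCriteria()) {
  donor <- as.numeric(donor); hydrogen <- as.numeric(hydrogen)
  acceptor <- as.numeric(acceptor)
  stopifnot(length(donor) == 3L, length(hydrogen) == 3L, length(acceptor) == 3L)
  d <- .vdist(donor, acceptor)
  ang <- .vangle(donor, hydrogen, acceptor)
  list(bonded = (d < criteria$maxDistance) && (ang > criteria$minAngle),
       distance = d, angle = ang)
}

#' Idealized polar hydrogen placement
#'
#' When explicit hydrogens are absent from a structure, an idealized polar
#' hydrogen is constructed on the donor heavy atom: the H is placed at
#' `bondLength` angstrom from the donor along the direction opposite to the
#' (normalized) sum of unit vectors toward the donor's bonded heavy-atom
#' neighbours -- the standard sp2/sp3 lone-direction idealization. For a
#' backbone amide N the neighbours are CA and the preceding carbonyl C; for
#' a Ser/Thr/Tyr hydroxyl, the single bonded carbon plus (optionally) the
#' intended acceptor to bias the proton toward the bond being tested.
#'
#' @param donor Length-3 coordinates of the donor heavy atom.
#' @param neighbours Matrix (rows = points) of bonded heavy-atom neighbours.
#' @param bondLength N-H/O-H bond length, default 1.0 angstrom.
#' @return Length-3 hydrogen coordinates.
#' @export
idealPolarHydrogen <- function(donor, neighbours, bondLength = 1.0) {
  donor <- as.numeric(donor)
  neighbours <- matrix(as.numeric(neighbours), ncol = 3L)
  if (nrow(neighbours) < 1L) stop("need at least one bonded neighbour")
  u <- rep(0, 3)
  for (i in seq_len(nrow(neighbours))) {
    v <- neighbours[i, ] - donor
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) stop("neighbour coincides with donor")
    u <- u + v / nv
  }
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("neighbour geometry gives no defined H direction")
  donor - bondLength * u / nu
}
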