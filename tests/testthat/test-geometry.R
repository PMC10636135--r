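test_that("distance, angle and dihedral measurements are correct", {
  expect_equal(measureGeometry("distance", rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(measureGeometry("angle",
                               rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))), 90)
  # planar cis four-point set has dihedral 0
  expect_equal(measureGeometry("dihedral",
                               rbind(c(1, 1, 0), c(1, 0, 0),
                                     c(-1, 0, 0), c(-1, 1, 0))), 0)
  # trans is 180, and a known chiral set is signed
  expect_equal(abs(measureGeometry("dihedral",
                                   rbind(c(1, 1, 0), c(1, 0, 0),
                                         c(-1, 0, 0), c(-1, -1, 0)))), 180)
  expect_error(measureGeometry("angle",
                               rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
               "degenerate")
  expect_error(measureGeometry("distance", rbind(c(0, 0, 0))), "needs 2")
})

test_that("kabschRmsd finds the least-squares superposition", {
  set.seed(42)
  A <- matrix(rnorm(30), 10, 3)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  B <- A %*% t(R) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  expect_lt(kabschRmsd(A, B), 1e-9)
  # raw RMSD of a uniform 1 A x-shift is exactly 1
  expect_equal(kabschRmsd(A, sweep(A, 2, c(-1, 0, 0)), superpose = FALSE), 1)
  expect_error(kabschRmsd(A, B[1:5, ]), "identical dimensions")
})

test_that("kabschRmsd agrees with an independent superposition method", {
  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    ours <- as.numeric(kabschRmsd(A, B))
    fitted <- bio3d::fit.xyz(as.numeric(t(A)), as.numeric(t(B)),
                             fixed.inds = 1:30, mobile.inds = 1:30)
    ref <- sqrt(mean(rowSums((A - matrix(fitted, ncol = 3,
                                         byrow = TRUE))^2)))
    expect_equal(ours, ref, tolerance = 1e-8)
    # superposed never exceeds raw
    expect_lte(ours, kabschRmsd(A, B, superpose = FALSE) + 1e-12)
  }
})

test_that("kabschRmsd is invariant under a common rigid motion of both sets", {
  set.seed(7)
  A <- matrix(rnorm(24), 8, 3)
  B <- matrix(rnorm(24), 8, 3)
  base <- as.numeric(kabschRmsd(A, B))
  w <- c(0.3, -1.1, 0.7)
  th <- sqrt(sum(w^2)); k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  shift <- matrix(c(5, -3, 2), 8, 3, byrow = TRUE)
  expect_equal(as.numeric(kabschRmsd(A %*% R + shift, B %*% R + shift)),
               base, tolerance = 1e-9)
})

test_that("hydrogen-bond test applies strict distance and angle thresholds", {
  crit <- hbondCriteria()
  mk <- function(d, ang) {
    # donor at origin, H at 1 A along x; acceptor placed analytically so the
    # donor-acceptor distance is d and the donor-H-acceptor angle is ang
    h <- c(1, 0, 0)
    a_ <- ang * pi / 180
    t <- cos(a_) + sqrt(d^2 - sin(a_)^2)
    a <- h + t * c(cos(pi - a_), sin(pi - a_), 0)
    isHydrogenBond(c(0, 0, 0), h, a, crit)
  }
  r <- mk(3.4, 130)
  expect_true(r$bonded)
  expect_equal(r$distance, 3.4, tolerance = 1e-9)
  expect_equal(r$angle, 130, tolerance = 1e-9)
  expect_false(mk(3.6, 170)$bonded)   # too long
  expect_false(mk(3.0, 110)$bonded)   # too bent
  # slightly over the line in either criterion fails (strict inequalities)
  expect_false(mk(3.5 + 1e-6, 170)$bonded)
  expect_false(mk(3.0, 120 - 1e-6)$bonded)
})

test_that("idealized polar hydrogen lies opposite the bonded neighbours", {
  d <- c(0, 0, 0)
  nb <- rbind(c(1.5, 0, 0), c(0, 1.5, 0))
  h <- idealPolarHydrogen(d, nb)
  expect_equal(sqrt(sum(h^2)), 1.0, tolerance = 1e-9)
  expect_equal(h / sqrt(sum(h^2)), -c(1, 1, 0) / sqrt(2), tolerance = 1e-9)
  expect_error(idealPolarHydrogen(d, matrix(0, 1, 3)), "coincides")
})
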