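test_that("shipped default model declares the full catalytic machinery", {
  m <- loadActiveSiteConfig()
  expect_s4_class(m, "ActiveSiteModel")
  expect_length(m@roles, 6L)
  expect_gte(length(m@constraints), 8L)
  ids <- vapply(m@roles, `[[`, character(1), "roleId")
  expect_setequal(ids, c("nucleophile_ser", "base_his", "acid_asp_glu",
                         "oxyanion_nh_1", "oxyanion_nh_2",
                         "carboxylate_binder_ser"))
  # oxyanion donors allow everything but proline
  oxy <- m@roles[[which(ids == "oxyanion_nh_1")]]
  expect_false("P" %in% oxy$allowedAa)
  expect_length(oxy$allowedAa, 19L)
  # the TS is a connected tetrahedral-intermediate model
  expect_equal(m@ts@tetrahedralCenter, "C1")
  expect_gte(length(m@ts@torsions), 2L)
})

test_that("config validation rejects broken models", {
  path <- system.file("extdata", "active_site_mhet.yaml", package = "enzdes")
  cfg <- readLines(path)
  # remove the base_his role
  drop <- withr::local_tempfile(fileext = ".yaml")
  i <- grep("role_id: base_his", cfg)
  writeLines(cfg[-(i:(i + 2L))], drop)
  expect_error(loadActiveSiteConfig(drop), "base_his")
  # invert a tolerance window
  bad <- withr::local_tempfile(fileext = ".yaml")
  cfg2 <- sub("    lo: 2.0", "    lo: 9.0", cfg, fixed = TRUE)
  writeLines(cfg2, bad)
  expect_error(loadActiveSiteConfig(bad), "tol_lo > tol_hi")
  # dangling role reference in a constraint
  dangle <- withr::local_tempfile(fileext = ".yaml")
  cfg3 <- sub("atoms: \\[\\[nucleophile_ser, OG\\], \\[TS, C1\\]\\]",
              "atoms: [[phantom_role, OG], [TS, C1]]", cfg)
  writeLines(cfg3, dangle)
  expect_error(loadActiveSiteConfig(dangle), "attack_distance")
})

test_that("penalty is zero at targets and quadratic outside the window", {
  m <- loadActiveSiteConfig()
  fx <- makeToyScaffold(seed = 5, nDecoys = 6)
  expect_equal(as.numeric(constraintPenalty(m, fx$truth$geometry)), 0)
  # a distance 0.5 A beyond tol_hi at weight 1 contributes exactly 0.25
  fx2 <- makeToyScaffold(seed = 5, nDecoys = 6,
                         offsets = c(oxyanion_hbond_1 = 0.5))
  pen <- constraintPenalty(m, fx2$truth$geometry)
  expect_equal(as.numeric(pen), 0.25)
  bd <- attr(pen, "breakdown")
  expect_equal(bd$penalty[bd$id == "oxyanion_hbond_1"], 0.25)
  expect_equal(sum(bd$penalty), as.numeric(pen))
})

test_that("penalty equals an independent per-constraint re-summation", {
  m <- loadActiveSiteConfig()
  set.seed(31)
  fx <- makeToyScaffold(seed = 31, nDecoys = 6)
  g <- fx$truth$geometry
  # randomly perturb every placed atom
  g <- lapply(g, function(mm) mm + matrix(rnorm(length(mm), 0, 0.45),
                                          nrow(mm), 3))
  names(g) <- names(fx$truth$geometry)
  for (i in seq_along(g)) rownames(g[[i]]) <- rownames(fx$truth$geometry[[i]])
  pen <- constraintPenalty(m, g)
  # hand re-summation straight from the model definition
  resolve <- function(ref, nm) {
    cand <- if (ref == "TS" && nm %in% names(m@tsAliases)) m@tsAliases[[nm]]
            else if (ref != "TS" && nm == "OD") c("OD1", "OD2")
            else nm
    intersect(cand, rownames(g[[ref]]))
  }
  total <- 0
  for (con in m@constraints) {
    opts <- lapply(con$atoms, function(at) resolve(at[[1]], at[[2]]))
    combos <- expand.grid(lapply(opts, seq_along))
    best <- Inf
    for (k in seq_len(nrow(combos))) {
      pts <- do.call(rbind, lapply(seq_along(opts), function(j)
        g[[con$atoms[[j]][[1]]]][opts[[j]][combos[k, j]], ]))
      v <- measureGeometry(con$kind, pts)
      exc <- if (v < con$lo) con$lo - v else if (v > con$hi) v - con$hi else 0
      best <- min(best, con$weight * exc^2)
    }
    total <- total + best
  }
  expect_equal(as.numeric(pen), total, tolerance = 1e-12)
})

test_that("penalty is non-decreasing as a value moves away from its window", {
  m <- loadActiveSiteConfig()
  fx <- makeToyScaffold(seed = 8, nDecoys = 6)
  g <- fx$truth$geometry
  oxy <- g$TS["OXY", ]
  dir <- (g$oxyanion_nh_1["N", ] - oxy) / sqrt(sum((g$oxyanion_nh_1["N", ] - oxy)^2))
  pens <- vapply(seq(0, 4, by = 0.25), function(extra) {
    g2 <- g
    g2$oxyanion_nh_1["N", ] <- oxy + (2.9 + extra) * dir
    as.numeric(constraintPenalty(m, g2))
  }, numeric(1))
  expect_true(all(diff(pens) >= -1e-12))
  expect_equal(pens[1], 0)            # inside the window
  expect_gt(pens[length(pens)], 0)    # far outside
})

test_that("unresolvable constraint atoms error with the constraint name", {
  m <- loadActiveSiteConfig()
  fx <- makeToyScaffold(seed = 5, nDecoys = 6)
  g <- fx$truth$geometry
  rownames(g$nucleophile_ser) <- c("XX", "CB")
  expect_error(constraintPenalty(m, g), "attack_distance")
})
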