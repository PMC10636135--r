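test_that("planted ideal site is found as the unique near-zero match", {
  m <- loadActiveSiteConfig()
  fx <- makeToyScaffold(seed = 3, nDecoys = 10)
  res <- matchActiveSite(fx$structure, m)
  expect_length(res, 1L)
  expect_lt(penaltyScore(res[[1]]), 1e-6)
  a <- roleAssignment(res[[1]])
  got <- setNames(a$resno, a$role)
  want <- setNames(fx$truth$positions$resno, fx$truth$positions$role)
  expect_equal(got[names(want)], want)
  # reported penalty is reproducible through constraintPenalty
  g <- res[[1]]@placedAtoms
  g$TS <- tsPose(res[[1]])
  expect_equal(as.numeric(constraintPenalty(m, g)), penaltyScore(res[[1]]),
               tolerance = 1e-9)
})

test_that("anchoring rules: removing the native Ser kills the match", {
  m <- loadActiveSiteConfig()
  fx <- makeToyScaffold(seed = 3, nDecoys = 10)
  a <- atomTable(fx$structure)
  # mutate the nucleophile Ser (residue 1) to Ala
  a <- a[!(a$resno == 1L & a$elety == "OG"), ]
  a$resid[a$resno == 1L] <- "ALA"
  s2 <- proteinStructure(a, id = "mutant")
  # the binder Ser (residue 6) cannot serve as nucleophile: its OG has no
  # viable His partner... unless geometry allows; membership is still
  # decided by the same placement routine, so compare to the oracle
  m1 <- matchActiveSite(s2, m)
  m2 <- matcherOracle(s2, m)
  expect_equal(vapply(m1, matchKey, character(1)),
               vapply(m2, matchKey, character(1)))
  expect_false(any(vapply(m1, function(x)
    any(roleAssignment(x)$role == "nucleophile_ser" &
        roleAssignment(x)$resno == 1L), logical(1))))
})

test_that("matcher equals exhaustive triple enumeration on mixed fixtures", {
  m <- loadActiveSiteConfig()
  for (seed in c(11, 23)) {
    fx <- makeToyScaffold(seed = seed, nDecoys = 10,
                          extraCatalytic = c(S = 1, H = 1, D = 1))
    got <- matchActiveSite(fx$structure, m)
    oracle <- matcherOracle(fx$structure, m)
    expect_equal(vapply(got, matchKey, character(1)),
                 vapply(oracle, matchKey, character(1)))
    expect_equal(vapply(got, penaltyScore, numeric(1)),
                 vapply(oracle, penaltyScore, numeric(1)), tolerance = 1e-6)
  }
})

test_that("ranking is ascending, deterministic and permutation-invariant", {
  m <- loadActiveSiteConfig()
  fx <- makeToyScaffold(seed = 11, nDecoys = 10,
                        extraCatalytic = c(S = 2, H = 1, D = 1))
  res <- matchActiveSite(fx$structure, m)
  pens <- vapply(res, penaltyScore, numeric(1))
  expect_false(is.unsorted(pens))
  if (length(res) > 1L) {
    set.seed(1)
    shuffled <- rankMatches(sample(res))
    expect_equal(vapply(shuffled, matchKey, character(1)),
                 vapply(res, matchKey, character(1)))
  }
  expect_length(rankMatches(res[1]), 1L)
})

test_that("far-away residues do not perturb an existing match", {
  m <- loadActiveSiteConfig()
  fx <- makeToyScaffold(seed = 3, nDecoys = 8)
  base <- matchActiveSite(fx$structure, m)
  a <- atomTable(fx$structure)
  extra <- do.call(rbind, lapply(1:4, function(i) {
    bb <- idealBackbone(c(40 + 6 * i, 35, -30), direction = c(1, 0, 0))
    data.frame(chain = "A", resno = 100L + i, insert = "", resid = "ALA",
               elety = rownames(bb), element = substr(rownames(bb), 1, 1),
               x = bb[, 1], y = bb[, 2], z = bb[, 3],
               stringsAsFactors = FALSE)
  }))
  s2 <- proteinStructure(rbind(a[, names(extra)], extra), id = "padded")
  res2 <- matchActiveSite(s2, m)
  expect_equal(vapply(res2, matchKey, character(1)),
               vapply(base, matchKey, character(1)))
  expect_equal(vapply(res2, penaltyScore, numeric(1)),
               vapply(base, penaltyScore, numeric(1)), tolerance = 1e-9)
})

test_that("triad RMSD versus native side chains behaves like a raw RMSD", {
  m <- loadActiveSiteConfig()
  fx <- makeToyScaffold(seed = 3, nDecoys = 6)
  match <- matchActiveSite(fx$structure, m)[[1]]
  # default placement uses the native conformations: RMSD 0
  expect_equal(triadRmsdVsNative(match, fx$structure), 0, tolerance = 1e-9)
  # displace every placed triad atom by 0.5 A in x -> RMSD exactly 0.5
  shifted <- match
  for (r in c("nucleophile_ser", "base_his", "acid_asp_glu"))
    shifted@placedAtoms[[r]] <- sweep(match@placedAtoms[[r]], 2,
                                      c(-0.5, 0, 0))
  expect_equal(triadRmsdVsNative(shifted, fx$structure), 0.5,
               tolerance = 1e-9)
  # agrees with kabschRmsd(superpose = FALSE) on the same atom stack
  placed <- do.call(rbind, shifted@placedAtoms[c("nucleophile_ser",
                                                 "base_his", "acid_asp_glu")])
  a <- roleAssignment(match)
  native <- do.call(rbind, lapply(1:3, function(i) {
    rc <- enzdes:::.residueCoords(fx$structure, a$chain[i], a$resno[i],
                                  a$insert[i])
    nm <- rownames(shifted@placedAtoms[[a$role[i]]])
    rc[nm, , drop = FALSE]
  }))
  expect_equal(triadRmsdVsNative(shifted, fx$structure),
               as.numeric(kabschRmsd(native, placed, superpose = FALSE)),
               tolerance = 1e-12)
  # missing native atoms error and are listed
  broken <- atomTable(fx$structure)
  broken <- broken[!(broken$resno == 1L & broken$elety == "CB"), ]
  expect_error(triadRmsdVsNative(match, proteinStructure(broken, id = "x")),
               "CB")
})

test_that("pocket detection finds engineered cavities, ranked by size", {
  # a convex straight strand has no enclosed cavity
  line <- do.call(rbind, lapply(1:10, function(i) {
    bb <- idealBackbone(c(3.5 * i, 0, 0), direction = c(1, 0, 0))
    data.frame(chain = "A", resno = i, insert = "", resid = "GLY",
               elety = rownames(bb), element = substr(rownames(bb), 1, 1),
               x = bb[, 1], y = bb[, 2], z = bb[, 3], stringsAsFactors = FALSE)
  }))
  expect_warning(pk0 <- detectPockets(proteinStructure(line, id = "line")),
                 "no cavities")
  expect_length(pk0, 0L)
  # one engineered cup -> exactly one pocket lined by the cup residues
  cup <- cupScaffold()
  s1 <- proteinStructure(cup$atoms, id = "cup1")
  expect_warning(pk1 <- detectPockets(s1, nPockets = 3), "pocket")
  expect_length(pk1, 1L)
  expect_true(all(pk1[[1]]$memberPositions$resno %in% cup$lining))
  expect_gt(nrow(pk1[[1]]$memberPositions), 5L)
  # two cavities of different size -> larger first
  cupA <- cupScaffold(center = c(0, 0, 0), radius = 7.5, perRing = 16,
                      resnoStart = 1L)
  cupB <- cupScaffold(center = c(60, 0, 0), radius = 5, perRing = 10,
                      resnoStart = 200L)
  s2 <- proteinStructure(rbind(cupA$atoms, cupB$atoms), id = "cups")
  pk2 <- suppressWarnings(detectPockets(s2, nPockets = 2))
  expect_length(pk2, 2L)
  expect_gt(pk2[[1]]$volumeProxy, pk2[[2]]$volumeProxy)
  expect_true(all(pk2[[1]]$memberPositions$resno %in% cupA$lining))
  expect_true(all(pk2[[2]]$memberPositions$resno %in% cupB$lining))
})
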