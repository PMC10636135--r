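test_that("frame loading resolves catalytic atoms and round-trips", {
  fs <- synthFrames(c(rmsd = 1, attack = 1, hbond1 = 1, hbond2 = 1),
                    nFrames = 5, seed = 2)[[1]]
  p <- withr::local_tempfile(fileext = ".pdb")
  writeFrames(fs, p)
  lf <- loadFrames(p, synthFrameLabeling(), designId = "d", replicateId = "r")
  expect_equal(nFrames(lf), 5L)
  expect_lt(max(abs(lf@frames[[3]] - fs@frames[[3]])), 1e-3 + 1e-9)
  # labels resolve to the same atoms
  expect_equal(lf@atomInfo$elety[lf@labels[["tsC"]]], "C1")
  expect_equal(lf@atomInfo$elety[lf@labels[["serOG"]]], "OG")
  # a missing labelled atom errors with its name
  badLab <- synthFrameLabeling()
  badLab$tsC$elety <- "C9"
  expect_error(loadFrames(p, badLab), "C9")
  expect_error(loadFrames(p, badLab[-2]), "tsC")
})

test_that("indicators recover constructed frame statistics exactly", {
  # all frames identical to the reference
  fs1 <- synthFrames(c(rmsd = 1, attack = 1, hbond1 = 1, hbond2 = 1),
                     nFrames = 20, seed = 1)[[1]]
  v1 <- indicatorVector(catalyticIndicators(fs1))
  expect_equal(unname(v1), c(1, 1, 1, 1))
  # exactly 55 of 100 frames under the attack cutoff
  fs2 <- synthFrames(c(rmsd = 0.8, attack = 0.55, hbond1 = 0.6, hbond2 = 0.7),
                     nFrames = 100, seed = 3)[[1]]
  v2 <- indicatorVector(catalyticIndicators(fs2))
  expect_equal(v2[["attackFrac3A"]], 0.55)
  expect_equal(v2[["freqRmsdTs"]], 0.8)
  # hydrogen-bond geometry failing in every frame gives zero frequencies
  fs3 <- synthFrames(c(rmsd = 1, attack = 1, hbond1 = 0, hbond2 = 0),
                     nFrames = 30, seed = 4)[[1]]
  v3 <- indicatorVector(catalyticIndicators(fs3))
  expect_equal(v3[["hbondFreq1"]], 0)
  expect_equal(v3[["hbondFreq2"]], 0)
  # fractions are bounded
  expect_true(all(v2 >= 0 & v2 <= 1))
})

test_that("pooling is frame-weighted and bounded by replicate extremes", {
  fs <- synthFrames(c(rmsd = 0.5, attack = 0.4, hbond1 = 0.5, hbond2 = 0.5),
                    nFrames = 50, seed = 6)[[1]]
  fs2 <- synthFrames(c(rmsd = 0.5, attack = 0.6, hbond1 = 0.5, hbond2 = 0.5),
                     nFrames = 50, seed = 7)[[1]]
  agg <- aggregateAndCompare(list(catalyticIndicators(fs),
                                  catalyticIndicators(fs2)))
  expect_equal(indicatorVector(agg$pooled)[["attackFrac3A"]], 0.5)
  # frame-weighted pooling with unequal frame counts
  fs3 <- synthFrames(c(rmsd = 0.5, attack = 1, hbond1 = 0.5, hbond2 = 0.5),
                     nFrames = 100, seed = 8)[[1]]
  agg2 <- aggregateAndCompare(list(catalyticIndicators(fs),
                                   catalyticIndicators(fs3)))
  expect_equal(indicatorVector(agg2$pooled)[["attackFrac3A"]],
               (0.4 * 50 + 1 * 100) / 150)
  # pooled equals a flat recomputation over concatenated frames
  both <- new("FrameSet", designId = fs@designId, replicateId = "cat",
              frames = c(fs@frames, fs2@frames), atomInfo = fs@atomInfo,
              labels = fs@labels, frameIntervalPs = 10)
  flat <- indicatorVector(catalyticIndicators(both))
  expect_equal(unname(indicatorVector(agg$pooled)), unname(flat))
})

test_that("improvement verdict is strict on all four indicators", {
  wtP <- c(rmsd = 0.5, attack = 0.4, hbond1 = 0.5, hbond2 = 0.45)
  wt <- aggregateAndCompare(lapply(
    synthFrames(wtP, nFrames = 100, nReplicates = 2, seed = 10),
    catalyticIndicators))$pooled
  up <- aggregateAndCompare(lapply(
    synthFrames(wtP + 0.2, nFrames = 100, nReplicates = 2, seed = 11),
    catalyticIndicators), wt = wt)
  expect_true(up$improved)
  # tying the wild type on a single indicator fails the strict test
  tie <- wtP + 0.2
  tie["hbond2"] <- wtP[["hbond2"]]
  tied <- aggregateAndCompare(lapply(
    synthFrames(tie, nFrames = 100, nReplicates = 2, seed = 12),
    catalyticIndicators), wt = wt)
  expect_false(tied$improved)
})

test_that("two-round funnel recovers a planted cohort and is order-invariant", {
  co <- makeFunnelCohort(nDesigns = 16, nImprove = 7, nFrames = 60,
                         nReplicates = 3, seed = 21)
  co2 <- makeFunnelCohort(nDesigns = 7, nImprove = 5, nFrames = 100,
                          nReplicates = 2, seed = 22)
  # name round-2 designs after the round-1 planted survivors
  r2ids <- co$planted
  r2map <- setNames(c(co2$planted,
                      setdiff(co2$ids, co2$planted))[seq_along(r2ids)], r2ids)
  provider2 <- function(id) co2$provider(r2map[[id]])
  rep1 <- twoRoundFunnel(co$provider, co$wt, round2Provider = provider2,
                         wtR2 = co2$wt, designIds = co$ids)
  expect_equal(sort(rep1$round1Survivors), co$planted)
  expect_equal(sort(rep1$round2Survivors),
               sort(names(r2map)[r2map %in% co2$planted]))
  # shuffled design order produces the identical report
  set.seed(99)
  rep2 <- twoRoundFunnel(co$provider, co$wt, round2Provider = provider2,
                         wtR2 = co2$wt, designIds = sample(co$ids))
  expect_identical(rep1$round1, rep2$round1)
  expect_identical(rep1$shortlist, rep2$shortlist)
  # the wild type submitted as a design can never beat itself
  wtAsDesign <- twoRoundFunnel(
    function(id) synthFrames(c(rmsd = 0.5, attack = 0.4, hbond1 = 0.5,
                               hbond2 = 0.45),
                             nFrames = 60, nReplicates = 3, seed = 21 + 13),
    co$wt, designIds = "WTcopy")
  expect_length(wtAsDesign$round1Survivors, 0L)
  # survivors without round-2 data are pending, excluded from ranking
  rep3 <- twoRoundFunnel(co$provider, co$wt, round2Provider = function(id) NULL,
                         designIds = co$ids)
  expect_equal(sort(rep3$pending), co$planted)
  expect_length(rep3$shortlist, 0L)
})
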