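test_that("PDB round trip preserves residues, order and coordinates", {
  fx <- makeToyScaffold(seed = 2, nDecoys = 8)
  s <- fx$structure
  p <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(s, p)
  s2 <- readStructure(p)
  expect_equal(nResidues(s2), nResidues(s))
  rt <- residueTable(s); rt2 <- residueTable(s2)
  expect_equal(rt2$resno, rt$resno)
  expect_equal(rt2$aa, rt$aa)
  a <- atomTable(s); a2 <- atomTable(s2)
  expect_equal(nrow(a2), nrow(a))
  expect_lt(max(abs(as.matrix(a2[, c("x", "y", "z")]) -
                    as.matrix(a[, c("x", "y", "z")]))), 1e-3 + 1e-9)
})

test_that("reader drops waters, keeps first altLoc, flags broken backbones", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  SER A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   SER A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   SER A   1       1.500   2.400   0.000  1.00  0.00           O",
    "ATOM      5  CB ASER A   1       2.000  -1.000   1.000  0.50  0.00           C",
    "ATOM      6  CB BSER A   1       2.000  -1.000  -1.000  0.50  0.00           C",
    "ATOM      7  N   GLY A   2       3.300   1.500   0.000  1.00  0.00           N",
    "ATOM      8  CA  GLY A   2       4.100   2.700   0.000  1.00  0.00           C",
    "HETATM    9  O   HOH A 101      8.000   8.000   8.000  1.00  0.00           O",
    "END"), p)
  expect_warning(s <- readStructure(p), "incomplete backbone")
  expect_equal(nResidues(s), 2L)             # water gone
  a <- atomTable(s)
  expect_equal(sum(a$elety == "CB"), 1L)     # only altLoc A kept
  expect_equal(a$z[a$elety == "CB"], 1.0)
  rt <- residueTable(s)
  expect_false(rt$hasBackbone[rt$resno == 2]) # Gly missing C/O flagged
  expect_true(rt$hasBackbone[rt$resno == 1])
})

test_that("unreadable file and missing file raise parse errors", {
  expect_error(readStructure(file.path(tempdir(), "nope.pdb")), "not found")
})

test_that("neighborsWithin matches an exhaustive all-atom scan", {
  fx <- makeToyScaffold(seed = 9, nDecoys = 44)  # 50 residues
  s <- fx$structure
  expect_equal(nResidues(s), 50L)
  center <- colMeans(tsPose(loadActiveSiteConfig()@ts))
  for (radius in c(0.5, 5, 10, 18)) {
    got <- neighborsWithin(s, center, radius)
    # brute force: per-residue min distance over all atoms
    a <- atomTable(s)
    d <- sqrt((a$x - center[1])^2 + (a$y - center[2])^2 + (a$z - center[3])^2)
    key <- paste(a$chain, a$resno, a$insert)
    dmin <- tapply(d, factor(key, levels = unique(key)), min)
    expect_setequal(paste(got$chain, got$resno, got$insert),
                    names(dmin)[dmin <= radius])
    expect_false(is.unsorted(got$minDist))
  }
  # monotone in radius
  r5 <- neighborsWithin(s, center, 5)
  r12 <- neighborsWithin(s, center, 12)
  expect_true(all(paste(r5$chain, r5$resno) %in% paste(r12$chain, r12$resno)))
  # inclusion is by nearest atom, not centroid
  one <- neighborsWithin(s, center, 0.2)
  expect_equal(nrow(one), 0L)
})

test_that("scaffold-library filter applies the assembly criteria", {
  rec <- data.frame(
    id = c("a", "b", "c", "d", "e"),
    resolution = c(1.8, 3.5, 2.0, 2.5, NA),
    length = c(300, 400, 150, 500, 420),
    keywords = c("thermophilic esterase", "thermophile", "thermophilus",
                 "mesophilic", "thermophila"),
    ec = c("hydrolase", "hydrolase", "hydrolase", "hydrolase", "oxidoreductase"),
    expressible = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  crit <- list(keywords = c("thermophilic", "thermophile", "thermophila",
                            "thermophilus"), ecClass = "hydrolase")
  out <- filterScaffoldLibrary(rec, crit)
  expect_equal(out$id, "a")
  log <- attr(out, "log")
  expect_equal(log$reason[log$id == "b"], "resolution 3.50 > 3.00")
  expect_match(log$reason[log$id == "c"], "length 150 outside")
  expect_match(log$reason[log$id == "d"], "keyword")
  expect_match(log$reason[log$id == "e"], "resolution")
  # empty input
  empty <- filterScaffoldLibrary(rec[0, ], crit)
  expect_equal(nrow(empty), 0L)
})

test_that("identity de-duplication is greedy keep-first", {
  rec <- data.frame(id = c("x", "y", "z"), resolution = 2, length = 300,
                    keywords = "thermophilic", ec = "hydrolase",
                    stringsAsFactors = FALSE)
  idm <- matrix(c(1, 0.97, 0.2, 0.97, 1, 0.3, 0.2, 0.3, 1), 3, 3,
                dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  out <- filterScaffoldLibrary(rec, list(), identity = idm)
  expect_equal(out$id, c("x", "z"))   # y dropped: 97% identical to kept x
})
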