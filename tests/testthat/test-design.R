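toyDesignSetup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- loadActiveSiteConfig()
      fx <- makeToyScaffold(seed = 3, nDecoys = 10)
      match <- matchActiveSite(fx$structure, m)[[1]]
      tsl <- generateTSLibrary(fx$structure, match, m,
                               params = list(torsionIds = 1, steps = 6),
                               seed = 1)
      cache <<- list(m = m, s = fx$structure, match = match, tsl = tsl)
    }
    cache
  }
})

test_that("rotamer library counts follow the expansion rules", {
  st <- toyDesignSetup()
  # a native-Ser position with a 3-entry Ser base library:
  # 3 chi x 3 hydroxyl-H + 1 crystal chi x 3 hydroxyl-H = 12
  spec <- designSpec(list(list(chain = "A", resno = 1, allowed = "S")),
                     x = st$s)
  base <- data.frame(aa = "S", chi1 = c(62, -177, -65), chi2 = NA,
                     chi3 = NA, chi4 = NA, prob = 1)
  rl <- buildRotamerLibrary(spec, st$s, baseLibrary = base)
  expect_length(rl$rotamers[[1]], 12L)
  expect_equal(sum(vapply(rl$rotamers[[1]], function(r) r$source == "crystal",
                          logical(1))), 3L)
  # Gly and Ala positions carry a single (null) rotamer
  rt <- residueTable(st$s)
  glyPos <- rt$resno[rt$aa == "G"][1]
  alaPos <- rt$resno[rt$aa == "A"][1]
  spec2 <- designSpec(list(), repack = list(list(chain = "A", resno = glyPos),
                                            list(chain = "A", resno = alaPos)),
                      x = st$s)
  rl2 <- buildRotamerLibrary(spec2, st$s)
  expect_length(rl2$rotamers[[1]], 1L)
  expect_length(rl2$rotamers[[2]], 1L)
  # unknown amino acid in the base library errors
  expect_error(buildRotamerLibrary(
    designSpec(list(list(chain = "A", resno = 1, allowed = c("S", "K"))),
               x = st$s),
    st$s, baseLibrary = base), "no base-library rotamers")
})

test_that("generated rotamers have ideal bond lengths", {
  st <- toyDesignSetup()
  rt <- residueTable(st$s)
  pos <- rt$resno[rt$aa %in% c("L", "V")][1]
  spec <- designSpec(list(list(chain = "A", resno = pos,
                               allowed = c("K", "F", "S", "L"))), x = st$s)
  rl <- buildRotamerLibrary(spec, st$s)
  bondLen <- list(
    K = rbind(c("CB", "CG", 1.520), c("CG", "CD", 1.520),
              c("CD", "CE", 1.508), c("CE", "NZ", 1.489)),
    F = rbind(c("CB", "CG", 1.502), c("CG", "CD1", 1.384)),
    S = rbind(c("CB", "OG", 1.417)),
    L = rbind(c("CB", "CG", 1.530), c("CG", "CD1", 1.521)))
  for (r in rl$rotamers[[1]]) {
    if (r$source != "lib") next
    spec_ <- bondLen[[r$aa]]
    for (k in seq_len(nrow(spec_))) {
      d <- measureGeometry("distance",
                           r$coords[c(spec_[k, 1], spec_[k, 2]), ])
      expect_equal(d, as.numeric(spec_[k, 3]), tolerance = 1e-2)
    }
  }
})

test_that("energy terms behave as specified", {
  ctl <- energyModelControl()
  # 12-6 LJ is exactly zero at r = sigma
  sigCC <- ctl$ljSigma[["C"]]
  e <- enzdes:::.nbEnergy(matrix(c(0, 0, 0), 1), "C", 0,
                          matrix(c(sigCC, 0, 0), 1), "C", 0, ctl)
  expect_equal(e, 0, tolerance = 1e-12)
  # repulsion is capped
  e2 <- enzdes:::.nbEnergy(matrix(c(0, 0, 0), 1), "C", 0,
                           matrix(c(0.5, 0, 0), 1), "C", 0, ctl)
  expect_equal(e2, ctl$clashCap)
  # screened Coulomb with dielectric 4r
  e3 <- enzdes:::.nbEnergy(matrix(c(0, 0, 0), 1), "C", 0.5,
                           matrix(c(100, 0, 0), 1), "C", -0.4, ctl) -
        enzdes:::.nbEnergy(matrix(c(0, 0, 0), 1), "C", 0,
                           matrix(c(100, 0, 0), 1), "C", 0, ctl)
  expect_equal(e3, ctl$coulombK * 0.5 * -0.4 / (4 * 100^2), tolerance = 1e-9)
})

test_that("an ideal hydrogen bond to the TS oxyanion is credited exactly once", {
  st <- toyDesignSetup()
  rt <- residueTable(st$s)
  # design the planted binder-Ser position; its crystal rotamer H-bonds the
  # carboxylate; use a custom TS pose so the oxyanion sits at the Ser OG
  spec <- designSpec(list(list(chain = "A", resno = 6, allowed = "S")),
                     x = st$s)
  rl <- buildRotamerLibrary(spec, st$s)
  og <- enzdes:::.residueCoords(st$s, "A", 6)["OG", ]
  ts <- tsPose(st$m@ts)
  ts <- sweep(ts, 2, ts["OXY", ] - (og + c(2.8, 0, 0)))  # OXY 2.8 A from OG
  ctl0 <- energyModelControl(hbondBonus = 0)
  ctl1 <- energyModelControl(hbondBonus = -2)
  et0 <- computeEnergyTables(st$s, rl, ts = ts, model = st$m, control = ctl0)
  et1 <- computeEnergyTables(st$s, rl, ts = ts, model = st$m, control = ctl1)
  delta <- et1@singlesTS[[1]] - et0@singlesTS[[1]]
  # every rotamer whose hydroxyl H points at the oxyanion gains one bonus;
  # the difference is always an integer multiple of the bonus
  expect_true(all(abs(delta - round(delta / 2) * 2) < 1e-9))
  expect_true(any(delta <= -2 + 1e-9))
  hasBonus <- which(delta <= -2 + 1e-9)
  # audit one credited rotamer geometrically: the number of TS acceptor
  # oxygens it hydrogen-bonds equals the credited bonus count
  r <- rl$rotamers[[1]][[hasBonus[1]]]
  tsAtoms <- st$m@ts@atoms
  acc <- tsAtoms$name[tsAtoms$element == "O" & tsAtoms$charge < 0]
  nBonded <- sum(vapply(acc, function(an)
    isHydrogenBond(r$coords["OG", ], r$coords["HG", ], ts[an, ],
                   ctl1$hbond)$bonded, logical(1)))
  expect_equal(delta[hasBonus[1]], -2 * nBonded)
})

test_that("pair energies are symmetric", {
  tb <- randomEnergyTables(nPos = 3, nRot = 4, seed = 5)
  for (k in 1:20) {
    i <- sample(3, 1); j <- sample(3, 1)
    ri <- sample(4, 1); rj <- sample(4, 1)
    expect_equal(pairEnergy(tb, i, ri, j, rj), pairEnergy(tb, j, rj, i, ri))
  }
})

test_that("searchGmec solves trivial and random instances exactly", {
  # 1 position, singles [5, 1, 3] -> rotamer 2, energy 1
  tb <- randomEnergyTables(nPos = 1, nRot = 3, seed = 1)
  tb@singlesTmpl[[1]] <- c(5, 1, 3)
  tb@singlesTS[[1]] <- c(0, 0, 0)
  g <- searchGmec(tb)
  expect_equal(g$assignment, 2L)
  expect_equal(g$energy, 1)
  # random 4-position x 5-rotamer instance vs exhaustive 625-enumeration
  tb2 <- randomEnergyTables(nPos = 4, nRot = 5, seed = 77)
  g2 <- searchGmec(tb2)
  ex <- exhaustiveGmec(tb2)
  expect_equal(g2$energy, ex$energy, tolerance = 1e-9)
  expect_equal(g2$assignment, ex$assignment)
  expect_true(g2$certified)
})

test_that("DEE never eliminates the exhaustive optimum", {
  for (seed in 1:10) {
    tb <- randomEnergyTables(nPos = sample(2:4, 1), nRot = sample(3:6, 1),
                             seed = 3000 + seed)
    ex <- exhaustiveGmec(tb)
    singles <- lapply(seq_along(tb@singlesTmpl), function(i)
      tb@singlesTmpl[[i]] + tb@singlesTS[[i]])
    live <- enzdes:::.deeGoldstein(tb, singles,
                                   lapply(tb@rotamers, seq_along))
    for (i in seq_along(live))
      expect_true(ex$assignment[i] %in% live[[i]])
  }
})

test_that("design enumeration carries exact thermodynamic bookkeeping", {
  st <- toyDesignSetup()
  rt <- residueTable(st$s)
  dp <- rt$resno[rt$resno >= 7][1:2]
  spec <- designSpec(
    mutable = list(list(chain = "A", resno = dp[1], allowed = c("A", "V", "L")),
                   list(chain = "A", resno = dp[2], allowed = c("A", "L"))),
    x = st$s)
  rl <- buildRotamerLibrary(spec, st$s)
  et <- computeEnergyTables(st$s, rl, ts = st$tsl, model = st$m)
  d <- enumerateDesigns(et, count = 6)
  # Eq identities to 1e-9 on every emitted design
  expect_true(all(abs(d$G_bind - (d$G_bound - d$G_unbound)) < 1e-9))
  expect_true(all(abs(d$G_fold - d$G_unbound) < 1e-9))
  expect_true(all(abs(d$ddG_total - (d$ddG_bind + d$ddG_fold)) < 1e-9))
  wt <- attr(d, "wt")
  expect_equal(wt$ddG_bind, 0)
  expect_equal(wt$ddG_fold, 0)
  # sorted by bound energy; sequences distinct at diversity 1
  expect_false(is.unsorted(d$G_bound))
  expect_equal(anyDuplicated(d$mutations), 0L)
  # mutation-class counting matches a hand count
  expect_equal(d$nMut,
               vapply(strsplit(d$mutations, "/"), function(x)
                 if (identical(x, "WT")) 0L else length(x), integer(1)))
  # exhaustive verification: best design's bound energy equals the minimum
  # over all sequences solved independently
  aaSets <- list(c("A", "V", "L"), c("A", "L"))
  allSeq <- expand.grid(aaSets, stringsAsFactors = FALSE)
  allE <- apply(as.matrix(allSeq), 1, function(sq)
    searchGmec(et, restrictAa = as.list(sq), includeWtOnly = FALSE)$energy)
  expect_equal(min(d$G_bound), min(allE), tolerance = 1e-9)
  # diversity = 2 forbids single-position neighbours
  d2 <- suppressWarnings(enumerateDesigns(et, count = 6, diversity = 2))
  if (nrow(d2) > 1) {
    seqs <- lapply(strsplit(d2$mutations, "/"), function(x) x)
    # reconstruct aa per position from mutation labels
    toSeq <- function(lab) {
      sq <- vapply(seq_len(nrow(et@positions)), function(i)
        et@positions$nativeAa[i], character(1))
      if (!identical(lab, "WT")) {
        for (mu in strsplit(lab, "/")[[1]]) {
          resno <- as.integer(gsub("\\D", "", mu))
          sq[et@positions$resno == resno] <- substr(mu, nchar(mu), nchar(mu))
        }
      }
      sq
    }
    for (i in seq_len(nrow(d2) - 1)) for (j in (i + 1):nrow(d2))
      expect_gte(sum(toSeq(d2$mutations[i]) != toSeq(d2$mutations[j])), 2L)
  }
})

test_that("candidate selection implements the two-clause admission rule", {
  base <- data.frame(mutations = c("A1B", "C2D", "E3F"),
                     ddG_bind = c(-1, 2, 5), ddG_fold = c(7.9, 20, 30))
  base$ddG_total <- base$ddG_bind + base$ddG_fold
  out <- selectCandidates(base, criteria = list(topTotal = 1))
  expect_true("A1B" %in% out$mutations)       # clause 1
  expect_equal(out$admittedBy[out$mutations == "A1B"], "energy+rank")
  # rank clause admits a design failing the energy clause
  out2 <- selectCandidates(base, criteria = list(topTotal = 2))
  expect_true("C2D" %in% out2$mutations)
  expect_equal(out2$admittedBy[out2$mutations == "C2D"], "rank")
  expect_false("E3F" %in% out2$mutations)
  # idempotent and order-invariant on a large randomized table
  tab <- synthDesignTable(300, seed = 4)
  s1 <- selectCandidates(tab)
  s2 <- selectCandidates(tab[sample(nrow(tab)), ])
  expect_equal(sort(s1$mutations), sort(s2$mutations))
  s3 <- selectCandidates(s1[, names(tab)])
  expect_setequal(s3$mutations, s1$mutations)
})
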