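# shared fixture builders (all programmatic; nothing read from disk)

# open-topped "cup" scaffold: cylindrical wall of Gly residues plus a bottom
# disk, leaving a buried cavity reachable from the top
cupScaffold <- function(center = c(0, 0, 0), rings = 3, perRing = 12,
                        radius = 6, id = "cup", resnoStart = 1L) {
  cas <- list()
  for (z in seq_len(rings)) for (k in seq_len(perRing)) {
    th <- 2 * pi * k / perRing
    cas[[length(cas) + 1L]] <- center + c(radius * cos(th),
                                          radius * sin(th), (z - 1) * 3)
  }
  for (k in 1:8) {
    th <- 2 * pi * k / 8
    cas[[length(cas) + 1L]] <- center + c(3 * cos(th), 3 * sin(th), -3)
  }
  cas[[length(cas) + 1L]] <- center + c(0, 0, -3)
  atoms <- do.call(rbind, lapply(seq_along(cas), function(i) {
    bb <- idealBackbone(cas[[i]], direction = c(cos(i), sin(i), 0.3))
    data.frame(chain = "A", resno = resnoStart + i - 1L, insert = "",
               resid = "GLY", elety = rownames(bb),
               element = substr(rownames(bb), 1, 1),
               x = bb[, 1], y = bb[, 2], z = bb[, 3],
               stringsAsFactors = FALSE)
  }))
  list(atoms = atoms,
       lining = resnoStart:(resnoStart + length(cas) - 1L))
}

# label map matching the roster emitted by synthFrames()
synthFrameLabeling <- function() {
  list(serOG = list(chain = "A", resno = 1, elety = "OG"),
       tsC = list(chain = "A", resno = 90, elety = "C1"),
       tsOxy = list(chain = "A", resno = 90, elety = "O1"),
       donor1N = list(chain = "A", resno = 2, elety = "N"),
       donor1H = list(chain = "A", resno = 2, elety = "H"),
       donor2N = list(chain = "A", resno = 3, elety = "N"),
       donor2H = list(chain = "A", resno = 3, elety = "H"))
}

# random pairwise-decomposed design instance as an EnergyTables object
randomEnergyTables <- function(nPos, nRot, seed, withTS = FALSE) {
  set.seed(seed)
  aaPool <- c("A", "V", "L", "I", "F", "S", "T", "K", "R", "N", "Q", "M")
  positions <- data.frame(chain = "A", resno = seq_len(nPos) * 10L,
                          insert = "", nativeAa = "A", type = "mutable",
                          stringsAsFactors = FALSE)
  positions$allowed <- I(replicate(nPos, aaPool, simplify = FALSE))
  rotamers <- lapply(seq_len(nPos), function(i)
    lapply(seq_len(nRot), function(r)
      list(aa = aaPool[((r - 1L) %% length(aaPool)) + 1L], chi = numeric(0),
           source = "lib", wtOnly = FALSE,
           coords = matrix(numeric(0), 0L, 3L))))
  singlesTmpl <- lapply(seq_len(nPos), function(i) rnorm(nRot, 0, 3))
  singlesTS <- if (withTS) lapply(seq_len(nPos), function(i) rnorm(nRot, 0, 1))
               else lapply(seq_len(nPos), function(i) numeric(nRot))
  pairs <- list()
  for (i in seq_len(nPos - 1L)) for (j in (i + 1L):nPos)
    pairs[[paste(i, j)]] <- matrix(rnorm(nRot * nRot, 0, 2), nRot, nRot)
  new("EnergyTables", positions = positions, rotamers = rotamers,
      singlesTmpl = singlesTmpl, singlesTS = singlesTS, pairs = pairs,
      control = energyModelControl())
}

# independent exhaustive GMEC oracle over an EnergyTables instance
exhaustiveGmec <- function(tables, state = "bound") {
  n <- nrow(tables@positions)
  singles <- lapply(seq_len(n), function(i) {
    s <- tables@singlesTmpl[[i]]
    if (state == "bound") s <- s + tables@singlesTS[[i]]
    s
  })
  grid <- as.matrix(expand.grid(lapply(seq_len(n), function(i)
    seq_along(tables@rotamers[[i]]))))
  energies <- rep(0, nrow(grid))
  for (i in seq_len(n)) energies <- energies + singles[[i]][grid[, i]]
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m <- tables@pairs[[paste(i, j)]]
    if (!is.null(m)) energies <- energies + m[cbind(grid[, i], grid[, j])]
  }
  k <- which.min(energies)
  list(assignment = as.integer(grid[k, ]), energy = energies[k],
       energies = energies, grid = grid)
}

# all-triple matcher oracle sharing the placement routine
matcherOracle <- function(s, model, config = matchConfig()) {
  rt <- residueTable(s)
  out <- list()
  for (i in which(rt$aa == "S"))
    for (j in which(rt$aa == "H"))
      for (k in which(rt$aa %in% c("D", "E"))) {
        r <- placeActiveSite(s, model,
                             list(nucleophile_ser = i, base_his = j,
                                  acid_asp_glu = k), config)
        if (!is.null(r)) out[[length(out) + 1L]] <- r
      }
  rankMatches(out)
}

matchKey <- function(m) {
  a <- roleAssignment(m)
  paste(a$role, a$chain, a$resno, sep = ":", collapse = "|")
}
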