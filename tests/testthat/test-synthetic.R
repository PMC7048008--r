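test_that("noiseless extreme densities give an exact block matrix", {
  cfg <- plantedConfig(nM = 20, nD = 12, kTrue = 3, withinDensity = 1,
                       backgroundDensity = 1e-12, flipNoise = 0, seed = 3)
  ## densities 1/~0 make every within-block cell 1 and the rest 0
  sim <- generatePlanted(cfg)
  X <- as.matrix(sim$X)
  for (c in 1:3) {
    mi <- truthModules(sim$truth, "microbe")[[c]]
    di <- truthModules(sim$truth, "disease")[[c]]
    expect_true(all(X[mi, di] == 1))
  }
  off <- X
  for (c in 1:3)
    off[truthModules(sim$truth, "microbe")[[c]],
        truthModules(sim$truth, "disease")[[c]]] <- NA
  expect_true(all(off == 0, na.rm = TRUE))
})

test_that("generation is reproducible from the seed", {
  cfg <- plantedConfig(nM = 15, nD = 8, kTrue = 3, seed = 99)
  a <- generatePlanted(cfg)
  b <- generatePlanted(cfg)
  expect_identical(as.matrix(a$X), as.matrix(b$X))
  expect_identical(as.matrix(a$phylo), as.matrix(b$phylo))
  expect_identical(taxonSets(a$taxonSets), taxonSets(b$taxonSets))
  expect_identical(a$truth@microbeAssignments, b$truth@microbeAssignments)
  c <- generatePlanted(plantedConfig(nM = 15, nD = 8, kTrue = 3, seed = 100))
  expect_false(identical(as.matrix(a$X), as.matrix(c$X)))
})

test_that("within-block density matches its closed-form expectation", {
  cfg <- plantedConfig(nM = 120, nD = 40, kTrue = 4, withinDensity = 0.8,
                       backgroundDensity = 0.05, flipNoise = 0.02, seed = 17)
  sim <- generatePlanted(cfg)
  X <- as.matrix(sim$X)
  cells <- 0; ones <- 0
  for (c in 1:4) {
    mi <- truthModules(sim$truth, "microbe")[[c]]
    di <- truthModules(sim$truth, "disease")[[c]]
    cells <- cells + length(mi) * length(di)
    ones <- ones + sum(X[mi, di])
  }
  pExp <- 0.8 * (1 - 0.02) + (1 - 0.8) * 0.02
  sdBin <- sqrt(pExp * (1 - pExp) / cells)
  expect_lt(abs(ones / cells - pExp), 3 * sdBin)
})

test_that("generator outputs satisfy reader-side invariants end-to-end", {
  sim <- generatePlanted(plantedConfig(nM = 12, nD = 8, kTrue = 3, seed = 5))
  dir <- withr::local_tempdir()
  writeAssociationTable(sim$X, file.path(dir, "x.tsv"))
  writeSquareMatrix(sim$phylo, file.path(dir, "p.tsv"))
  writeSquareMatrix(sim$symptom, file.path(dir, "s.tsv"))
  writeGMT(sim$taxonSets, file.path(dir, "t.gmt"))
  expect_identical(as.matrix(readAssociationTable(file.path(dir, "x.tsv"))),
                   as.matrix(sim$X))
  expect_equal(as.matrix(readSquareMatrix(file.path(dir, "p.tsv"), "distance")),
               as.matrix(sim$phylo), tolerance = 1e-12)
  expect_equal(as.matrix(readSquareMatrix(file.path(dir, "s.tsv"), "similarity")),
               as.matrix(sim$symptom), tolerance = 1e-12)
  expect_identical(lapply(taxonSets(readGMT(file.path(dir, "t.gmt"))), sort),
                   lapply(taxonSets(sim$taxonSets), sort))
})

test_that("invalid planted configurations are rejected", {
  expect_error(plantedConfig(nM = 10, nD = 4, kTrue = 4), "kTrue")
  expect_error(plantedConfig(withinDensity = 0.05, backgroundDensity = 0.8),
               "withinDensity")
  expect_error(plantedConfig(phyloWithin = 0.9, phyloBetween = 0.2),
               "phyloWithin")
})

test_that("recovery score is matching-invariant and matches brute force", {
  tru <- list(c("a", "b"), c("c", "d"), c("e"), c("f", "g"))
  expect_equal(recoveryScore(tru, tru), 1)
  expect_equal(recoveryScore(tru[c(3, 1, 4, 2)], tru), 1)

  set.seed(33)
  for (rep in 1:10) {
    pred <- lapply(1:4, function(i) sample(letters[1:7], sample(0:3, 1)))
    expect_equal(recoveryScore(pred, tru), bruteBestF1(pred, tru))
  }
})

test_that("recovery degrades on average as flip noise grows", {
  score <- function(noise, seed) {
    sim <- generatePlanted(plantedConfig(nM = 60, nD = 20, kTrue = 4,
                                         flipNoise = noise, seed = seed))
    fit <- fitBaseline(sim$X, "netnmf",
                       hyper = mdnmfHyper(k = 4, restarts = 3, maxIter = 150,
                                          seed = seed))
    ms <- extractModules(factorH1(fit), 1.5, "microbe")
    recoveryScore(ms, sim$truth, "microbe")
  }
  lo <- mean(sapply(1:10, function(s) score(0.02, s)))
  hi <- mean(sapply(1:10, function(s) score(0.10, s)))
  expect_lte(hi, lo)
})
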