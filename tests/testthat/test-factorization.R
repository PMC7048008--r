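makeState <- function(H1, H2, S1, S2, ins, hyper, model = "mdnmf") {
  new("FactorizationState", H1 = H1, H2 = H2, S1 = S1, S2 = S2,
      objectiveTrace = numeric(0), hyper = hyper, model = model,
      inputs = ins)
}

## exact tri-factorization with orthonormal block-indicator columns
exactInstance <- function(nM = 12, nD = 8, k = 4, seed = 1) {
  set.seed(seed)
  blockIndicator <- function(n, k) {
    g <- rep(seq_len(k), length.out = n)
    H <- matrix(0, n, k)
    for (c in seq_len(k)) H[g == c, c] <- 1 / sqrt(sum(g == c))
    H
  }
  H1 <- blockIndicator(nM, k)
  H2 <- blockIndicator(nD, k)
  A <- matrix(runif(k * k), k, k); S1 <- (A + t(A)) / 2
  A <- matrix(runif(k * k), k, k); S2 <- (A + t(A)) / 2
  list(H1 = H1, H2 = H2, S1 = S1, S2 = S2,
       MS = H1 %*% S1 %*% t(H1), DS = H2 %*% S2 %*% t(H2),
       X = H1 %*% t(H2))
}

test_that("restart initialization is reproducible and restart-specific", {
  h <- mdnmfHyper(k = 3, seed = 5)
  a <- initializeFactors(10, 6, h, restartIndex = 2L)
  b <- initializeFactors(10, 6, h, restartIndex = 2L)
  c <- initializeFactors(10, 6, h, restartIndex = 3L)
  expect_identical(a@H1, b@H1)
  expect_identical(a@S2, b@S2)
  expect_false(identical(a@H1, c@H1))
  expect_true(all(a@H1 >= 0) && all(is.finite(a@H1)))
  expect_lt(max(abs(a@S1 - t(a@S1))), 1e-15)
})

test_that("objective value matches a term-by-term brute-force evaluation", {
  set.seed(21)
  nM <- 8; nD <- 4; k <- 2
  X <- matrix(rbinom(nM * nD, 1, 0.4), nM, nD)
  MS <- as.matrix(randomSimilarity(nM))
  DS <- as.matrix(randomSimilarity(nD))
  W1 <- as.matrix(randomSimilarity(nM))
  W2 <- as.matrix(randomSimilarity(nD))
  H1 <- matrix(runif(nM * k), nM, k); H2 <- matrix(runif(nD * k), nD, k)
  A <- matrix(runif(k * k), k, k); S1 <- (A + t(A)) / 2
  A <- matrix(runif(k * k), k, k); S2 <- (A + t(A)) / 2
  h <- mdnmfHyper(k = k, lambda1 = 1.7, lambda2 = 0.6, mu = 0.05)
  st <- makeState(H1, H2, S1, S2,
                  list(MS = MS, DS = DS, X = X, Wphylo = W1, Wsymptom = W2),
                  h)
  expect_equal(objectiveValue(st),
               bruteObjective(H1, H2, S1, S2, MS, DS, X, 1.7, 0.6, 0.05,
                              W1, W2),
               tolerance = 1e-10)

  ## all-zero factors with mu = 0: the three data norms remain
  z1 <- matrix(0, nM, k); z2 <- matrix(0, nD, k); zk <- matrix(0, k, k)
  h0 <- mdnmfHyper(k = k, lambda1 = 1.7, lambda2 = 0.6, mu = 0)
  st0 <- makeState(z1, z2, zk, zk, list(MS = MS, DS = DS, X = X), h0)
  expect_equal(objectiveValue(st0),
               sum(MS^2) + 1.7 * sum(X^2) + 0.6 * sum(DS^2))

  ## exact planted factorization with mu = 0: objective 0
  ex <- exactInstance()
  hx <- mdnmfHyper(k = 4, lambda1 = 1, lambda2 = 1, mu = 0)
  stx <- makeState(ex$H1, ex$H2, ex$S1, ex$S2,
                   list(MS = ex$MS, DS = ex$DS, X = ex$X), hx)
  expect_lt(objectiveValue(stx), 1e-20)
})

test_that("S update fixes exact factorizations, keeps zeros, descends", {
  ex <- exactInstance(seed = 3)
  expect_equal(updateS(ex$S1, ex$H1, ex$MS), ex$S1, tolerance = 1e-10)

  ## multiplicative form: zero entries stay zero
  S0 <- ex$S1; S0[1, 2] <- S0[2, 1] <- 0
  expect_identical(updateS(S0, ex$H1, ex$MS)[1, 2], 0)

  ## one update strictly reduces the symmetric reconstruction error
  set.seed(14)
  for (rep in 1:5) {
    H <- matrix(runif(6 * 2), 6, 2)
    A <- as.matrix(randomSimilarity(6))
    S <- matrix(runif(4), 2, 2); S <- (S + t(S)) / 2
    before <- sum((A - H %*% S %*% t(H))^2)
    S2 <- updateS(S, H, A)
    expect_lt(sum((A - H %*% S2 %*% t(H))^2), before)
  }
})

test_that("H updates fix exact factorizations and preserve zeros", {
  ex <- exactInstance(seed = 6)
  h <- mdnmfHyper(k = 4, lambda1 = 2.5, lambda2 = 1.3, mu = 0)
  st <- makeState(ex$H1, ex$H2, ex$S1, ex$S2,
                  list(MS = ex$MS, DS = ex$DS, X = ex$X), h)
  expect_equal(updateH1(st), ex$H1, tolerance = 1e-10)
  expect_equal(updateH2(st), ex$H2, tolerance = 1e-10)
  ## block indicators are full of structural zeros: all preserved
  expect_true(all(updateH1(st)[ex$H1 == 0] == 0))
})

test_that("transposing the whole problem swaps the roles of H1 and H2", {
  set.seed(31)
  nM <- 9; nD <- 6; k <- 3
  X <- matrix(rbinom(nM * nD, 1, 0.4), nM, nD)
  MS <- as.matrix(randomSimilarity(nM)); DS <- as.matrix(randomSimilarity(nD))
  W1 <- as.matrix(randomSimilarity(nM)); W2 <- as.matrix(randomSimilarity(nD))
  H1 <- matrix(runif(nM * k), nM, k); H2 <- matrix(runif(nD * k), nD, k)
  A <- matrix(runif(k * k), k, k); S1 <- (A + t(A)) / 2
  A <- matrix(runif(k * k), k, k); S2 <- (A + t(A)) / 2
  lam <- 1.4
  ## lambda2 = 1 makes the two sides exactly symmetric under transposition
  h <- mdnmfHyper(k = k, lambda1 = lam, lambda2 = 1, mu = 0.07)
  fwd <- makeState(H1, H2, S1, S2,
                   list(MS = MS, DS = DS, X = X, Wphylo = W1, Wsymptom = W2), h)
  swp <- makeState(H2, H1, S2, S1,
                   list(MS = DS, DS = MS, X = t(X), Wphylo = W2,
                        Wsymptom = W1), h)
  expect_equal(updateH2(fwd), updateH1(swp), tolerance = 1e-12)
})

test_that("descent mode is monotone and selection picks the argmin restart", {
  set.seed(77)
  sim <- generatePlanted(plantedConfig(nM = 30, nD = 12, kTrue = 4, seed = 4))
  h <- mdnmfHyper(k = 4, mu = 0.01, restarts = 3, maxIter = 120,
                  tol = 1e-12, seed = 2)
  fit <- mdnmfFit(sim$X, phylo = sim$phylo, symptom = sim$symptom, hyper = h)
  finals <- finalObjectives(fit)
  expect_equal(fit@selectedRestart, which.min(finals))
  tr <- objectiveTrace(fit)
  expect_true(all(diff(tr) <= 1e-9 * pmax(head(tr, -1), 1)))
  st <- bestState(fit)
  expect_true(all(st@H1 >= 0) && all(st@H2 >= 0))
  expect_lt(max(abs(st@S1 - t(st@S1))), 1e-8)
})

test_that("the model nests: mu = 0 reproduces NetNMF seed-for-seed", {
  sim <- generatePlanted(plantedConfig(nM = 24, nD = 10, kTrue = 3, seed = 6))
  h <- mdnmfHyper(k = 4, mu = 0, restarts = 2, maxIter = 60, seed = 8)
  full <- mdnmfFit(sim$X, phylo = sim$phylo, symptom = sim$symptom, hyper = h)
  net <- fitBaseline(sim$X, "netnmf", hyper = h)
  expect_equal(objectiveTrace(full), objectiveTrace(net))
  expect_equal(finalObjectives(full), finalObjectives(net))
  expect_equal(factorH1(full), factorH1(net))
})

test_that("plain NMF solves a separable rank-revealing toy to near zero", {
  set.seed(9)
  W <- matrix(0, 12, 3); W[cbind(1:12, rep(1:3, each = 4))] <- 1
  H <- matrix(0, 3, 6); H[cbind(rep(1:3, each = 2), 1:6)] <- 1
  X <- BipartiteAssociationMatrix(W %*% H, sprintf("m%02d", 1:12),
                                  sprintf("d%01d", 1:6))
  fit <- fitBaseline(X, "nmf",
                     hyper = mdnmfHyper(k = 3, restarts = 4, maxIter = 2000,
                                        tol = 1e-14, seed = 3))
  expect_lt(min(finalObjectives(fit), na.rm = TRUE), 1e-8)
  tr <- objectiveTrace(fit)
  expect_true(all(diff(tr) <= 1e-9 * pmax(head(tr, -1), 1e-12)))
})

test_that("fitting planted noiseless data reaches the planted optimum", {
  cfg <- plantedConfig(nM = 24, nD = 12, kTrue = 3, withinDensity = 0.999,
                       backgroundDensity = 0.001, flipNoise = 0, seed = 12)
  sim <- generatePlanted(cfg)
  h <- mdnmfHyper(k = 3, mu = 0, restarts = 5, maxIter = 400, seed = 4)
  fit <- fitBaseline(sim$X, "netnmf", hyper = h)

  ## objective at the planted block factors (least-squares optimal S given H)
  Xm <- as.matrix(sim$X)
  tru <- truthModules(sim$truth, "microbe")
  H1 <- sapply(tru, function(s) as.numeric(rownames(Xm) %in% s))
  H1 <- H1 / rep(sqrt(colSums(H1^2)), each = nrow(H1))
  trud <- truthModules(sim$truth, "disease")
  H2 <- sapply(trud, function(s) as.numeric(colnames(Xm) %in% s))
  H2 <- H2 / rep(sqrt(colSums(H2^2)), each = nrow(H2))
  MS <- as.matrix(gipKernel(sim$X, "microbe"))
  DS <- as.matrix(gipKernel(sim$X, "disease"))
  S1 <- t(H1) %*% MS %*% H1
  S2 <- t(H2) %*% DS %*% H2
  l1 <- nrow(Xm) / ncol(Xm); l2 <- l1^2
  planted <- sum((MS - H1 %*% S1 %*% t(H1))^2) +
    l1 * sum((Xm - H1 %*% t(H2))^2) +
    l2 * sum((DS - H2 %*% S2 %*% t(H2))^2)
  expect_lte(min(finalObjectives(fit), na.rm = TRUE), planted + 1e-6)
})

test_that("paper-mode updates run and differ from descent placement", {
  sim <- generatePlanted(plantedConfig(nM = 20, nD = 10, kTrue = 3, seed = 5))
  hd <- mdnmfHyper(k = 3, mu = 0.1, restarts = 1, maxIter = 30, seed = 1,
                   updateMode = "descent")
  hp <- mdnmfHyper(k = 3, mu = 0.1, restarts = 1, maxIter = 30, seed = 1,
                   updateMode = "paper")
  fd <- mdnmfFit(sim$X, phylo = sim$phylo, symptom = sim$symptom, hyper = hd)
  fp <- mdnmfFit(sim$X, phylo = sim$phylo, symptom = sim$symptom, hyper = hp)
  expect_false(isTRUE(all.equal(factorH1(fd), factorH1(fp))))
  expect_true(all(factorH1(fp) >= 0))
})
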