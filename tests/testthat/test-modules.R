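test_that("row threshold is mean + t * sample sd", {
  expect_equal(rowThreshold(rep(3, 5), 1.5), 3)        # sd = 0
  expect_equal(rowThreshold(c(1, 2, 3, 4), 0), 2.5)    # t = 0: the mean
  h <- c(1, rep(0, 14))                                # one-hot, k = 15
  expect_equal(rowThreshold(h, 1.5), mean(h) + 1.5 * sd(h))
  expect_gt(1, rowThreshold(h, 1.5))                   # the single 1 passes
  expect_error(rowThreshold(1, 1.5), "k >= 2")
})

test_that("module extraction agrees with a brute-force per-row loop", {
  set.seed(19)
  for (rep in 1:8) {
    n <- sample(5:20, 1); k <- sample(3:8, 1)
    H <- matrix(runif(n * k), n, k,
                dimnames = list(sprintf("r%02d", 1:n), NULL))
    ms <- extractModules(H, t = 1.5, side = "microbe")
    expect_identical(unname(memberships(ms)), bruteExtract(H, 1.5))
  }
})

test_that("thresholding is strict, scale-equivariant, anti-monotone in t", {
  H <- rbind(const = rep(0.4, 5),
             hot = c(1, 0, 0, 0, 0),
             mix = c(0.9, 0.8, 0.1, 0.1, 0.1))
  ms <- extractModules(H, t = 1.5)
  expect_false("const" %in% unlist(memberships(ms)))   # ties excluded
  expect_true("hot" %in% memberships(ms)[[1]])

  ## scaling a row leaves its membership unchanged
  H2 <- H; H2["hot", ] <- H["hot", ] * 37.5
  expect_identical(memberships(extractModules(H2, 1.5)),
                   memberships(extractModules(H, 1.5)))

  ## raising t never adds members
  set.seed(23)
  H <- matrix(runif(60), 12, 5)
  for (tPair in list(c(0.5, 1), c(1, 1.5), c(1.5, 2.5))) {
    lo <- memberships(extractModules(H, tPair[1]))
    hi <- memberships(extractModules(H, tPair[2]))
    for (c in seq_along(lo)) expect_true(all(hi[[c]] %in% lo[[c]]))
  }
})

test_that("planted block indicators are recovered exactly at zero noise", {
  set.seed(2)
  k <- 5; n <- 20
  g <- rep(1:k, each = 4)
  H <- matrix(0, n, k, dimnames = list(sprintf("m%02d", 1:n), NULL))
  H[cbind(1:n, g)] <- runif(n, 0.5, 1.5)
  ms <- extractModules(H, 1.5)
  for (c in 1:k)
    expect_setequal(memberships(ms)[[c]], sprintf("m%02d", which(g == c)))
})

test_that("module links sort S off-diagonals and expose cohesion", {
  expect_identical(nrow(moduleLinks(diag(3))$links[
    moduleLinks(diag(3))$links$weight > 0, ]), 0L)

  ## the strongest off-diagonal names the top link pair
  k <- 10
  S <- matrix(0.1, k, k); diag(S) <- 3
  S[4, 7] <- S[7, 4] <- 2.72
  ml <- moduleLinks(S)
  expect_equal(unlist(ml$links[1, c("a", "b")]), c(a = 4, b = 7))
  expect_equal(ml$links$weight[1], 2.72)
  expect_equal(ml$cohesion, diag(S))
  expect_true(all(diff(ml$links$weight) <= 0))
})

test_that("orthonormal block indicators reduce S to normalized block sums", {
  set.seed(40)
  for (rep in 1:5) {
    n <- 6; k <- 4
    g <- sample(rep(1:2, each = 3)); gd <- sample(rep(1:2, 2))
    X <- matrix(rbinom(n * k, 1, 0.5), n, k)
    Cm <- split(seq_len(n), g); Cd <- split(seq_len(k), gd)
    ## mean-indicator columns h_l = 1_{C_l} / n_l
    H1 <- sapply(Cm, function(ix) as.numeric(seq_len(n) %in% ix) / length(ix))
    H2 <- sapply(Cd, function(ix) as.numeric(seq_len(k) %in% ix) / length(ix))
    S <- t(H1) %*% X %*% H2
    brute <- outer(seq_along(Cm), seq_along(Cd), Vectorize(function(l, m) {
      s <- 0
      for (i in Cm[[l]]) for (j in Cd[[m]]) s <- s + X[i, j]
      s / (length(Cm[[l]]) * length(Cd[[m]]))
    }))
    expect_equal(S, brute, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("co-modules pair same-index columns with symmetric links", {
  mm <- new("ModuleSet", memberships = list(c("m1", "m2"), c("m3")),
            side = "microbe", t = 1.5)
  dm <- new("ModuleSet", memberships = list(c("d1"), character(0)),
            side = "disease", t = 1.5)
  S1 <- matrix(c(2, 0.5, 0.5, 3), 2, 2)
  S2 <- matrix(c(1, 0.8, 0.8, 2), 2, 2)
  cms <- assembleComodules(mm, dm, S1, S2)
  expect_length(cms, 2)
  expect_identical(cms[[1]]@microbeMembers, c("m1", "m2"))
  expect_identical(cms[[1]]@diseaseMembers, "d1")
  expect_identical(cms[[2]]@diseaseMembers, character(0))  # empty side ok

  ## link symmetry: weight of (1 -> 2) equals (2 -> 1)
  w12 <- cms[[1]]@links$weight[cms[[1]]@links$other == 2]
  w21 <- cms[[2]]@links$weight[cms[[2]]@links$other == 1]
  expect_equal(w12, w21)
  expect_equal(w12, 0.8)

  dm3 <- new("ModuleSet", memberships = list("d1", "d2", "d3"),
             side = "disease", t = 1.5)
  expect_error(assembleComodules(mm, dm3, S1, S2), "disagree on k")
})
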