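## Independent oracles used across the suite: deliberately written as naive
## loops/enumerations, never sharing code with the package internals.

## elementwise GIP kernel by explicit double loop
bruteGip <- function(X, axis = "microbe", gammaPrime = 1) {
  P <- if (axis == "microbe") X else t(X)
  n <- nrow(P)
  gamma <- gammaPrime / (mean(sapply(seq_len(n), function(i) sum(P[i, ]^2))))
  K <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
  K
}

## term-by-term objective with explicit Laplacian construction
bruteObjective <- function(H1, H2, S1, S2, MS, DS, X, l1, l2, mu,
                           W1 = NULL, W2 = NULL) {
  fro2 <- function(M) sum(diag(t(M) %*% M))
  v <- fro2(MS - H1 %*% S1 %*% t(H1)) +
    l1 * fro2(X - H1 %*% t(H2)) +
    l2 * fro2(DS - H2 %*% S2 %*% t(H2))
  if (mu > 0) {
    if (!is.null(W1)) {
      L1 <- diag(rowSums(W1)) - W1
      v <- v + mu * sum(diag(t(H1) %*% L1 %*% H1))
    }
    if (!is.null(W2)) {
      L2 <- diag(rowSums(W2)) - W2
      v <- v + mu * sum(diag(t(H2) %*% L2 %*% H2))
    }
  }
  v
}

## exhaustive hypergeometric tail: enumerate all C(universe, module) draws
enumHypergeomTail <- function(overlap, setSize, moduleSize, universeSize) {
  if (moduleSize == 0) return(as.numeric(overlap <= 0))
  draws <- utils::combn(universeSize, moduleSize)
  inSet <- colSums(draws <= setSize)   # set = labels 1..setSize
  mean(inSet >= overlap)
}

## per-row threshold rule applied by explicit loop
bruteExtract <- function(H, t) {
  k <- ncol(H)
  out <- vector("list", k)
  for (c in seq_len(k)) {
    members <- character(0)
    for (f in seq_len(nrow(H))) {
      m <- sum(H[f, ]) / k
      s <- sqrt(sum((H[f, ] - m)^2) / (k - 1))
      if (H[f, c] > m + t * s) members <- c(members, rownames(H)[f])
    }
    out[[c]] <- members
  }
  out
}

## mean F1 of the best of all k! pairings, explicit loop over permutations
bruteBestF1 <- function(pred, tru) {
  k <- length(tru)
  f1 <- function(a, b) {
    if (!length(a) && !length(b)) return(1)
    if (!length(a) || !length(b)) return(0)
    tp <- length(intersect(a, b))
    if (!tp) return(0)
    2 * (tp / length(a)) * (tp / length(b)) / (tp / length(a) + tp / length(b))
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, mean(mapply(function(i, j) f1(pred[[i]], tru[[j]]),
                                  p, seq_len(k))))
  best
}

## random labeled binary association fixture
randomAssociation <- function(nM, nD, density = 0.3) {
  repeat {
    m <- matrix(rbinom(nM * nD, 1, density), nM, nD)
    if (any(m != 0)) break
  }
  BipartiteAssociationMatrix(m, sprintf("m%02d", seq_len(nM)),
                             sprintf("d%02d", seq_len(nD)))
}

## random symmetric similarity with unit diagonal
randomSimilarity <- function(n, labels = sprintf("x%02d", seq_len(n))) {
  A <- matrix(runif(n * n), n, n)
  S <- (A + t(A)) / 2
  diag(S) <- 1
  LabeledSquareMatrix(S, kind = "similarity", labels = labels)
}
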