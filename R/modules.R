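## Soft-clustering module extraction and co-module assembly.

#' Row-wise soft-clustering threshold
#'
#' For a row h of a factor matrix, the membership threshold is
#' \deqn{Th(f) = \mu(f) + t\,\sigma(f)} with \eqn{\mu(f)} the row mean over
#' its k entries and \eqn{\sigma(f)} the sample standard deviation (divisor
#' k - 1). A row joins module c when its c-th loading strictly exceeds
#' Th(f); since both statistics scale with the row, membership is invariant
#' to rescaling a row by any positive factor.
#'
#' @param h nonnegative numeric vector of length k >= 2.
#' @param t threshold multiplier (default 1.5).
#' @return the scalar threshold.
#' @export
rowThreshold <- function(h, t = 1.5) {
  if (length(h) < 2L) stop("need k >= 2 entries to form a threshold")
  mean(h) + t * stats::sd(h)
}

#' Extract soft modules from a factor matrix
#'
#' Row f belongs to module c iff `H[f, c] > rowThreshold(H[f, ], t)`
#' (strict). A row may join several modules or none; a constant row joins
#' none. Modules may be empty.
#'
#' @param H nonnegative factor matrix with entity rownames (n-by-k).
#' @param t threshold multiplier.
#' @param side `"microbe"` or `"disease"`.
#' @return a [ModuleSet-class].
#' @export
extractModules <- function(H, t = 1.5, side = c("microbe", "disease")) {
  side <- match.arg(side)
  if (min(H) < 0) stop("H must be nonnegative")
  if (is.null(rownames(H))) rownames(H) <- as.character(seq_len(nrow(H)))
  th <- rowMeans(H) + t * apply(H, 1, stats::sd)
  memberships <- lapply(seq_len(ncol(H)), function(c)
    rownames(H)[H[, c] > th])
  names(memberships) <- as.character(seq_len(ncol(H)))
  new("ModuleSet", memberships = memberships, side = side, t = t)
}

#' Inter-module links from a central matrix
#'
#' In the tri-factorization \eqn{A \approx H S H^T}, the off-diagonal
#' \eqn{S_{cc'}} weights the outer product of indicator columns c and c',
#' so a large off-diagonal marks a strong connection between the two
#' modules; the diagonal measures within-module cohesion (for orthonormal
#' block indicators, S reduces to normalized within/between block sums of
#' A).
#'
#' @param S nonnegative symmetric k-by-k matrix.
#' @return a list with `links` (data.frame `a`, `b`, `weight` over all
#'   unordered pairs, descending weight) and `cohesion` (the diagonal).
#' @export
moduleLinks <- function(S) {
  S <- as.matrix(S)
  if (min(S) < 0) stop("S must be nonnegative")
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  k <- nrow(S)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  links <- data.frame(a = idx[, 1], b = idx[, 2], weight = S[idx])
  links <- links[order(-links$weight, links$a, links$b), , drop = FALSE]
  rownames(links) <- NULL
  list(links = links, cohesion = diag(S))
}

#' Pair microbe and disease modules into co-modules
#'
#' The association coupling term binds column c of H1 to column c of H2, so
#' co-module c pairs the c-th microbe module with the c-th disease module.
#' Link lists come from the off-diagonals of S2 (disease-level connections,
#' the ones the co-module tables report), with the S1 weights recorded in
#' the `weightS1` column. Either side of a co-module may be empty.
#'
#' @param microbeModules,diseaseModules [ModuleSet-class] objects built
#'   from the same k.
#' @param S1,S2 central matrices of the fit.
#' @return list of [CoModule-class], one per factor column.
#' @export
assembleComodules <- function(microbeModules, diseaseModules, S1, S2) {
  stopifnot(is(microbeModules, "ModuleSet"), is(diseaseModules, "ModuleSet"))
  k <- length(microbeModules@memberships)
  if (length(diseaseModules@memberships) != k)
    stop("module sets disagree on k")
  S1 <- as.matrix(S1); S2 <- as.matrix(S2)
  if (!identical(dim(S2), c(k, k)) || !identical(dim(S1), c(k, k)))
    stop("S matrices must be k-by-k")
  lapply(seq_len(k), function(c) {
    others <- setdiff(seq_len(k), c)
    lk <- data.frame(other = others, weight = S2[c, others],
                     weightS1 = S1[c, others])
    lk <- lk[order(-lk$weight, lk$other), , drop = FALSE]
    rownames(lk) <- NULL
    new("CoModule", index = as.integer(c),
        microbeMembers = microbeModules@memberships[[c]],
        diseaseMembers = diseaseModules@memberships[[c]],
        links = lk)
  })
}

#' Extract modules and co-modules from a fit in one call
#'
#' Convenience wrapper: applies [extractModules()] to H1 and H2 of the best
#' state and assembles the co-modules with S1/S2 links.
#'
#' @param fit a [FitResult-class] or [FactorizationState-class].
#' @param t threshold multiplier.
#' @return list with `microbeModules`, `diseaseModules`, `comodules`.
#' @export
comodulesFromFit <- function(fit, t = 1.5) {
  state <- if (is(fit, "FitResult")) fit@bestState else fit
  mm <- extractModules(state@H1, t = t, side = "microbe")
  dm <- extractModules(state@H2, t = t, side = "disease")
  list(microbeModules = mm, diseaseModules = dm,
       comodules = assembleComodules(mm, dm, state@S1, state@S2))
}
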