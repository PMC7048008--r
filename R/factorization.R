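## Multiplicative-update solvers for the graph-regularized tri-factorization
## and its two baselines (plain NMF, NetNMF).

.EPS <- 1e-12  # floor under every multiplicative denominator

.restartSeed <- function(seed, restartIndex) {
  as.integer(((abs(as.numeric(seed)) %% 2147483647) * 1009 +
                restartIndex) %% 2147483647)
}

.resolveLambdas <- function(hyper, nM, nD) {
  if (is.na(hyper@lambda1)) hyper@lambda1 <- nM / nD
  if (is.na(hyper@lambda2)) hyper@lambda2 <- (nM / nD)^2
  hyper
}

#' Random initialization of one restart
#'
#' H1 and H2 are drawn i.i.d. Uniform(0, 1); S1 and S2 are symmetrized
#' Uniform(0, 1) draws, `(A + t(A))/2`. The RNG stream is derived
#' deterministically from `(seed, restartIndex)` so every restart of the
#' multi-restart protocol is individually reproducible.
#'
#' @param nM,nD numbers of microbes and diseases.
#' @param hyper a [Hyperparameters-class] (uses `k` and `seed`).
#' @param restartIndex 1-based restart number.
#' @param inputs optional named list of input matrices to carry in the
#'   state (`MS`, `DS`, `X`, optionally `Wphylo`, `Wsymptom`).
#' @param model objective this state belongs to.
#' @return a [FactorizationState-class] with an empty objective trace.
#' @export
initializeFactors <- function(nM, nD, hyper, restartIndex = 1L,
                              inputs = list(), model = "mdnmf") {
  k <- hyper@k
  if (k >= min(nM, nD)) stop("k must be smaller than min(nM, nD)")
  runif <- stats::runif
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.restartSeed(hyper@seed, restartIndex))
  H1 <- matrix(runif(nM * k), nM, k)
  H2 <- matrix(runif(nD * k), nD, k)
  A <- matrix(runif(k * k), k, k); S1 <- (A + t(A)) / 2
  A <- matrix(runif(k * k), k, k); S2 <- (A + t(A)) / 2
  if (!is.null(inputs$X)) {
    rownames(H1) <- rownames(inputs$X)
    rownames(H2) <- colnames(inputs$X)
  }
  if (model == "nmf") { S1 <- diag(k); S2 <- diag(k) }
  new("FactorizationState", H1 = H1, H2 = H2, S1 = S1, S2 = S2,
      objectiveTrace = numeric(0), hyper = hyper, model = model,
      inputs = inputs)
}

.traceQuad <- function(H, L) sum(H * (L %*% H))

.objective <- function(H1, H2, S1, S2, ins, lambda1, lambda2, mu, model) {
  if (model == "nmf")
    return(sum((ins$X - tcrossprod(H1, H2))^2))
  v <- sum((ins$MS - H1 %*% tcrossprod(S1, H1))^2) +
    lambda1 * sum((ins$X - tcrossprod(H1, H2))^2) +
    lambda2 * sum((ins$DS - H2 %*% tcrossprod(S2, H2))^2)
  if (model == "mdnmf" && mu > 0) {
    if (!is.null(ins$L1)) v <- v + mu * .traceQuad(H1, ins$L1)
    if (!is.null(ins$L2)) v <- v + mu * .traceQuad(H2, ins$L2)
  }
  v
}

#' Objective value of a factorization state
#'
#' For the full model this is
#' \deqn{\|MS - H_1 S_1 H_1^T\|_F^2 + \lambda_1 \|X - H_1 H_2^T\|_F^2 +
#'   \lambda_2 \|DS - H_2 S_2 H_2^T\|_F^2 +
#'   \mu(\mathrm{tr}(H_1^T L_1 H_1) + \mathrm{tr}(H_2^T L_2 H_2)),}
#' for `model = "netnmf"` the same without the Laplacian term, and for
#' `model = "nmf"` simply \eqn{\|X - H_1 H_2^T\|_F^2}.
#'
#' @param state a [FactorizationState-class] carrying its inputs.
#' @return the scalar objective.
#' @export
objectiveValue <- function(state) {
  stopifnot(is(state, "FactorizationState"))
  h <- state@hyper
  ins <- .withLaplacians(state@inputs)
  v <- .objective(state@H1, state@H2, state@S1, state@S2, ins,
                  h@lambda1, h@lambda2, h@mu, state@model)
  if (!is.finite(v)) stop("non-finite objective value")
  v
}

.withLaplacians <- function(ins) {
  if (!is.null(ins$Wphylo) && is.null(ins$L1)) {
    ins$d1 <- rowSums(ins$Wphylo)
    ins$L1 <- diag(ins$d1, nrow = length(ins$d1)) - ins$Wphylo
  }
  if (!is.null(ins$Wsymptom) && is.null(ins$L2)) {
    ins$d2 <- rowSums(ins$Wsymptom)
    ins$L2 <- diag(ins$d2, nrow = length(ins$d2)) - ins$Wsymptom
  }
  ins
}

#' Multiplicative update of a central matrix S
#'
#' \deqn{S_{ij} \leftarrow S_{ij} \frac{(H^T A H)_{ij}}
#'   {(H^T H\, S\, H^T H)_{ij}}}
#' with the denominator floored at 1e-12. Applied to S1 with
#' `(A = MS, H = H1)` and to S2 with `(A = DS, H = H2)`; the lambda2 weight
#' of the disease term cancels between numerator and denominator.
#'
#' @param S current k-by-k nonnegative matrix.
#' @param H current factor matrix.
#' @param A the symmetric similarity matrix being tri-factorized.
#' @return the updated S.
#' @export
updateS <- function(S, H, A) {
  if (is(A, "LabeledSquareMatrix")) A <- A@values
  HtH <- crossprod(H)
  S * (t(H) %*% A %*% H) / pmax(HtH %*% S %*% HtH, .EPS)
}

.updateH <- function(H, S, other, A, Xside, lambda1, lambdaA, mu, W, d,
                     mode) {
  ## generic one-sided update; for the microbe side: A = MS, Xside = X %*% H2,
  ## lambdaA = 1; for the disease side: A = DS, Xside = t(X) %*% H1,
  ## lambdaA = lambda2.
  num <- 2 * lambdaA * (A %*% H %*% S) + lambda1 * Xside
  den <- 2 * lambdaA * (H %*% S %*% crossprod(H) %*% S) +
    lambda1 * H %*% crossprod(other)
  if (mu > 0 && !is.null(W)) {
    if (mode == "descent") {
      num <- num + mu * (W %*% H)
      den <- den + mu * d * H
    } else {
      num <- num + mu * d * H
      den <- den + mu * (W %*% H)
    }
  }
  H * num / pmax(den, .EPS)
}

#' Multiplicative update of the microbe factor H1
#'
#' With `updateMode = "descent"` (the default) the Laplacian penalty is
#' split the standard way for graph-regularized NMF: the similarity part
#' \eqn{\mu\,MS_{phy} H_1} joins the numerator and the degree part
#' \eqn{\mu\,D_1 H_1} the denominator, which makes the update a descent step
#' on the objective. `updateMode = "paper"` applies the opposite placement
#' (degree matrix in the numerator), reproducing the printed update rule of
#' the original description verbatim; that variant is not monotone in the
#' penalized objective.
#'
#' @param state a [FactorizationState-class].
#' @return the updated H1 matrix.
#' @export
updateH1 <- function(state) {
  h <- state@hyper
  ins <- .withLaplacians(state@inputs)
  .updateH(state@H1, state@S1, state@H2, ins$MS, ins$X %*% state@H2,
           h@lambda1, 1,
           if (state@model == "mdnmf") h@mu else 0,
           ins$Wphylo, ins$d1, h@updateMode)
}

#' Multiplicative update of the disease factor H2
#'
#' Mirror of [updateH1()] with the roles (DS, S2, t(X), lambda2, symptom
#' prior) substituted.
#'
#' @param state a [FactorizationState-class].
#' @return the updated H2 matrix.
#' @export
updateH2 <- function(state) {
  h <- state@hyper
  ins <- .withLaplacians(state@inputs)
  .updateH(state@H2, state@S2, state@H1, ins$DS, t(ins$X) %*% state@H1,
           h@lambda1, h@lambda2,
           if (state@model == "mdnmf") h@mu else 0,
           ins$Wsymptom, ins$d2, h@updateMode)
}

.runRestart <- function(ins, hyper, restartIndex, model) {
  k <- hyper@k
  nM <- nrow(ins$X); nD <- ncol(ins$X)
  st <- initializeFactors(nM, nD, hyper, restartIndex, inputs = list(),
                          model = model)
  H1 <- st@H1; H2 <- st@H2; S1 <- st@S1; S2 <- st@S2
  rownames(H1) <- rownames(ins$X); rownames(H2) <- colnames(ins$X)
  mu <- if (model == "mdnmf") hyper@mu else 0
  l1 <- hyper@lambda1; l2 <- hyper@lambda2
  mode <- hyper@updateMode
  trace <- numeric(hyper@maxIter)
  prev <- Inf
  nIter <- 0L
  for (it in seq_len(hyper@maxIter)) {
    if (model == "nmf") {
      ## Lee-Seung updates for X ~ W H with W = H1, H = t(H2)
      H1 <- H1 * (ins$X %*% H2) / pmax(H1 %*% crossprod(H2), .EPS)
      H2 <- H2 * (t(ins$X) %*% H1) / pmax(H2 %*% crossprod(H1), .EPS)
    } else {
      S1 <- updateS(S1, H1, ins$MS)
      S2 <- updateS(S2, H2, ins$DS)
      H1 <- .updateH(H1, S1, H2, ins$MS, ins$X %*% H2, l1, 1,
                     mu, ins$Wphylo, ins$d1, mode)
      H2 <- .updateH(H2, S2, H1, ins$DS, t(ins$X) %*% H1, l1, l2,
                     mu, ins$Wsymptom, ins$d2, mode)
    }
    f <- .objective(H1, H2, S1, S2, ins, l1, l2, mu, model)
    if (!is.finite(f) || anyNA(H1) || anyNA(H2)) {
      return(NULL)  # aborted restart
    }
    nIter <- it
    trace[it] <- f
    if (is.finite(prev) && abs(f - prev) / max(prev, .EPS) < hyper@tol) break
    prev <- f
  }
  new("FactorizationState", H1 = H1, H2 = H2,
      S1 = (S1 + t(S1)) / 2, S2 = (S2 + t(S2)) / 2,
      objectiveTrace = trace[seq_len(nIter)], hyper = hyper, model = model,
      inputs = ins)
}

.fitEngine <- function(ins, hyper, model) {
  hyper <- .resolveLambdas(hyper, nrow(ins$X), ncol(ins$X))
  ins <- .withLaplacians(ins)
  finals <- rep(NA_real_, hyper@restarts)
  best <- NULL
  for (r in seq_len(hyper@restarts)) {
    st <- .runRestart(ins, hyper, r, model)
    if (is.null(st)) {
      warning("restart ", r, " aborted on non-finite factors")
      next
    }
    finals[r] <- utils::tail(st@objectiveTrace, 1)
    if (is.null(best) || finals[r] < finals[best[[1]]]) best <- list(r, st)
  }
  if (is.null(best)) stop("all restarts failed")
  new("FitResult", bestState = best[[2]], allFinalObjectives = finals,
      selectedRestart = as.integer(best[[1]]))
}

.asPriorW <- function(prior, labels) {
  if (is.null(prior)) return(NULL)
  if (is(prior, "LabeledSquareMatrix") && prior@kind == "distance")
    prior <- phyloSimilarity(prior)
  if (!is(prior, "LabeledSquareMatrix"))
    prior <- LabeledSquareMatrix(prior, kind = "similarity")
  alignSimilarity(prior, labels)@values
}

#' Fit the graph-regularized tri-factorization
#'
#' Jointly factorizes the microbe GIP kernel `MS`, the association matrix
#' `X` and the disease GIP kernel `DS` as \eqn{MS \approx H_1 S_1 H_1^T},
#' \eqn{X \approx H_1 H_2^T}, \eqn{DS \approx H_2 S_2 H_2^T}, with Laplacian
#' smoothing of H1 towards phylogenetic closeness and of H2 towards shared
#' symptoms. Each restart alternates the multiplicative updates in the order
#' S1, S2, H1, H2 until the relative objective change drops below `tol` or
#' `maxIter` is reached; the restart with the minimal final objective is
#' returned. Restarts whose factors turn non-finite are excluded with a
#' warning.
#'
#' @param X a [BipartiteAssociationMatrix-class].
#' @param MS,DS optional precomputed similarity matrices; computed as GIP
#'   kernels of `X` when omitted.
#' @param phylo optional microbe prior: a [LabeledSquareMatrix-class] of
#'   kind `"distance"` (converted via [phyloSimilarity()]) or
#'   `"similarity"`. Microbes absent from the prior get zero edge weights.
#' @param symptom optional disease prior similarity, same conventions.
#' @param hyper a [Hyperparameters-class]; when both priors are absent the
#'   Laplacian term is dropped (equivalent to `mu = 0`).
#' @return a [FitResult-class].
#' @seealso [fitBaseline()], [extractModules()], [assembleComodules()]
#' @export
mdnmfFit <- function(X, MS = NULL, DS = NULL, phylo = NULL, symptom = NULL,
                     hyper = mdnmfHyper()) {
  stopifnot(is(X, "BipartiteAssociationMatrix"))
  Xm <- X@values
  if (hyper@k >= min(dim(Xm))) stop("k must be smaller than min(nM, nD)")
  MSm <- if (is.null(MS)) gipKernel(X, "microbe", hyper@gammaM)@values
         else if (is(MS, "LabeledSquareMatrix")) MS@values else as.matrix(MS)
  DSm <- if (is.null(DS)) gipKernel(X, "disease", hyper@gammaD)@values
         else if (is(DS, "LabeledSquareMatrix")) DS@values else as.matrix(DS)
  ins <- list(MS = MSm, DS = DSm, X = Xm,
              Wphylo = .asPriorW(phylo, rownames(Xm)),
              Wsymptom = .asPriorW(symptom, colnames(Xm)))
  if (is.null(ins$Wphylo) && is.null(ins$Wsymptom)) hyper@mu <- 0
  .fitEngine(ins, hyper, "mdnmf")
}

#' Fit a baseline factorization
#'
#' `variant = "nmf"` minimizes \eqn{\|X - W H\|_F^2} with the standard
#' Lee-Seung multiplicative updates (`H1` plays W, `H2` plays \eqn{H^T};
#' S1, S2 are fixed at the identity). `variant = "netnmf"` is the joint
#' tri-factorization without any Laplacian penalty (`mu = 0`), i.e. the
#' model the full method reduces to when the phylogenetic and symptom
#' priors are removed. Both use the same restart/selection protocol as
#' [mdnmfFit()].
#'
#' @param X a [BipartiteAssociationMatrix-class].
#' @param variant `"nmf"` or `"netnmf"`.
#' @param hyper a [Hyperparameters-class].
#' @param MS,DS optional precomputed kernels (netnmf only).
#' @return a [FitResult-class].
#' @export
fitBaseline <- function(X, variant = c("netnmf", "nmf"),
                        hyper = mdnmfHyper(), MS = NULL, DS = NULL) {
  variant <- match.arg(variant)
  stopifnot(is(X, "BipartiteAssociationMatrix"))
  Xm <- X@values
  if (hyper@k >= min(dim(Xm))) stop("k must be smaller than min(nM, nD)")
  if (variant == "nmf") {
    ins <- list(X = Xm)
    return(.fitEngine(ins, hyper, "nmf"))
  }
  MSm <- if (is.null(MS)) gipKernel(X, "microbe", hyper@gammaM)@values
         else if (is(MS, "LabeledSquareMatrix")) MS@values else as.matrix(MS)
  DSm <- if (is.null(DS)) gipKernel(X, "disease", hyper@gammaD)@values
         else if (is(DS, "LabeledSquareMatrix")) DS@values else as.matrix(DS)
  hyper@mu <- 0
  .fitEngine(list(MS = MSm, DS = DSm, X = Xm), hyper, "netnmf")
}
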