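## Similarity matrices and graph Laplacians feeding the factorization.

#' Gaussian interaction-profile (GIP) kernel similarity
#'
#' Similarity between two microbes (or diseases) from their binary
#' association profiles: for the microbe axis,
#' \deqn{MS(i,j) = \exp(-\gamma_m \|X_{i,\cdot} - X_{j,\cdot}\|^2)} with the
#' bandwidth normalized by the mean squared profile norm,
#' \deqn{\gamma_m = \gamma'_m \big/ \frac{1}{n_m}\sum_i \|X_{i,\cdot}\|^2.}
#' The disease axis is the analogous computation over columns. The
#' normalization always uses the matrix actually supplied, so subsetting the
#' data re-derives the bandwidth.
#'
#' @param X a [BipartiteAssociationMatrix-class] (or binary matrix with
#'   dimnames).
#' @param axis `"microbe"` (rows) or `"disease"` (columns).
#' @param gammaPrime positive bandwidth base (default 1).
#' @return a [LabeledSquareMatrix-class] of kind `"similarity"`; symmetric,
#'   unit diagonal, entries in (0, 1].
#' @examples
#' X <- BipartiteAssociationMatrix(diag(2), paste0("m", 1:2), paste0("d", 1:2))
#' as.matrix(gipKernel(X, "microbe"))[1, 2]  # exp(-2)
#' @export
gipKernel <- function(X, axis = c("microbe", "disease"), gammaPrime = 1) {
  axis <- match.arg(axis)
  if (gammaPrime <= 0) stop("gammaPrime must be positive")
  P <- if (is(X, "BipartiteAssociationMatrix")) X@values else as.matrix(X)
  if (axis == "disease") P <- t(P)
  sq <- rowSums(P^2)
  meanSq <- mean(sq)
  if (meanSq == 0)
    stop("degenerate input: all interaction profiles are zero")
  gamma <- gammaPrime / meanSq
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0               # guard fp negatives for identical profiles
  K <- exp(-gamma * D2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(rownames(P), rownames(P))
  new("LabeledSquareMatrix", values = K, kind = "similarity")
}

#' Phylogenetic distance to similarity
#'
#' Converts a pairwise phylogenetic distance matrix (e.g. Kimura
#' 2-parameter distances between 16S sequences) into the similarity prior
#' `MS_phy = 1 - M_phy`. Distances are expected in [0, 1]; a matrix with a
#' larger maximum is rescaled by that maximum first (with a warning) so the
#' graph penalty keeps weights in [0, 1].
#'
#' @param D a [LabeledSquareMatrix-class] of kind `"distance"`.
#' @return a [LabeledSquareMatrix-class] of kind `"similarity"`.
#' @export
phyloSimilarity <- function(D) {
  stopifnot(is(D, "LabeledSquareMatrix"))
  if (D@kind != "distance") stop("expected a distance matrix")
  v <- D@values
  if (min(v) < 0) stop("negative phylogenetic distances")
  mx <- max(v)
  if (mx > 1) {
    warning(sprintf("max distance %.4g > 1; rescaling by the maximum", mx))
    v <- v / mx
  }
  S <- 1 - v
  diag(S) <- 1
  new("LabeledSquareMatrix", values = S, kind = "similarity")
}

#' Cosine similarity between disease symptom profiles
#'
#' Each disease is represented by a vector of symptom-term co-occurrence
#' counts; similarity is the cosine of the angle between two such vectors.
#' A disease with an all-zero profile gets off-diagonal similarity 0 (with
#' a warning) and keeps the unit diagonal.
#'
#' @param counts nonnegative matrix, diseases in rows, symptom terms in
#'   columns, disease labels as rownames.
#' @return a [LabeledSquareMatrix-class] of kind `"similarity"`.
#' @export
cosineSimilarity <- function(counts) {
  counts <- as.matrix(counts)
  if (min(counts) < 0) stop("counts must be nonnegative")
  nrm <- sqrt(rowSums(counts^2))
  zero <- nrm == 0
  if (any(zero))
    warning(sum(zero), " disease(s) with empty symptom profile; ",
            "their similarities are set to 0")
  nrm[zero] <- 1
  S <- tcrossprod(counts / nrm)
  S[zero, ] <- 0
  S[, zero] <- 0
  S[S > 1] <- 1
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rownames(counts), rownames(counts))
  new("LabeledSquareMatrix", values = S, kind = "similarity")
}

#' Graph Laplacian of a similarity matrix
#'
#' Builds \eqn{L = D - W} with \eqn{D_{ii} = \sum_j W_{ij}}; the resulting
#' L is symmetric positive semidefinite with zero row sums.
#'
#' @param W a [LabeledSquareMatrix-class] of kind `"similarity"` or a
#'   symmetric nonnegative matrix.
#' @return a [GraphLaplacian-class].
#' @export
graphLaplacian <- function(W) {
  Wm <- if (is(W, "LabeledSquareMatrix")) W@values else as.matrix(W)
  if (min(Wm) < 0) stop("similarity weights must be nonnegative")
  if (max(abs(Wm - t(Wm))) > 1e-10) stop("W must be symmetric")
  d <- rowSums(Wm)
  L <- diag(d, nrow = nrow(Wm)) - Wm
  dimnames(L) <- dimnames(Wm)
  new("GraphLaplacian", L = L, degree = d, W = Wm)
}

#' Align a prior similarity matrix to a reference label set
#'
#' Prior similarity networks rarely cover every entity of the association
#' matrix (the phylogeny may cover a subset of microbes, the symptom network
#' a subset of diseases). Pairs with no prior information get similarity 0 —
#' a zero edge weight contributes no Laplacian smoothing, which is the
#' neutral choice in a graph penalty — and every diagonal is kept at 1.
#' Coverage is reported via `message()`.
#'
#' @param sim a [LabeledSquareMatrix-class] of kind `"similarity"`.
#' @param labels reference labels, in the order of the association matrix.
#' @return a [LabeledSquareMatrix-class] over `labels`.
#' @export
alignSimilarity <- function(sim, labels) {
  stopifnot(is(sim, "LabeledSquareMatrix"))
  if (sim@kind != "similarity") stop("expected a similarity matrix")
  have <- intersect(labels, rownames(sim@values))
  out <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
  out[have, have] <- sim@values[have, have]
  diag(out) <- 1
  if (length(have) < length(labels))
    message(sprintf("similarity prior covers %d of %d entities; %d without prior get zero weights",
                    length(have), length(labels),
                    length(labels) - length(have)))
  new("LabeledSquareMatrix", values = out, kind = "similarity")
}
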