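#' Construct a BipartiteAssociationMatrix
#'
#' @param values binary matrix (microbes in rows, diseases in columns).
#' @param microbes,diseases optional label vectors; taken from `dimnames`
#'   when omitted.
#' @return a [BipartiteAssociationMatrix-class].
#' @examples
#' X <- matrix(c(1, 0, 0, 1, 1, 1), nrow = 3, byrow = TRUE)
#' BipartiteAssociationMatrix(X, microbes = paste0("m", 1:3),
#'                            diseases = c("d1", "d2"))
#' @export
BipartiteAssociationMatrix <- function(values, microbes = NULL,
                                       diseases = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(microbes)) rownames(values) <- microbes
  if (!is.null(diseases)) colnames(values) <- diseases
  new("BipartiteAssociationMatrix", values = values)
}

#' Construct a LabeledSquareMatrix
#'
#' The matrix is symmetrized as `(A + t(A))/2`; asymmetry beyond `atol`
#' is a hard error (hand-edited or rounded files commonly carry tiny
#' asymmetry, anything larger signals corrupt data).
#'
#' @param values square numeric matrix.
#' @param kind `"distance"` or `"similarity"`.
#' @param labels optional label vector; taken from `dimnames` when omitted.
#' @param atol symmetry tolerance before symmetrization.
#' @return a [LabeledSquareMatrix-class].
#' @export
LabeledSquareMatrix <- function(values, kind = c("similarity", "distance"),
                                labels = NULL, atol = 1e-8) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (max(abs(values - t(values))) > atol)
    stop("matrix asymmetric beyond tolerance ", atol)
  values <- (values + t(values)) / 2
  if (kind == "distance") diag(values) <- 0
  new("LabeledSquareMatrix", values = values, kind = kind)
}

#' Hyperparameters of the MDNMF objective
#'
#' Defaults follow the selected configuration of the method's model
#' selection: rank `k = 15` (from \{10, 15, 20\}), Laplacian weight
#' `mu = 0.001` (from \{0.001, 0.01, 0.1\}), 50 random restarts with the
#' minimum-objective restart kept, GIP bandwidth bases `gammaM = gammaD = 1`,
#' and module threshold multiplier `t = 1.5`. `lambda1`/`lambda2` default to
#' `NA`, meaning they are derived from the association matrix shape at fit
#' time as \eqn{\lambda_1 = n_m/n_d} and \eqn{\lambda_2 = (n_m/n_d)^2},
#' which balances the three reconstruction terms by matrix size.
#'
#' @param k factor rank (number of co-modules); must satisfy
#'   `k < min(n_m, n_d)` for the matrix eventually fitted.
#' @param lambda1,lambda2 weights of the association and disease-similarity
#'   terms, or `NA` to derive from shape.
#' @param mu graph-regularization weight.
#' @param gammaM,gammaD GIP kernel bandwidth bases.
#' @param t module threshold multiplier (mean + t*sd rule).
#' @param maxIter,tol convergence controls (relative objective change).
#' @param restarts number of random restarts.
#' @param seed base seed; restart r uses a stream derived from `(seed, r)`.
#' @param updateMode `"descent"` or `"paper"` (see [updateH1()]).
#' @return a [Hyperparameters-class].
#' @export
mdnmfHyper <- function(k = 15, lambda1 = NA_real_, lambda2 = NA_real_,
                       mu = 0.001, gammaM = 1, gammaD = 1, t = 1.5,
                       maxIter = 500, tol = 1e-6, restarts = 50,
                       seed = 1, updateMode = c("descent", "paper")) {
  new("Hyperparameters", k = as.integer(k), lambda1 = as.numeric(lambda1),
      lambda2 = as.numeric(lambda2), mu = as.numeric(mu),
      gammaM = as.numeric(gammaM), gammaD = as.numeric(gammaD),
      t = as.numeric(t), maxIter = as.integer(maxIter),
      tol = as.numeric(tol), restarts = as.integer(restarts),
      seed = as.integer(seed), updateMode = match.arg(updateMode))
}

#' Construct a TaxonSetCollection
#'
#' @param sets named list of character member vectors.
#' @param source free-text provenance string.
#' @return a [TaxonSetCollection-class].
#' @export
TaxonSetCollection <- function(sets, source = "") {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  new("TaxonSetCollection", sets = sets, source = source)
}

#' Configuration for the planted co-module generator
#'
#' Defaults define a benchmark of 150 microbes by 45 diseases with 5 planted
#' co-modules: association density 0.8 inside a planted block against a 0.05
#' background, 2% flip noise, phylogenetic distances centred at 0.1 within /
#' 0.6 between microbe modules, symptom similarities centred at 0.7 within /
#' 0.1 between disease modules (both drawn with sd 0.05 and truncated to
#' [0, 1]), and no overlapping memberships.
#'
#' @param nM,nD numbers of microbes and diseases.
#' @param kTrue number of planted co-modules.
#' @param withinDensity,backgroundDensity association probability inside /
#'   outside a planted block.
#' @param flipNoise probability of flipping any cell of X.
#' @param phyloWithin,phyloBetween mean phylogenetic distance within /
#'   between planted microbe modules.
#' @param sympWithin,sympBetween mean symptom similarity within / between
#'   planted disease modules.
#' @param overlapFraction fraction of entities planted into a second module.
#' @param seed generator seed.
#' @return a [PlantedConfig-class].
#' @export
plantedConfig <- function(nM = 150, nD = 45, kTrue = 5,
                          withinDensity = 0.8, backgroundDensity = 0.05,
                          flipNoise = 0.02, phyloWithin = 0.1,
                          phyloBetween = 0.6, sympWithin = 0.7,
                          sympBetween = 0.1, overlapFraction = 0,
                          seed = 1) {
  new("PlantedConfig", nM = as.integer(nM), nD = as.integer(nD),
      kTrue = as.integer(kTrue), withinDensity = withinDensity,
      backgroundDensity = backgroundDensity, flipNoise = flipNoise,
      phyloWithin = phyloWithin, phyloBetween = phyloBetween,
      sympWithin = sympWithin, sympBetween = sympBetween,
      overlapFraction = overlapFraction, seed = as.integer(seed))
}
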