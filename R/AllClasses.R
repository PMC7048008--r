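#' @import methods
NULL

.checkLabels <- function(labels, what) {
  if (is.null(labels) || any(is.na(labels)) || any(!nzchar(labels)))
    return(sprintf("%s labels must be non-empty strings", what))
  if (anyDuplicated(labels))
    return(sprintf("duplicate %s labels: %s", what,
                   paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  NULL
}

#' Binary microbe-disease association matrix
#'
#' Wraps a binary matrix \eqn{X \in \{0,1\}^{n_m \times n_d}} whose rows are
#' microbes and columns diseases, with \eqn{X_{ij} = 1} when microbe \eqn{i}
#' has a reported association with disease \eqn{j} (HMDAD-style data).
#'
#' @slot values binary matrix with microbe rownames and disease colnames.
#'
#' @exportClass BipartiteAssociationMatrix
setClass("BipartiteAssociationMatrix",
         slots = c(values = "matrix"),
         validity = function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (nrow(v) < 2L || ncol(v) < 2L)
    return("need at least 2 microbes and 2 diseases")
  if (anyNA(v) || !all(v %in% c(0, 1)))
    return("entries must all be 0 or 1")
  msg <- .checkLabels(rownames(v), "microbe")
  if (!is.null(msg)) return(msg)
  msg <- .checkLabels(colnames(v), "disease")
  if (!is.null(msg)) return(msg)
  TRUE
})

#' Labeled square matrix (distance or similarity)
#'
#' A symmetric labeled square matrix. `kind = "distance"` requires a zero
#' diagonal and nonnegative entries (e.g. pairwise phylogenetic distances);
#' `kind = "similarity"` requires a unit diagonal and entries in [0, 1]
#' (e.g. a Gaussian interaction-profile kernel or a symptom-based cosine
#' similarity).
#'
#' @slot values symmetric numeric matrix with matching row/col names.
#' @slot kind `"distance"` or `"similarity"`.
#'
#' @exportClass LabeledSquareMatrix
setClass("LabeledSquareMatrix",
         slots = c(values = "matrix", kind = "character"),
         validity = function(object) {
  v <- object@values
  if (!is.numeric(v) || nrow(v) != ncol(v)) return("values must be square numeric")
  if (anyNA(v)) return("entries must be finite, no NA")
  if (length(object@kind) != 1L || !object@kind %in% c("distance", "similarity"))
    return("kind must be 'distance' or 'similarity'")
  msg <- .checkLabels(rownames(v), "row")
  if (!is.null(msg)) return(msg)
  if (!identical(rownames(v), colnames(v)))
    return("row and column labels must be identical")
  if (max(abs(v - t(v))) > 1e-10) return("matrix not symmetric within 1e-10")
  if (object@kind == "distance") {
    if (max(abs(diag(v))) > 1e-10) return("distance matrix must have zero diagonal")
    if (min(v) < 0) return("distance entries must be nonnegative")
  } else {
    if (max(abs(diag(v) - 1)) > 1e-8) return("similarity matrix must have unit diagonal")
    if (min(v) < 0 || max(v) > 1 + 1e-8) return("similarity entries must lie in [0, 1]")
  }
  TRUE
})

#' Graph Laplacian of a similarity matrix
#'
#' Holds \eqn{L = D - W} where \eqn{W} is a symmetric nonnegative similarity
#' and \eqn{D_{ii} = \sum_j W_{ij}} its degree matrix; used as the smoothing
#' penalty \eqn{\mu\,\mathrm{tr}(H^T L H)} in the factorization objective.
#'
#' @slot L Laplacian matrix.
#' @slot degree numeric vector of row sums of `W`.
#' @slot W the underlying similarity matrix.
#'
#' @exportClass GraphLaplacian
setClass("GraphLaplacian",
         slots = c(L = "matrix", degree = "numeric", W = "matrix"),
         validity = function(object) {
  if (!identical(dim(object@L), dim(object@W)))
    return("L and W must have the same shape")
  if (length(object@degree) != nrow(object@W))
    return("degree length must match W")
  if (max(abs(rowSums(object@L))) > 1e-8) return("rows of L must sum to 0")
  if (max(abs(object@L - t(object@L))) > 1e-10) return("L must be symmetric")
  TRUE
})

#' Hyperparameters of the tri-factorization
#'
#' @slot k factor rank (number of co-modules).
#' @slot lambda1,lambda2 weights of the association and disease-similarity
#'   terms; `NA` means "derive from matrix shape at fit time"
#'   (\eqn{\lambda_1 = n_m/n_d}, \eqn{\lambda_2 = (n_m/n_d)^2}).
#' @slot mu graph-regularization weight.
#' @slot gammaM,gammaD bandwidth bases of the microbe/disease GIP kernels.
#' @slot t module-extraction threshold multiplier.
#' @slot maxIter,tol,restarts optimization controls.
#' @slot seed base RNG seed; each restart derives its own stream from it.
#' @slot updateMode `"descent"` (monotone placement of the Laplacian terms)
#'   or `"paper"` (degree matrix in the numerator).
#'
#' @exportClass Hyperparameters
setClass("Hyperparameters",
         slots = c(k = "integer", lambda1 = "numeric", lambda2 = "numeric",
                   mu = "numeric", gammaM = "numeric", gammaD = "numeric",
                   t = "numeric", maxIter = "integer", tol = "numeric",
                   restarts = "integer", seed = "integer",
                   updateMode = "character"),
         validity = function(object) {
  if (object@k < 1L) return("k must be a positive integer")
  for (nm in c("lambda1", "lambda2", "mu")) {
    v <- slot(object, nm)
    if (!is.na(v) && v < 0) return(sprintf("%s must be nonnegative", nm))
  }
  if (object@gammaM <= 0 || object@gammaD <= 0)
    return("gamma bandwidth bases must be positive")
  if (object@maxIter < 1L) return("maxIter must be positive")
  if (object@tol <= 0) return("tol must be positive")
  if (object@restarts < 1L) return("restarts must be positive")
  if (!object@updateMode %in% c("descent", "paper"))
    return("updateMode must be 'descent' or 'paper'")
  TRUE
})

#' State of one factorization
#'
#' Factors \eqn{H_1} (microbes-by-k), \eqn{H_2} (diseases-by-k) and the
#' symmetric central matrices \eqn{S_1}, \eqn{S_2}, together with the inputs
#' they were fitted to and the per-iteration objective trace. `model` records
#' which objective the state optimizes: `"mdnmf"` (full graph-regularized
#' tri-factorization), `"netnmf"` (no Laplacian penalty) or `"nmf"` (plain
#' two-factor approximation of the association matrix, with `S1`, `S2`
#' fixed at the identity).
#'
#' @slot H1,H2 nonnegative factor matrices with entity rownames.
#' @slot S1,S2 nonnegative symmetric k-by-k matrices.
#' @slot objectiveTrace objective value at every iteration.
#' @slot hyper [Hyperparameters-class] used.
#' @slot model `"mdnmf"`, `"netnmf"` or `"nmf"`.
#' @slot inputs list holding `MS`, `DS`, `X` and optional `Wphylo`,
#'   `Wsymptom` prior similarity matrices.
#'
#' @exportClass FactorizationState
setClass("FactorizationState",
         slots = c(H1 = "matrix", H2 = "matrix", S1 = "matrix", S2 = "matrix",
                   objectiveTrace = "numeric", hyper = "Hyperparameters",
                   model = "character", inputs = "list"),
         validity = function(object) {
  k <- ncol(object@H1)
  if (ncol(object@H2) != k) return("H1 and H2 must share k")
  if (!identical(dim(object@S1), c(k, k)) || !identical(dim(object@S2), c(k, k)))
    return("S1 and S2 must be k-by-k")
  if (min(object@H1) < 0 || min(object@H2) < 0 ||
      min(object@S1) < 0 || min(object@S2) < 0)
    return("all factor entries must be nonnegative")
  if (max(abs(object@S1 - t(object@S1))) > 1e-10 ||
      max(abs(object@S2 - t(object@S2))) > 1e-10)
    return("S1 and S2 must be symmetric within 1e-10")
  if (length(object@objectiveTrace) &&
      !all(is.finite(object@objectiveTrace)))
    return("objective trace must be finite")
  if (!object@model %in% c("mdnmf", "netnmf", "nmf"))
    return("model must be 'mdnmf', 'netnmf' or 'nmf'")
  TRUE
})

#' Result of a multi-restart fit
#'
#' @slot bestState the [FactorizationState-class] with the smallest final
#'   objective among all successful restarts.
#' @slot allFinalObjectives final objective of every restart (NA for
#'   restarts aborted on non-finite factors).
#' @slot selectedRestart index of the restart kept.
#'
#' @exportClass FitResult
setClass("FitResult",
         slots = c(bestState = "FactorizationState",
                   allFinalObjectives = "numeric",
                   selectedRestart = "integer"),
         validity = function(object) {
  finals <- object@allFinalObjectives
  i <- object@selectedRestart
  if (i < 1L || i > length(finals)) return("selectedRestart out of range")
  ok <- which(is.finite(finals))
  if (!length(ok)) return("no successful restart")
  if (abs(finals[i] - min(finals[ok])) > 1e-9 * max(1, abs(finals[i])))
    return("selected restart is not the argmin of final objectives")
  TRUE
})

#' Soft module assignments of one factor matrix
#'
#' For each factor column c, the set of row labels whose loading exceeds the
#' row-wise threshold mean + t*sd. Memberships may overlap and modules may be
#' empty (soft clustering).
#'
#' @slot memberships list of length k; element c holds the labels in module c.
#' @slot side `"microbe"` or `"disease"`.
#' @slot t threshold multiplier used.
#'
#' @exportClass ModuleSet
setClass("ModuleSet",
         slots = c(memberships = "list", side = "character", t = "numeric"),
         validity = function(object) {
  if (!object@side %in% c("microbe", "disease"))
    return("side must be 'microbe' or 'disease'")
  if (!all(vapply(object@memberships, is.character, logical(1))))
    return("memberships must be character vectors")
  TRUE
})

#' A paired microbe-disease co-module
#'
#' Column c of H1 and column c of H2 are bound to the same co-module by the
#' association coupling term; `links` lists the other co-modules it connects
#' to, weighted by the off-diagonal entries of S2 (disease level), with the
#' S1 (microbe level) weights recorded alongside.
#'
#' @slot index factor column index.
#' @slot microbeMembers,diseaseMembers member labels.
#' @slot links data.frame with columns `other`, `weight` (S2 off-diagonals,
#'   descending) and `weightS1`.
#'
#' @exportClass CoModule
setClass("CoModule",
         slots = c(index = "integer", microbeMembers = "character",
                   diseaseMembers = "character", links = "data.frame"),
         validity = function(object) {
  if (object@index < 1L) return("index must be positive")
  if (nrow(object@links)) {
    if (!all(c("other", "weight") %in% names(object@links)))
      return("links must have columns 'other' and 'weight'")
    if (min(object@links$weight) < 0) return("link weights must be nonnegative")
    if (is.unsorted(rev(object@links$weight)))
      return("links must be sorted by descending weight")
  }
  TRUE
})

#' Collection of taxon sets
#'
#' Named microbe sets (the microbiome analogue of gene sets, GMT dialect)
#' used for local hypergeometric enrichment of microbe modules.
#'
#' @slot sets named list mapping set name to a character vector of members.
#' @slot source free-text provenance.
#'
#' @exportClass TaxonSetCollection
setClass("TaxonSetCollection",
         slots = c(sets = "list", source = "character"),
         validity = function(object) {
  if (length(object@sets)) {
    msg <- .checkLabels(names(object@sets), "taxon-set")
    if (!is.null(msg)) return(msg)
    if (any(vapply(object@sets, length, integer(1)) == 0L))
      return("every taxon set must be non-empty")
  }
  TRUE
})

#' Configuration of the planted co-module generator
#'
#' Defines the study conditions of a synthetic benchmark: a blockwise
#' Bernoulli association matrix with `kTrue` planted microbe-disease blocks,
#' flip noise, phylogenetic distances drawn around a small within-module and
#' a large between-module mean, symptom similarities with the opposite
#' ordering, and taxon sets (one per planted module plus size-matched
#' decoys).
#'
#' @slot nM,nD,kTrue dimensions and number of planted co-modules.
#' @slot withinDensity,backgroundDensity,flipNoise Bernoulli parameters.
#' @slot phyloWithin,phyloBetween mean phylogenetic distances.
#' @slot sympWithin,sympBetween mean symptom similarities.
#' @slot overlapFraction fraction of entities planted in two modules.
#' @slot seed generator seed.
#'
#' @exportClass PlantedConfig
setClass("PlantedConfig",
         slots = c(nM = "integer", nD = "integer", kTrue = "integer",
                   withinDensity = "numeric", backgroundDensity = "numeric",
                   flipNoise = "numeric", phyloWithin = "numeric",
                   phyloBetween = "numeric", sympWithin = "numeric",
                   sympBetween = "numeric", overlapFraction = "numeric",
                   seed = "integer"),
         validity = function(object) {
  if (object@kTrue >= min(object@nM, object@nD))
    return("kTrue must be smaller than min(nM, nD)")
  probs <- c(object@withinDensity, object@backgroundDensity,
             object@flipNoise, object@overlapFraction)
  if (any(probs < 0 | probs > 1)) return("probabilities must lie in [0, 1]")
  if (object@withinDensity <= object@backgroundDensity)
    return("withinDensity must exceed backgroundDensity")
  if (object@phyloWithin >= object@phyloBetween)
    return("phyloWithin must be below phyloBetween")
  if (object@sympWithin <= object@sympBetween)
    return("sympWithin must exceed sympBetween")
  TRUE
})

#' Ground truth of a planted dataset
#'
#' @slot microbeAssignments,diseaseAssignments named lists mapping label to
#'   the integer module indices it was planted in.
#' @slot blockMap pairing of microbe to disease modules (the identity).
#'
#' @exportClass PlantedTruth
setClass("PlantedTruth",
         slots = c(microbeAssignments = "list", diseaseAssignments = "list",
                   blockMap = "integer"),
         validity = function(object) {
  n1 <- vapply(object@microbeAssignments, length, integer(1))
  n2 <- vapply(object@diseaseAssignments, length, integer(1))
  if (any(c(n1, n2) == 0L)) return("every entity must belong to >= 1 module")
  TRUE
})
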