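## Planted co-module generator and recovery scoring.

.truncNorm01 <- function(n, mean, sd = 0.05) {
  pmin(pmax(stats::rnorm(n, mean, sd), 0), 1)
}

.sampleAssignments <- function(n, k, overlapFraction) {
  primary <- rep(seq_len(k), length.out = n)[sample.int(n)]
  a <- as.list(primary)
  nOv <- round(overlapFraction * n)
  if (nOv > 0) {
    for (i in sample.int(n, nOv))
      a[[i]] <- c(a[[i]], sample(setdiff(seq_len(k), a[[i]]), 1))
  }
  a
}

.pairwiseBlockMatrix <- function(assign, within, between, sd, kind) {
  n <- length(assign)
  shares <- function(i, j) length(intersect(assign[[i]], assign[[j]])) > 0
  M <- matrix(0, n, n)
  ut <- which(upper.tri(M), arr.ind = TRUE)
  same <- vapply(seq_len(nrow(ut)),
                 function(r) shares(ut[r, 1], ut[r, 2]), logical(1))
  vals <- numeric(nrow(ut))
  vals[same] <- .truncNorm01(sum(same), within, sd)
  vals[!same] <- .truncNorm01(sum(!same), between, sd)
  M[ut] <- vals
  M <- M + t(M)
  if (kind == "similarity") diag(M) <- 1
  M
}

#' Generate a planted co-module dataset
#'
#' Produces all four inputs of the pipeline with known ground truth:
#' \itemize{
#'   \item an association matrix X sampled Bernoulli(`withinDensity`)
#'     inside each planted microbe-disease block and
#'     Bernoulli(`backgroundDensity`) elsewhere, then flip-noised;
#'   \item a phylogenetic distance matrix with pair means `phyloWithin` /
#'     `phyloBetween` (same planted module vs. not), sd 0.05, truncated to
#'     [0, 1];
#'   \item a symptom-based disease similarity matrix with pair means
#'     `sympWithin` / `sympBetween`;
#'   \item a taxon-set collection holding one set per planted microbe
#'     module plus `2 * kTrue` decoy sets drawn uniformly from the microbe
#'     universe with sizes resampled from the true set sizes.
#' }
#' Everything is reproducible from `config@seed`.
#'
#' @param config a [PlantedConfig-class].
#' @return list with elements `X`
#'   ([BipartiteAssociationMatrix-class]), `phylo`
#'   ([LabeledSquareMatrix-class], distance), `symptom`
#'   ([LabeledSquareMatrix-class], similarity), `taxonSets`
#'   ([TaxonSetCollection-class]) and `truth` ([PlantedTruth-class]).
#' @export
generatePlanted <- function(config) {
  stopifnot(is(config, "PlantedConfig"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config@seed)
  nM <- config@nM; nD <- config@nD; k <- config@kTrue
  mLab <- sprintf("microbe_%03d", seq_len(nM))
  dLab <- sprintf("disease_%02d", seq_len(nD))
  ma <- .sampleAssignments(nM, k, config@overlapFraction)
  da <- .sampleAssignments(nD, k, config@overlapFraction)
  names(ma) <- mLab; names(da) <- dLab

  P <- matrix(config@backgroundDensity, nM, nD)
  for (c in seq_len(k)) {
    mi <- which(vapply(ma, function(a) c %in% a, logical(1)))
    di <- which(vapply(da, function(a) c %in% a, logical(1)))
    P[mi, di] <- config@withinDensity
  }
  X <- matrix(stats::rbinom(nM * nD, 1, P), nM, nD)
  flip <- matrix(stats::rbinom(nM * nD, 1, config@flipNoise), nM, nD) == 1
  X[flip] <- 1 - X[flip]
  dimnames(X) <- list(mLab, dLab)

  Dphy <- .pairwiseBlockMatrix(ma, config@phyloWithin, config@phyloBetween,
                               0.05, "distance")
  dimnames(Dphy) <- list(mLab, mLab)
  Ssym <- .pairwiseBlockMatrix(da, config@sympWithin, config@sympBetween,
                               0.05, "similarity")
  dimnames(Ssym) <- list(dLab, dLab)

  trueSets <- lapply(seq_len(k), function(c)
    mLab[vapply(ma, function(a) c %in% a, logical(1))])
  ## Taxon sets carry disease-style names (as curated collections do), so
  ## the enrichment index can match them against the paired disease module:
  ## each true set is named after a disease planted in its co-module.
  used <- character(0)
  names(trueSets) <- vapply(seq_len(k), function(c) {
    ds <- dLab[vapply(da, function(a) c %in% a, logical(1))]
    ds <- setdiff(ds, used)
    nm <- if (length(ds)) sprintf("%s (increase)", ds[1])
          else sprintf("planted_module_%d_taxa", c)
    used <<- c(used, ds[1])
    nm
  }, character(1))
  sizes <- vapply(trueSets, length, integer(1))
  decoys <- lapply(seq_len(2L * k), function(j)
    sample(mLab, sample(sizes, 1)))
  names(decoys) <- sprintf("decoy_set_%02d", seq_len(2L * k))

  list(X = BipartiteAssociationMatrix(X),
       phylo = LabeledSquareMatrix(Dphy, kind = "distance"),
       symptom = LabeledSquareMatrix(Ssym, kind = "similarity"),
       taxonSets = TaxonSetCollection(c(trueSets, decoys),
                                      source = "planted generator"),
       truth = new("PlantedTruth", microbeAssignments = ma,
                   diseaseAssignments = da,
                   blockMap = seq_len(k)))
}

#' Module sets implied by a planted truth
#'
#' @param truth a [PlantedTruth-class].
#' @param side `"microbe"` or `"disease"`.
#' @return list of character vectors, one per planted module.
#' @export
truthModules <- function(truth, side = c("microbe", "disease")) {
  side <- match.arg(side)
  a <- if (side == "microbe") truth@microbeAssignments
       else truth@diseaseAssignments
  k <- max(unlist(a))
  lapply(seq_len(k), function(c)
    names(a)[vapply(a, function(v) c %in% v, logical(1))])
}

.setF1 <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  if (!length(a) || !length(b)) return(0)
  tp <- length(intersect(a, b))
  if (tp == 0) return(0)
  p <- tp / length(a); r <- tp / length(b)
  2 * p * r / (p + r)
}

.permutations <- function(v) {
  if (length(v) == 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(.permutations(v[-i]), function(p) c(v[i], p))))
}

#' Best-match F1 between predicted and planted modules
#'
#' Scores a module set against planted truth by the optimal one-to-one
#' matching of predicted to planted modules that maximizes the mean F1 of
#' member sets: exhaustive over all k! pairings for k <= 8, greedy
#' (largest remaining F1 first) beyond. The score is invariant to
#' permutation of module indices, as it must be for factorization output.
#'
#' @param predicted a [ModuleSet-class] or list of character member
#'   vectors.
#' @param truth a [PlantedTruth-class] or list of character member vectors.
#' @param side side to score when `truth` is a `PlantedTruth`.
#' @return mean F1 of the optimal matching, in [0, 1].
#' @export
recoveryScore <- function(predicted, truth,
                          side = c("microbe", "disease")) {
  side <- match.arg(side)
  pred <- if (is(predicted, "ModuleSet")) predicted@memberships
          else predicted
  tru <- if (is(truth, "PlantedTruth")) truthModules(truth, side) else truth
  k <- max(length(pred), length(tru))
  length(pred) <- k; length(tru) <- k
  pred <- lapply(pred, function(x) if (is.null(x)) character(0) else x)
  tru <- lapply(tru, function(x) if (is.null(x)) character(0) else x)
  F1 <- outer(seq_len(k), seq_len(k),
              Vectorize(function(i, j) .setF1(pred[[i]], tru[[j]])))
  if (k <= 8L) {
    best <- 0
    for (p in .permutations(seq_len(k)))
      best <- max(best, mean(F1[cbind(p, seq_len(k))]))
    return(best)
  }
  ## greedy fallback for large k
  total <- 0
  rows <- seq_len(k); cols <- seq_len(k)
  for (step in seq_len(k)) {
    sub <- F1[rows, cols, drop = FALSE]
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    total <- total + sub[ij[1], ij[2]]
    rows <- rows[-ij[1]]; cols <- cols[-ij[2]]
  }
  total / k
}
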