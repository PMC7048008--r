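#' @rdname BipartiteAssociationMatrix-class
#' @export
setMethod("microbes", "BipartiteAssociationMatrix",
          function(x) rownames(x@values))

#' @rdname BipartiteAssociationMatrix-class
#' @export
setMethod("diseases", "BipartiteAssociationMatrix",
          function(x) colnames(x@values))

#' @rdname BipartiteAssociationMatrix-class
#' @export
setMethod("as.matrix", "BipartiteAssociationMatrix", function(x) x@values)

#' @rdname LabeledSquareMatrix-class
#' @param x a `LabeledSquareMatrix`.
#' @export
setMethod("as.matrix", "LabeledSquareMatrix", function(x) x@values)

#' @rdname BipartiteAssociationMatrix-class
#' @export
setMethod("dim", "BipartiteAssociationMatrix", function(x) dim(x@values))

#' @rdname LabeledSquareMatrix-class
#' @export
setMethod("dim", "LabeledSquareMatrix", function(x) dim(x@values))

#' @rdname BipartiteAssociationMatrix-class
#' @export
setMethod("dimnames", "BipartiteAssociationMatrix",
          function(x) dimnames(x@values))

#' @rdname LabeledSquareMatrix-class
#' @export
setMethod("dimnames", "LabeledSquareMatrix", function(x) dimnames(x@values))

#' Kind of a labeled square matrix
#' @param x a [LabeledSquareMatrix-class].
#' @return `"distance"` or `"similarity"`.
#' @export
matrixKind <- function(x) {
  stopifnot(is(x, "LabeledSquareMatrix"))
  x@kind
}

setMethod("show", "BipartiteAssociationMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("BipartiteAssociationMatrix: %d microbes x %d diseases, %d associations\n",
              d[1], d[2], sum(object@values)))
})

setMethod("show", "LabeledSquareMatrix", function(object) {
  cat(sprintf("LabeledSquareMatrix (%s): %d x %d\n",
              object@kind, nrow(object@values), ncol(object@values)))
})

setMethod("show", "Hyperparameters", function(object) {
  cat(sprintf("Hyperparameters: k=%d lambda1=%s lambda2=%s mu=%g t=%g\n",
              object@k, format(object@lambda1), format(object@lambda2),
              object@mu, object@t))
  cat(sprintf("  restarts=%d maxIter=%d tol=%g seed=%d mode=%s\n",
              object@restarts, object@maxIter, object@tol, object@seed,
              object@updateMode))
})

setMethod("show", "FactorizationState", function(object) {
  cat(sprintf("FactorizationState (%s): H1 %dx%d, H2 %dx%d, %d iterations, objective %.6g\n",
              object@model, nrow(object@H1), ncol(object@H1),
              nrow(object@H2), ncol(object@H2),
              length(object@objectiveTrace),
              utils::tail(object@objectiveTrace, 1)))
})

setMethod("show", "FitResult", function(object) {
  ok <- sum(is.finite(object@allFinalObjectives))
  cat(sprintf("FitResult: %d/%d restarts converged, best objective %.6g (restart %d)\n",
              ok, length(object@allFinalObjectives),
              object@allFinalObjectives[object@selectedRestart],
              object@selectedRestart))
})

setMethod("show", "ModuleSet", function(object) {
  sizes <- vapply(object@memberships, length, integer(1))
  cat(sprintf("ModuleSet (%s): k=%d, t=%g, sizes: %s\n", object@side,
              length(sizes), object@t, paste(sizes, collapse = " ")))
})

setMethod("show", "CoModule", function(object) {
  cat(sprintf("CoModule %d: %d microbes, %d diseases, %d links\n",
              object@index, length(object@microbeMembers),
              length(object@diseaseMembers), nrow(object@links)))
})

setMethod("show", "TaxonSetCollection", function(object) {
  cat(sprintf("TaxonSetCollection: %d sets (%s)\n", length(object@sets),
              if (nzchar(object@source)) object@source else "unspecified source"))
})

#' @rdname objectiveTrace
#' @export
setMethod("objectiveTrace", "FactorizationState",
          function(x) x@objectiveTrace)

#' @rdname objectiveTrace
#' @export
setMethod("objectiveTrace", "FitResult",
          function(x) x@bestState@objectiveTrace)

#' Best state of a multi-restart fit
#' @param x a [FitResult-class].
#' @return the selected [FactorizationState-class].
#' @export
bestState <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@bestState
}

#' Final objective of every restart
#' @param x a [FitResult-class].
#' @return numeric vector (NA for aborted restarts).
#' @export
finalObjectives <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@allFinalObjectives
}

#' Factor matrices of a state
#'
#' @param x a [FactorizationState-class] or [FitResult-class].
#' @return the requested factor matrix.
#' @export
factorH1 <- function(x) {
  if (is(x, "FitResult")) x <- x@bestState
  x@H1
}

#' @rdname factorH1
#' @export
factorH2 <- function(x) {
  if (is(x, "FitResult")) x <- x@bestState
  x@H2
}

#' @rdname factorH1
#' @export
factorS1 <- function(x) {
  if (is(x, "FitResult")) x <- x@bestState
  x@S1
}

#' @rdname factorH1
#' @export
factorS2 <- function(x) {
  if (is(x, "FitResult")) x <- x@bestState
  x@S2
}

#' @rdname memberships
#' @export
setMethod("memberships", "ModuleSet", function(x) x@memberships)

#' @rdname taxonSets
#' @export
setMethod("taxonSets", "TaxonSetCollection", function(x) x@sets)
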