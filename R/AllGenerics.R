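#' @rdname BipartiteAssociationMatrix-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("microbes", function(x) standardGeneric("microbes"))

#' @rdname BipartiteAssociationMatrix-class
#' @export
setGeneric("diseases", function(x) standardGeneric("diseases"))

#' Extract the objective trace of a fitted state
#' @param x a `FactorizationState` or `FitResult`.
#' @return numeric vector, one objective value per iteration.
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' Module memberships of a ModuleSet
#' @param x a `ModuleSet`.
#' @return named list of character vectors, one per factor column.
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))

#' Taxon sets of a collection
#' @param x a `TaxonSetCollection`.
#' @return named list of character vectors.
#' @export
setGeneric("taxonSets", function(x) standardGeneric("taxonSets"))
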