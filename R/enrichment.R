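## Local taxon-set enrichment, the enrichment index (EI) and the Jaccard
## disease-profile statistic.

#' Upper tail of the hypergeometric distribution
#'
#' Exact probability of drawing at least `overlap` members of a taxon set
#' of size `setSize` when `moduleSize` entities are drawn without
#' replacement from a universe of `universeSize`.
#'
#' @param overlap observed overlap count.
#' @param setSize taxon-set size within the universe.
#' @param moduleSize module size within the universe.
#' @param universeSize total number of entities.
#' @return `P[X >= overlap]`, exact.
#' @export
hypergeomTail <- function(overlap, setSize, moduleSize, universeSize) {
  if (any(c(overlap, setSize, moduleSize, universeSize) < 0) ||
      overlap > min(setSize, moduleSize) ||
      max(setSize, moduleSize) > universeSize)
    stop("inconsistent hypergeometric counts")
  stats::phyper(overlap - 1, setSize, universeSize - setSize, moduleSize,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values with monotone enforcement; invariant to input order
#' (each p keeps its own q under permutation).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values, same order as `p`.
#' @export
bhFDR <- function(p) {
  if (length(p) && (min(p) < 0 || max(p) > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric taxon-set enrichment of one microbe module
#'
#' Every taxon set is first intersected with the universe; sets with no
#' member in the universe are not tested. FDR control is applied across all
#' sets tested for this module, and a set is flagged significant when
#' p < `pCut` and q < `fdrCut` (both must hold).
#'
#' The default universe (when `universe = NULL` callers should pass the
#' association-matrix microbes that appear in at least one taxon set) fixes
#' the sampling frame of the test.
#'
#' @param members microbe labels of the module.
#' @param collection a [TaxonSetCollection-class].
#' @param universe character vector of labels defining the sampling frame.
#' @param pCut,fdrCut significance cut-offs (defaults 0.005 and 0.05).
#' @return data.frame with one row per tested set: `set_name`, `overlap`,
#'   `set_size`, `module_size_in_universe`, `universe_size`, `p_value`,
#'   `q_value`, `significant`; ordered by p-value.
#' @export
enrichModule <- function(members, collection, universe,
                         pCut = 0.005, fdrCut = 0.05) {
  stopifnot(is(collection, "TaxonSetCollection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  empty <- data.frame(set_name = character(0), overlap = integer(0),
                      set_size = integer(0),
                      module_size_in_universe = integer(0),
                      universe_size = integer(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0))
  if (!length(members)) return(empty)
  modU <- intersect(unique(as.character(members)), universe)
  eff <- lapply(collection@sets, intersect, universe)
  eff <- eff[vapply(eff, length, integer(1)) > 0L]
  if (!length(eff)) return(empty)
  rows <- lapply(names(eff), function(nm) {
    s <- eff[[nm]]
    ov <- length(intersect(s, modU))
    data.frame(set_name = nm, overlap = ov, set_size = length(s),
               module_size_in_universe = length(modU),
               universe_size = length(universe),
               p_value = hypergeomTail(ov, length(s), length(modU),
                                       length(universe)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bhFDR(out$p_value)
  out$significant <- out$p_value < pCut & out$q_value < fdrCut
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize names for enrichment-index matching
#'
#' Taxon-set names only loosely match disease names (case, punctuation,
#' qualifiers like "(increase)"), so both sides are casefolded, stripped of
#' parenthetical qualifiers and punctuation, and whitespace-collapsed
#' before comparison. A user-supplied synonym map (named character vector,
#' applied after normalization) handles abbreviations such as
#' "ibs" -> "irritable bowel syndrome".
#'
#' @param x character vector of names.
#' @param synonyms optional named character vector mapping a normalized
#'   name to its canonical normalized form.
#' @return normalized names.
#' @export
normalizeNames <- function(x, synonyms = NULL) {
  y <- tolower(x)
  y <- gsub("\\([^)]*\\)", " ", y)       # drop parenthetical qualifiers
  y <- gsub("['’]", "", y)          # crohn's -> crohns
  y <- gsub("[[:punct:]]", " ", y)
  y <- gsub("[[:space:]]+", " ", y)
  y <- trimws(y)
  if (!is.null(synonyms)) {
    hit <- y %in% names(synonyms)
    y[hit] <- unname(synonyms[y[hit]])
  }
  y
}

#' Enrichment index of a co-module
#'
#' Jaccard-style agreement between the names of a microbe module's
#' significantly enriched taxon sets and the diseases of its paired disease
#' module:
#' \deqn{EI = \frac{|\{enriched\} \cap \{diseases\}|}
#'   {|\{enriched\} \cup \{diseases\}|}.}
#' Both name sets are normalized with [normalizeNames()] before the set
#' arithmetic. An empty union leaves EI undefined (`NA`), never 0.
#'
#' @param enrichedNames names of significantly enriched taxon sets.
#' @param diseaseNames disease names of the paired module.
#' @param synonyms optional synonym map, see [normalizeNames()].
#' @return EI in [0, 1], or `NA` when both sets are empty.
#' @export
enrichmentIndex <- function(enrichedNames, diseaseNames, synonyms = NULL) {
  e <- unique(normalizeNames(as.character(enrichedNames), synonyms))
  d <- unique(normalizeNames(as.character(diseaseNames), synonyms))
  u <- union(e, d)
  if (!length(u)) return(NA_real_)
  length(intersect(e, d)) / length(u)
}

#' Jaccard coefficient between two binary association profiles
#'
#' Used to relate phylogenetic closeness to disease-profile similarity:
#' for two microbes' rows of the association matrix,
#' `|support(a) & support(b)| / |support(a) | support(b)|`. Two all-zero
#' profiles leave the coefficient undefined (`NA`).
#'
#' @param a,b binary vectors of equal length.
#' @return the Jaccard coefficient, or `NA`.
#' @export
jaccardProfile <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  sa <- which(a != 0); sb <- which(b != 0)
  u <- union(sa, sb)
  if (!length(u)) return(NA_real_)
  length(intersect(sa, sb)) / length(u)
}

#' Evaluate co-modules by taxon-set enrichment
#'
#' Runs [enrichModule()] on the microbe side of every co-module and scores
#' each against its disease side with [enrichmentIndex()]. The summary
#' reports the mean EI over co-modules with defined EI, the number of
#' distinct significantly enriched taxon sets (`tsSig`), and `ots` — the
#' significantly enriched sets whose (normalized) name matches no disease
#' of their own co-module, i.e. enrichment signal beyond the diseases
#' already in the module.
#'
#' @param comodules list of [CoModule-class].
#' @param collection a [TaxonSetCollection-class].
#' @param universe sampling frame; defaults to all microbes of the
#'   co-modules' union that appear in at least one taxon set.
#' @param allMicrobes optional full microbe label set used to build the
#'   default universe (e.g. `microbes(X)`).
#' @param pCut,fdrCut significance cut-offs.
#' @param synonyms optional synonym map for name matching.
#' @return list with `perComodule` (data.frame: index, sizes, number of
#'   significant sets, EI), `enrichments` (list of per-module enrichment
#'   tables), `meanEI`, `tsSig`, `ots`, `identifiedComodules`.
#' @export
evaluateComodules <- function(comodules, collection, universe = NULL,
                              allMicrobes = NULL, pCut = 0.005,
                              fdrCut = 0.05, synonyms = NULL) {
  stopifnot(is(collection, "TaxonSetCollection"))
  inSets <- unique(unlist(collection@sets, use.names = FALSE))
  if (is.null(universe)) {
    pool <- if (!is.null(allMicrobes)) allMicrobes
            else unique(unlist(lapply(comodules, slot, "microbeMembers")))
    universe <- intersect(pool, inSets)
  }
  if (!length(universe)) stop("empty enrichment universe")
  sigByModule <- list()
  rows <- list()
  enr <- list()
  for (cm in comodules) {
    tab <- enrichModule(cm@microbeMembers, collection, universe,
                        pCut = pCut, fdrCut = fdrCut)
    enr[[as.character(cm@index)]] <- tab
    sig <- tab$set_name[tab$significant]
    sigByModule[[as.character(cm@index)]] <- sig
    rows[[length(rows) + 1L]] <- data.frame(
      comodule = cm@index,
      n_microbes = length(cm@microbeMembers),
      n_diseases = length(cm@diseaseMembers),
      n_significant_sets = length(sig),
      ei = enrichmentIndex(sig, cm@diseaseMembers, synonyms))
  }
  per <- do.call(rbind, rows)
  eis <- per$ei[!is.na(per$ei)]
  allSig <- unique(unlist(sigByModule, use.names = FALSE))
  matched <- unique(unlist(lapply(comodules, function(cm) {
    sig <- sigByModule[[as.character(cm@index)]]
    dn <- normalizeNames(cm@diseaseMembers, synonyms)
    sig[normalizeNames(sig, synonyms) %in% dn]
  }), use.names = FALSE))
  list(perComodule = per, enrichments = enr,
       meanEI = if (length(eis)) mean(eis) else NA_real_,
       tsSig = length(allSig),
       ots = length(allSig) - length(matched),
       identifiedComodules = sum(per$n_microbes > 0 | per$n_diseases > 0))
}
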