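## Readers/writers for the labeled TSV, GMT and run-summary formats.
## Dialect: tab-separated, UTF-8, first header cell ignored.

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("expected a labeled table in ", path)
  labs <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labs
  ## data.frame subsetting deduplicates repeated header names; recover the
  ## raw header so duplicate labels are detectable downstream
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]][-1]
  if (length(hdr) == ncol(m)) colnames(m) <- hdr
  m
}

#' Read a microbe-disease association table
#'
#' Expects a labeled TSV: first row holds disease labels (first header cell
#' ignored), first column holds microbe labels, cells are 0/1.
#'
#' @param path file path.
#' @return a [BipartiteAssociationMatrix-class] with labels in file order.
#' @seealso [writeAssociationTable()]
#' @export
readAssociationTable <- function(path) {
  m <- .readTable(path)
  bad <- which(is.na(m) | !(m %in% c(0, 1)))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(m))
    stop(sprintf("non-binary cell at microbe '%s', disease '%s' in %s",
                 rownames(m)[i[1]], colnames(m)[i[2]], path))
  }
  for (side in 1:2) {
    labs <- dimnames(m)[[side]]
    if (anyDuplicated(labs))
      stop(sprintf("duplicate %s label '%s' in %s",
                   c("microbe", "disease")[side],
                   labs[duplicated(labs)][1], path))
  }
  BipartiteAssociationMatrix(m)
}

#' @rdname readAssociationTable
#' @param x object to write.
#' @export
writeAssociationTable <- function(x, path) {
  stopifnot(is(x, "BipartiteAssociationMatrix"))
  .writeLabeledTSV(x@values, path)
  invisible(path)
}

.writeLabeledTSV <- function(m, path, corner = "label") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(corner, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Read a labeled square matrix (distance or similarity)
#'
#' Reads a labeled TSV, checks row/column labels agree, symmetrizes as
#' `(A + t(A))/2` (asymmetry beyond `atol` is an error) and enforces the
#' invariants of the declared kind: zero diagonal and nonnegative entries
#' for a distance, unit diagonal and entries in [0, 1] for a similarity.
#'
#' @param path file path.
#' @param kind `"distance"` or `"similarity"`.
#' @param atol symmetry tolerance.
#' @return a [LabeledSquareMatrix-class].
#' @export
readSquareMatrix <- function(path, kind = c("distance", "similarity"),
                             atol = 1e-8) {
  kind <- match.arg(kind)
  m <- .readTable(path)
  if (anyNA(m)) stop("non-numeric cell in ", path)
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels differ in ", path)
  if (anyDuplicated(rownames(m)))
    stop("duplicate labels in ", path)
  if (kind == "distance" && max(abs(diag(m))) > atol)
    stop("distance matrix in ", path, " has a nonzero diagonal")
  if (kind == "similarity" && max(abs(diag(m) - 1)) > atol)
    stop("similarity matrix in ", path, " diagonal is not 1")
  LabeledSquareMatrix(m, kind = kind, atol = atol)
}

#' @rdname readSquareMatrix
#' @param x a [LabeledSquareMatrix-class] to write.
#' @export
writeSquareMatrix <- function(x, path) {
  stopifnot(is(x, "LabeledSquareMatrix"))
  .writeLabeledTSV(x@values, path)
  invisible(path)
}

#' Read a GMT taxon-set file
#'
#' Standard gene-set dialect reused for taxa: each line is
#' `set-name<TAB>description<TAB>member1<TAB>member2...`. Sets with no
#' members are skipped with a warning; duplicate set names are an error.
#'
#' @param path file path.
#' @return a [TaxonSetCollection-class].
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    name <- f[1]
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning("skipping empty taxon set '", name, "'")
      next
    }
    if (name %in% names(sets)) stop("duplicate taxon-set name '", name, "'")
    sets[[name]] <- unique(members)
  }
  TaxonSetCollection(sets, source = path)
}

#' @rdname readGMT
#' @param x a [TaxonSetCollection-class].
#' @param descriptions optional named character of set descriptions.
#' @export
writeGMT <- function(x, path, descriptions = NULL) {
  stopifnot(is(x, "TaxonSetCollection"))
  lines <- vapply(names(x@sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, x@sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write the results of a fitted factorization
#'
#' Emits a machine-readable run summary (`summary.json`: hyperparameters,
#' model, seed, per-restart final objectives, objective trace, S1 and S2),
#' one membership TSV per side (`microbe_modules.tsv`,
#' `disease_modules.tsv`) and a co-module table
#' (`comodules.tsv`: disease module | microbe module | associated
#' co-modules by descending S2 link weight).
#'
#' @param fit a [FitResult-class] (or [FactorizationState-class]).
#' @param comodules list of [CoModule-class], e.g. from
#'   [assembleComodules()].
#' @param outDir output directory (created if missing).
#' @param topLinks number of link partners listed per co-module in the
#'   co-module table (all links are kept in the JSON summary).
#' @return invisibly, the paths written.
#' @export
writeResults <- function(fit, comodules, outDir, topLinks = 3) {
  state <- if (is(fit, "FitResult")) fit@bestState else fit
  stopifnot(is(state, "FactorizationState"))
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", outDir)
  }
  h <- state@hyper
  summary <- list(
    model = state@model,
    hyperparameters = list(
      k = h@k, lambda1 = h@lambda1, lambda2 = h@lambda2, mu = h@mu,
      gammaM = h@gammaM, gammaD = h@gammaD, t = h@t,
      maxIter = h@maxIter, tol = h@tol, restarts = h@restarts,
      seed = h@seed, updateMode = h@updateMode),
    selectedRestart = if (is(fit, "FitResult")) fit@selectedRestart else NA,
    finalObjectives = if (is(fit, "FitResult")) fit@allFinalObjectives
                      else utils::tail(state@objectiveTrace, 1),
    objectiveTrace = state@objectiveTrace,
    S1 = state@S1, S2 = state@S2,
    H1 = state@H1, H2 = state@H2,
    microbes = rownames(state@H1), diseases = rownames(state@H2))
  paths <- file.path(outDir, c("summary.json", "microbe_modules.tsv",
                               "disease_modules.tsv", "comodules.tsv"))
  jsonlite::write_json(summary, paths[1], auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)

  moduleDf <- function(side) {
    rows <- do.call(rbind, lapply(comodules, function(cm) {
      mem <- if (side == "microbe") cm@microbeMembers else cm@diseaseMembers
      if (!length(mem)) return(NULL)
      data.frame(module = cm@index, member = mem,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(rows))
      rows <- data.frame(module = integer(0), member = character(0))
    rows
  }
  utils::write.table(moduleDf("microbe"), paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(moduleDf("disease"), paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cmDf <- do.call(rbind, lapply(comodules, function(cm) {
    lk <- cm@links
    lk <- lk[lk$weight > 0, , drop = FALSE]
    lk <- utils::head(lk, topLinks)
    data.frame(comodule = cm@index,
               disease_module = paste(cm@diseaseMembers, collapse = "; "),
               microbe_module = paste(cm@microbeMembers, collapse = "; "),
               associated_comodules = paste(lk$other, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(cmDf))
    cmDf <- data.frame(comodule = integer(0), disease_module = character(0),
                       microbe_module = character(0),
                       associated_comodules = character(0))
  utils::write.table(cmDf, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Re-load a run summary written by writeResults
#'
#' @param path path to `summary.json` (or the directory holding it).
#' @return a list with hyperparameters, objective trace and S1/S2 matrices.
#' @export
readRunSummary <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "summary.json")
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  s$S1 <- as.matrix(s$S1)
  s$S2 <- as.matrix(s$S2)
  s$H1 <- as.matrix(s$H1)
  s$H2 <- as.matrix(s$H2)
  rownames(s$H1) <- s$microbes
  rownames(s$H2) <- s$diseases
  s
}
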