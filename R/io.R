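# Reading and preprocessing of samples x taxa abundance tables.

#' Read an abundance table
#'
#' Reads a rectangular TSV/CSV file with a header row and an id column into
#' a samples-by-taxa numeric matrix. Count tables (integer entries with row
#' sums above 1) are detected automatically and converted to relative
#' abundances by row normalization; values within 1e-12 of 1 are clamped
#' into the open support \[0, 1).
#'
#' @param path file path.
#' @param format `"auto"` (by file extension), `"tsv"` or `"csv"`.
#' @param orientation `"samplesInRows"` (default), `"taxaInRows"`
#'   (transposed input), or `"auto"` (taxa-in-rows is assumed when the file
#'   has more rows than columns, the common layout of OTU tables).
#' @return numeric matrix (samples in rows) with attribute `"counts"`
#'   indicating whether count-to-relative conversion was applied.
#' @export
readAbundanceTable <- function(path, format = c("auto", "tsv", "csv"),
                               orientation = c("samplesInRows", "taxaInRows",
                                               "auto")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (format == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate id(s) in first column: %s",
                 paste(unique(dup), collapse = ", ")))
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("abundance table contains missing values")
  if (any(mat < 0)) {
    bad <- which(rowSums(mat < 0) > 0)[1L]
    stop(sprintf("negative value in data row %d (id %s)", bad, ids[bad]))
  }
  rownames(mat) <- ids
  if (orientation == "auto" && nrow(mat) > ncol(mat)) orientation <- "taxaInRows"
  if (orientation == "taxaInRows") mat <- t(mat)
  isCounts <- all(abs(mat - round(mat)) < 1e-9) && any(rowSums(mat) > 1 + 1e-9)
  if (isCounts) {
    message("integer count table detected; converting to relative abundances")
    rs <- rowSums(mat)
    mat[rs > 0, ] <- mat[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  mat <- .clampUnit(mat, warn = FALSE)
  attr(mat, "counts") <- isCounts
  mat
}

#' Filter an abundance table before network analysis
#'
#' Applies the standard preprocessing sequence: remove taxa whose prevalence
#' (fraction of samples with nonzero abundance) is strictly below
#' `minPrevalence`; optionally remove taxa labeled as unassigned; remove
#' samples left with all-zero abundance; and, when covariates are supplied,
#' restrict to complete cases on the requested columns. Every drop is
#' logged with counts.
#'
#' @param table samples-by-taxa numeric matrix.
#' @param metadata optional data.frame of per-sample covariates, row-aligned
#'   with `table`.
#' @param minPrevalence prevalence threshold (default 0.20: taxa present in
#'   fewer than 20 percent of samples are removed).
#' @param dropUnassigned logical; drop taxa whose label matches
#'   "unassigned"/"unclassified" (case-insensitive).
#' @param completeCase character vector of metadata columns on which to do
#'   complete-case deletion (`NULL` keeps all samples).
#' @param renormalize logical; renormalize rows to unit sum over the
#'   retained taxa (logged when applied).
#' @return list with `table`, `metadata` and a character `log` of the
#'   filtering steps.
#' @export
preprocessAbundance <- function(table, metadata = NULL, minPrevalence = 0.20,
                                dropUnassigned = FALSE, completeCase = NULL,
                                renormalize = FALSE) {
  table <- as.matrix(table)
  if (!is.null(metadata) && nrow(metadata) != nrow(table))
    stop("metadata must be row-aligned with the abundance table")
  log <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log <<- c(log, msg)
  }

  if (dropUnassigned) {
    un <- grepl("unassigned|unclassified", colnames(table), ignore.case = TRUE)
    note("dropped %d unassigned taxa", sum(un))
    table <- table[, !un, drop = FALSE]
  }
  prevalence <- colMeans(table > 0)
  keep <- prevalence >= minPrevalence
  note("dropped %d of %d taxa with prevalence < %g", sum(!keep), length(keep),
       minPrevalence)
  table <- table[, keep, drop = FALSE]
  if (ncol(table) == 0L) stop("no taxa left after prevalence filtering")

  allZero <- rowSums(table) == 0
  note("dropped %d all-zero samples", sum(allZero))
  table <- table[!allZero, , drop = FALSE]
  if (!is.null(metadata)) metadata <- metadata[!allZero, , drop = FALSE]

  if (!is.null(completeCase) && !is.null(metadata)) {
    missing <- setdiff(completeCase, colnames(metadata))
    if (length(missing))
      stop(sprintf("covariate(s) not in metadata: %s",
                   paste(missing, collapse = ", ")))
    cc <- stats::complete.cases(metadata[, completeCase, drop = FALSE])
    note("dropped %d samples with missing covariates (complete-case)", sum(!cc))
    table <- table[cc, , drop = FALSE]
    metadata <- metadata[cc, , drop = FALSE]
  }
  if (nrow(table) == 0L) stop("no samples left after filtering")

  if (renormalize) {
    note("renormalized rows to unit sum over retained taxa")
    rs <- rowSums(table)
    table[rs > 0, ] <- table[rs > 0, , drop = FALSE] / rs[rs > 0]
    table <- .clampUnit(table, warn = FALSE)
  }
  list(table = table, metadata = metadata, log = log)
}
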