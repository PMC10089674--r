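# Count/score matrices travel as plain base matrices with gene identifiers in
# rownames and sample identifiers in colnames.  One fixed TSV dialect is used
# throughout: tab-separated, UTF-8, no quoting, header row "gene_id\t<samples>",
# one gene per row.  Gzip input is auto-detected by R's file() connection.

#' Validate a count matrix
#'
#' Checks the invariants every pipeline stage relies on: a numeric matrix with
#' at least two genes (rows) and two samples (columns), unique gene and sample
#' identifiers, and entries that are finite non-negative integers.
#'
#' @param counts matrix of read counts, genes in rows, samples in columns.
#' @return `counts`, invisibly, if valid; otherwise a classed error is raised.
#' @export
validate_counts <- function(counts) {
  validate_real_matrix(counts)
  bad <- which(counts < 0 | counts != round(counts))
  if (length(bad) > 0L) {
    j <- ((bad[1L] - 1L) %% nrow(counts)) + 1L
    i <- ((bad[1L] - 1L) %/% nrow(counts)) + 1L
    osv_stop("outsvd_bad_value",
             "counts must be non-negative integers; offending value %s at gene '%s', sample '%s'",
             format(counts[j, i]), rownames(counts)[j], colnames(counts)[i])
  }
  invisible(counts)
}

#' Validate a real-valued matrix with gene/sample identifiers
#'
#' @param x numeric matrix with unique rownames (genes) and colnames (samples).
#' @return `x`, invisibly.
#' @export
validate_real_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    osv_stop("outsvd_bad_matrix", "expected a numeric matrix")
  if (nrow(x) < 2L || ncol(x) < 2L)
    osv_stop("outsvd_bad_shape",
             "matrix must have at least 2 genes and 2 samples (got %d x %d)",
             nrow(x), ncol(x))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    osv_stop("outsvd_bad_ids", "matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    osv_stop("outsvd_duplicate_ids", "duplicate gene identifiers: %s",
             paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    osv_stop("outsvd_duplicate_ids", "duplicate sample identifiers: %s",
             paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(!is.finite(x)))
    osv_stop("outsvd_bad_value", "matrix contains missing or non-finite values")
  invisible(x)
}

#' Read a gene x sample count matrix from TSV
#'
#' The first header field is a label (ignored), the remaining fields are sample
#' identifiers; each subsequent row is a gene identifier followed by one count
#' per sample.  `.gz` files are decompressed transparently.
#'
#' @param path path to a tab-separated count file.
#' @return numeric matrix of counts with gene rownames and sample colnames.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t5\t9", "g2\t0\t2"), tf)
#' read_counts(tf)
read_counts <- function(path) {
  m <- read_matrix_tsv(path)
  validate_counts(m)
  m
}

#' Read a real-valued matrix (z-scores, P-values, ...) from TSV
#'
#' @inheritParams read_counts
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_real_matrix <- function(path) {
  m <- read_matrix_tsv(path)
  validate_real_matrix(m)
  m
}

read_matrix_tsv <- function(path) {
  if (!file.exists(path))
    osv_stop("outsvd_missing_file", "file not found: %s", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      quote = "", comment.char = "", colClasses = NA,
                      stringsAsFactors = FALSE),
    error = function(e)
      osv_stop("outsvd_parse_error", "cannot parse '%s': %s", path, conditionMessage(e)))
  if (ncol(df) < 3L || nrow(df) < 2L)
    osv_stop("outsvd_bad_shape",
             "'%s' must contain at least 2 genes and 2 samples", path)
  genes <- as.character(df[[1L]])
  vals <- df[-1L]
  nonnum <- !vapply(vals, is.numeric, logical(1L))
  if (any(nonnum))
    osv_stop("outsvd_bad_value",
             "non-numeric values in '%s', e.g. column '%s'",
             path, names(vals)[which(nonnum)[1L]])
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  # data.frame subsetting deduplicates names; restore the raw header so the
  # duplicate-ID check sees what the file actually contained
  dimnames(m) <- list(genes, names(df)[-1L])
  m
}

#' Write a count or score matrix in the package's TSV dialect
#'
#' Counts are written as integers; real values with 15 significant digits so
#' that a write/read roundtrip is stable well below 1e-9.
#'
#' @param x validated numeric matrix (see [validate_counts()],
#'   [validate_real_matrix()]).
#' @param path destination file path; a `.gz` suffix enables compression.
#' @param label first header field, conventionally `"gene_id"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, label = "gene_id") {
  validate_real_matrix(x)
  integral <- all(x == round(x)) && max(abs(x)) < 2^53
  fmt <- function(v) if (integral) format(v, scientific = FALSE, trim = TRUE)
                     else formatC(v, digits = 15, format = "g")
  con <- tryCatch(
    if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt"),
    error = function(e)
      osv_stop("outsvd_unwritable", "cannot open '%s' for writing", path))
  on.exit(close(con))
  writeLines(paste(c(label, colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(j)
    paste(c(rownames(x)[j], fmt(x[j, ])), collapse = "\t"), character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Drop genes with too many zero counts
#'
#' Removes genes whose fraction of zero-count samples exceeds
#' `max_zero_fraction`.  The conventional expressed-gene filter discards genes
#' with zero counts in more than 75% of samples, hence the default.
#'
#' @param counts validated count matrix.
#' @param max_zero_fraction maximum tolerated fraction of zero-count samples;
#'   genes at exactly the threshold are retained.
#' @return the filtered count matrix, gene order preserved.
#' @export
filter_zero_genes <- function(counts, max_zero_fraction = 0.75) {
  validate_counts(counts)
  stopifnot(max_zero_fraction >= 0, max_zero_fraction <= 1)
  frac0 <- rowMeans(counts == 0)
  keep <- frac0 <= max_zero_fraction
  if (sum(keep) < 2L)
    osv_stop("outsvd_bad_shape",
             "fewer than 2 genes survive the zero-count filter")
  counts[keep, , drop = FALSE]
}
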