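# Depth normalization and gene-wise standardization of log fold changes.
# Every step retains what is needed to run the transform backwards, which is
# what makes count-level outlier injection possible.

#' Median-of-ratios size factors
#'
#' Estimates one sequencing-depth multiplier per sample as the median, over
#' genes, of the ratio between the gene's count in that sample and the gene's
#' geometric mean across samples.  Genes containing any zero count have a zero
#' geometric mean and are excluded from the median.
#'
#' @param counts validated count matrix.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  # geometric means in log space; genes with zeros drop out (log 0 = -Inf)
  loggeo <- rowMeans(log(counts))
  eligible <- is.finite(loggeo)
  if (!any(eligible))
    osv_stop("outsvd_no_reference_genes",
             "no gene has strictly positive counts in every sample")
  s <- apply(counts[eligible, , drop = FALSE], 2L, function(k)
    stats::median(exp(log(k) - loggeo[eligible])))
  names(s) <- colnames(counts)
  s
}

#' Depth-controlled log fold change matrix
#'
#' Divides counts by their sample's size factor and log2-transforms each
#' controlled count against its gene's mean controlled count, with a
#' pseudocount of 1 on both sides:
#' `l_ji = log2((k_ji/s_i + 1) / (mean_i(k_ji/s_i) + 1))`.
#'
#' @param counts validated count matrix.
#' @param sf size factors from [size_factors()] (names must match samples).
#' @return list with `l` (log fold change matrix) and `baseline` (per-gene mean
#'   controlled count, needed for inversion).
#' @export
log_fold_transform <- function(counts, sf) {
  validate_counts(counts)
  if (!identical(names(sf), colnames(counts)))
    osv_stop("outsvd_mismatched_samples",
             "size factor names do not match count matrix samples")
  if (any(!is.finite(sf)) || any(sf <= 0))
    osv_stop("outsvd_bad_value", "size factors must be positive and finite")
  ctrl <- sweep(counts, 2L, sf, "/")
  baseline <- rowMeans(ctrl)
  l <- log2((ctrl + 1) / (baseline + 1))
  list(l = l, baseline = baseline)
}

#' Gene-wise standardization
#'
#' Standardizes each row to mean 0 and standard deviation 1.  The population
#' (divisor N) standard deviation is the default so the forward and inverse
#' transforms share the same algebra; rows with zero spread are flagged
#' degenerate and emitted as all-zero z rows rather than dropped.
#'
#' @param l numeric matrix (log fold changes, or a residual noise matrix).
#' @param sd_divisor `"population"` (divisor N) or `"sample"` (divisor N-1).
#' @return object of class `outsvd_standardized`: list with `z` (the z-score
#'   matrix) and `stats` (data frame with per-gene `mean`, `sd`, `degenerate`).
#' @export
standardize_rows <- function(l, sd_divisor = c("population", "sample")) {
  sd_divisor <- match.arg(sd_divisor)
  validate_real_matrix(l)
  n <- ncol(l)
  mu <- rowMeans(l)
  dev <- l - mu
  tau <- sqrt(rowSums(dev^2) / if (sd_divisor == "population") n else n - 1L)
  degenerate <- tau == 0
  z <- dev / ifelse(degenerate, 1, tau)
  z[degenerate, ] <- 0
  structure(list(
    z = z,
    stats = data.frame(gene = rownames(l), mean = mu, sd = tau,
                       degenerate = degenerate, row.names = rownames(l)),
    sd_divisor = sd_divisor
  ), class = "outsvd_standardized")
}

#' Forward normalization in one call
#'
#' Convenience wrapper running [size_factors()], [log_fold_transform()] and
#' [standardize_rows()], keeping all inversion state together.
#'
#' @inheritParams standardize_rows
#' @param counts validated count matrix.
#' @return `outsvd_standardized` object additionally carrying `size_factors`
#'   and per-gene `baseline` in `stats`.
#' @export
normalize_counts <- function(counts, sd_divisor = c("population", "sample")) {
  sd_divisor <- match.arg(sd_divisor)
  sf <- size_factors(counts)
  lf <- log_fold_transform(counts, sf)
  std <- standardize_rows(lf$l, sd_divisor)
  std$stats$baseline <- lf$baseline
  std$size_factors <- sf
  std
}

#' Invert standardization back to integer counts
#'
#' Maps a z-score matrix back through the gene-wise standardization, the log
#' fold transform and the depth scaling:
#' `l = mean + sd * z`, `c = (baseline + 1) * 2^l - 1`, `k = round(c * s_i)`
#' clipped below at zero.  Rounding is banker's rounding (round half to even),
#' so feeding the pipeline's own z-scores back reproduces the original counts
#' exactly.
#'
#' @param z numeric z-score matrix.
#' @param stats per-gene data frame with `mean`, `sd`, `baseline` columns, as
#'   produced by [normalize_counts()].
#' @param sf size factors of the originating dataset.
#' @return count matrix with the same dimnames as `z`.
#' @export
invert_standardization <- function(z, stats, sf) {
  validate_real_matrix(z)
  stopifnot(identical(rownames(z), rownames(stats)),
            identical(colnames(z), names(sf)))
  l <- stats$mean + stats$sd * z
  ctrl <- (stats$baseline + 1) * 2^l - 1
  k <- sweep(ctrl, 2L, sf, "*")
  if (any(!is.finite(k))) {
    bad <- which(!is.finite(k))[1L]
    j <- ((bad - 1L) %% nrow(k)) + 1L
    i <- ((bad - 1L) %/% nrow(k)) + 1L
    osv_stop("outsvd_overflow",
             "count inversion overflowed at gene '%s', sample '%s' (z = %s)",
             rownames(z)[j], colnames(z)[i], format(z[j, i]))
  }
  pmax(round(k), 0)
}
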