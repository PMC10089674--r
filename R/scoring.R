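# Outlier scoring on the residual noise matrix: gene-wise z-scores, two-sided
# normal P-values, Benjamini-Yekutieli FDR, and the end-to-end detector.

#' Gene-wise z-scores of the noise matrix
#'
#' Re-standardizes the residual noise matrix row by row with the same
#' arithmetic as [standardize_rows()].  Outliers survive the signal/noise
#' split inside the noise matrix, but noise levels differ between genes, so a
#' second gene-wise standardization puts all genes on a common scale.
#'
#' @param noise residual noise matrix from [split_signal_noise()].
#' @inheritParams standardize_rows
#' @return `outsvd_standardized` object (`z` holds the noise z-scores).
#' @export
noise_zscores <- function(noise, sd_divisor = c("population", "sample")) {
  standardize_rows(noise, sd_divisor)
}

#' Two-sided normal P-values for a z-score matrix
#'
#' `p = 2 * min(Phi(z), 1 - Phi(z))`, floored at the smallest positive normal
#' double so that `-log10(p)` stays finite for ranking, and capped at 1.
#'
#' @param zhat numeric matrix of z-scores.
#' @return matrix of P-values in (0, 1], same dimnames as `zhat`.
#' @export
zscore_pvalues <- function(zhat) {
  validate_real_matrix(zhat)
  p <- 2 * stats::pnorm(-abs(zhat))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Benjamini-Yekutieli FDR adjustment of a P-value matrix
#'
#' Step-up adjustment with the harmonic correction factor
#' `c(m) = sum_{i=1}^m 1/i`, valid under arbitrary dependence between tests.
#' By default all J x N tests are corrected jointly; `scope = "per_sample"`
#' corrects each sample's column separately.
#'
#' @param p matrix of raw P-values in (0, 1].
#' @param scope `"matrix"` (all cells jointly) or `"per_sample"`.
#' @return matrix of adjusted P-values (q-values), entrywise >= `p`.
#' @export
by_adjust <- function(p, scope = c("matrix", "per_sample")) {
  scope <- match.arg(scope)
  validate_real_matrix(p)
  if (any(p <= 0 | p > 1))
    osv_stop("outsvd_bad_value", "P-values must lie in (0, 1]")
  if (scope == "matrix") {
    q <- matrix(stats::p.adjust(p, method = "BY"), nrow(p), ncol(p),
                dimnames = dimnames(p))
  } else {
    q <- apply(p, 2L, stats::p.adjust, method = "BY")
    dimnames(q) <- dimnames(p)
  }
  q
}

#' Detect aberrant expression outliers in a count matrix
#'
#' Runs the whole pipeline: size factors, log fold transform, gene-wise
#' standardization, SVD with the optimal hard threshold to strip low-rank
#' confounder structure, gene-wise noise z-scores, two-sided normal P-values,
#' and Benjamini-Yekutieli FDR correction.  Degenerate genes (zero spread)
#' receive p = q = 1 and are never called.
#'
#' @param counts validated count matrix (>= 2 genes, >= 2 samples).
#' @param fdr_level FDR level for the boolean call matrix (default 0.05).
#' @param rank optional manual signal-rank override; `rank = 0` disables
#'   confounder removal entirely (ablation).
#' @inheritParams standardize_rows
#' @param by_scope multiple-testing scope, see [by_adjust()].
#' @return object of class `outsvd_report`: list with matrices `zhat`,
#'   `pvalues`, `qvalues`, `calls`, the `oht` threshold object, `noise_stats`,
#'   and the normalization state (`norm`, `split`) for provenance.
#' @export
detect_outliers <- function(counts, fdr_level = 0.05, rank = NULL,
                            sd_divisor = c("population", "sample"),
                            by_scope = c("matrix", "per_sample")) {
  sd_divisor <- match.arg(sd_divisor)
  by_scope <- match.arg(by_scope)
  stopifnot(fdr_level > 0, fdr_level < 1)
  norm <- normalize_counts(counts, sd_divisor)
  split <- split_signal_noise(norm$z, rank = rank)
  nz <- noise_zscores(split$noise, sd_divisor)
  degen <- norm$stats$degenerate | nz$stats$degenerate
  p <- zscore_pvalues(nz$z)
  p[degen, ] <- 1
  q <- by_adjust(p, by_scope)
  q[degen, ] <- 1
  calls <- q < fdr_level
  calls[degen, ] <- FALSE
  structure(list(zhat = nz$z, pvalues = p, qvalues = q, calls = calls,
                 oht = split$oht, noise_stats = nz$stats, norm = norm,
                 split = split, fdr_level = fdr_level),
            class = "outsvd_report")
}

#' @export
print.outsvd_report <- function(x, ...) {
  cat(sprintf(paste0("Aberrant expression report: %d genes x %d samples\n",
                     "  confounder rank removed: %d (threshold %.3f)\n",
                     "  calls at FDR < %g: %d\n"),
              nrow(x$zhat), ncol(x$zhat), x$oht$rank, x$oht$threshold,
              x$fdr_level, sum(x$calls)))
  invisible(x)
}

#' Write a detection report to TSV files
#'
#' Emits `zhat.tsv`, `pvalues.tsv`, `qvalues.tsv` and a key-value
#' `summary.txt` (selected rank, beta, threshold, number of calls) into a
#' directory.
#'
#' @param report `outsvd_report` from [detect_outliers()].
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "outsvd_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(report$zhat, file.path(dir, "zhat.tsv"))
  write_matrix(report$pvalues, file.path(dir, "pvalues.tsv"))
  write_matrix(report$qvalues, file.path(dir, "qvalues.tsv"))
  s <- c(genes = nrow(report$zhat), samples = ncol(report$zhat),
         rank = report$oht$rank, beta = report$oht$beta,
         median_sv = report$oht$median_sv, threshold = report$oht$threshold,
         fdr_level = report$fdr_level, n_calls = sum(report$calls))
  writeLines(paste(names(s), format(s, digits = 10, trim = TRUE), sep = "\t"),
             file.path(dir, "summary.txt"))
  invisible(dir)
}
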