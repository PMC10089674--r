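# Benchmark metrics: precision-recall against a ground-truth mask, using the
# average-precision step rule for the area, plus rank-of-truth summaries and
# bootstrap confidence bands.

#' Precision-recall curve and average precision
#'
#' Ranks all cells by ascending P-value (ties broken by descending `|zhat|`
#' when supplied, then by stable cell order) and computes precision and recall
#' at every rank.  The area is the average-precision step rule: the mean over
#' true cells of the precision at the rank where each is hit.
#'
#' @param pvalues matrix of P-value scores (smaller = more outlying).
#' @param truth logical matrix of the same shape, `TRUE` at true outliers.
#' @param zhat optional z-score matrix used only for tie-breaking.
#' @return object of class `outsvd_pr`: list with vectors `precision`,
#'   `recall`, `threshold` (the P-value at each rank) and scalar `auc`.
#' @export
pr_curve <- function(pvalues, truth, zhat = NULL) {
  validate_real_matrix(pvalues)
  stopifnot(identical(dim(pvalues), dim(truth)), is.logical(truth))
  n_truth <- sum(truth)
  if (n_truth < 1L)
    osv_stop("outsvd_empty_truth", "truth mask contains no true cells")
  tie <- if (is.null(zhat)) rep(0, length(pvalues)) else -abs(zhat)
  ord <- order(as.vector(pvalues), as.vector(tie))
  hits <- as.vector(truth)[ord]
  tp <- cumsum(hits)
  precision <- tp / seq_along(tp)
  recall <- tp / n_truth
  structure(list(precision = precision, recall = recall,
                 threshold = as.vector(pvalues)[ord],
                 auc = sum(precision[hits]) / n_truth),
            class = "outsvd_pr")
}

#' @export
print.outsvd_pr <- function(x, ...) {
  cat(sprintf("Precision-recall curve over %d cells: AUC-PR (average precision) = %.4f\n",
              length(x$precision), x$auc))
  invisible(x)
}

#' Global ranks of the true outliers
#'
#' 1-based rank of each true cell when all J x N P-values are sorted
#' ascending; tied P-values share the minimum rank of the tied block.
#'
#' @inheritParams pr_curve
#' @return integer vector, one rank per true cell (row-major cell order).
#' @export
truth_ranks <- function(pvalues, truth) {
  validate_real_matrix(pvalues)
  stopifnot(identical(dim(pvalues), dim(truth)), is.logical(truth))
  if (sum(truth) < 1L)
    osv_stop("outsvd_empty_truth", "truth mask contains no true cells")
  r <- rank(as.vector(pvalues), ties.method = "min")
  as.integer(r[as.vector(truth)])
}

#' Bootstrap confidence bands for a precision-recall curve
#'
#' Resamples the true cells and the non-true cells (each stratum at its
#' original size, with replacement) `n_boot` times, recomputes the PR curve,
#' reads precision off a fixed recall grid (step interpolation), and returns
#' the 2.5/97.5 percentile band together with the point estimate.
#'
#' @inheritParams pr_curve
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param recall_grid recall values at which the band is evaluated.
#' @return data frame with columns `recall`, `lower`, `estimate`, `upper`.
#' @export
bootstrap_pr <- function(pvalues, truth, n_boot = 200L, seed = 1L,
                         recall_grid = seq(0.05, 1, by = 0.05)) {
  validate_real_matrix(pvalues)
  stopifnot(identical(dim(pvalues), dim(truth)), is.logical(truth),
            n_boot >= 100L)
  if (sum(truth) < 2L)
    osv_stop("outsvd_empty_truth", "bootstrap needs at least 2 true cells")
  p <- as.vector(pvalues)
  pos <- p[as.vector(truth)]
  neg <- p[!as.vector(truth)]
  prec_at <- function(pp, nn) {
    ord <- order(c(pp, nn))
    hits <- c(rep(TRUE, length(pp)), rep(FALSE, length(nn)))[ord]
    tp <- cumsum(hits)
    prec <- tp / seq_along(tp)
    rec <- tp / length(pp)
    # precision at the first rank reaching each grid recall
    vapply(recall_grid, function(g) {
      i <- which(rec >= g - 1e-12 & hits)
      if (length(i) == 0L) 0 else prec[i[1L]]
    }, numeric(1L))
  }
  est <- prec_at(pos, neg)
  bands <- withr::with_seed(as.integer(seed), {
    reps <- replicate(n_boot, prec_at(sample(pos, replace = TRUE),
                                      sample(neg, replace = TRUE)))
    apply(reps, 1L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  })
  data.frame(recall = recall_grid, lower = bands[1L, ], estimate = est,
             upper = bands[2L, ])
}

#' Write PR evaluation results to TSV files
#'
#' Emits `pr_curve.tsv` (recall, precision, threshold per rank) and a
#' key-value `summary.txt` with the AUC and the truth-rank quantiles;
#' optionally `bootstrap.tsv` with the confidence band.
#'
#' @param pr `outsvd_pr` from [pr_curve()].
#' @param ranks integer vector from [truth_ranks()].
#' @param dir output directory, created if missing.
#' @param bands optional data frame from [bootstrap_pr()].
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(pr, ranks, dir, bands = NULL) {
  stopifnot(inherits(pr, "outsvd_pr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(recall = pr$recall, precision = pr$precision,
               threshold = pr$threshold),
    file.path(dir, "pr_curve.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  s <- c(auc_pr = pr$auc, n_truth = length(ranks),
         median_truth_rank = stats::median(ranks),
         max_truth_rank = max(ranks))
  writeLines(paste(names(s), format(s, digits = 10, trim = TRUE), sep = "\t"),
             file.path(dir, "summary.txt"))
  if (!is.null(bands))
    utils::write.table(bands, file.path(dir, "bootstrap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}
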