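# Benchmark construction: plan outlier locations/magnitudes, plant them in the
# noise component of the decomposition, and invert the normalization back to
# integer counts.  The confounder (signal) component is untouched, so the
# planted outliers are masked exactly the way real aberrant counts are.

#' Plan artificial outliers for a dataset
#'
#' Chooses cells and signed z-magnitudes.  In `per_sample` mode exactly one
#' outlier is placed in every sample, at a gene drawn uniformly from the
#' eligible (non-degenerate) genes — the single-gene Mendelian scenario.  In
#' `frequency` mode every eligible cell is drawn independently with the given
#' probability.  Signs are positive for `overexpressed`, negative for
#' `underexpressed`, and a fair coin for `both`.
#'
#' @param counts validated count matrix.
#' @param scheme `"overexpressed"`, `"underexpressed"` or `"both"`.
#' @param magnitude positive outlier magnitude in noise z-score units;
#'   values of 6-8 exceed the expected extreme of the null (about 5 for a
#'   10^6-cell matrix, see [expected_extreme_z()]).
#' @param mode `"per_sample"` (default) or `"frequency"`.
#' @param frequency per-cell injection probability in (0, 1); only used in
#'   `frequency` mode (a conventional value is 1e-4).
#' @param seed integer seed; the plan is a pure function of (inputs, seed).
#' @return object of class `outsvd_spec`: data frame `entries` with columns
#'   `gene`, `sample`, `z` plus the planning parameters as attributes.
#' @export
plan_outliers <- function(counts, scheme = c("both", "overexpressed", "underexpressed"),
                          magnitude = 6, mode = c("per_sample", "frequency"),
                          frequency = 1e-4, seed = 1L) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  validate_counts(counts)
  if (!is.numeric(magnitude) || magnitude <= 0)
    osv_stop("outsvd_bad_magnitude", "magnitude must be > 0, got %s",
             format(magnitude))
  norm <- normalize_counts(counts)
  eligible <- rownames(counts)[!norm$stats$degenerate]
  if (length(eligible) == 0L)
    osv_stop("outsvd_no_eligible_genes",
             "no non-degenerate genes available for injection")
  entries <- withr::with_seed(as.integer(seed), {
    if (mode == "per_sample") {
      data.frame(gene = sample(eligible, ncol(counts), replace = TRUE),
                 sample = colnames(counts), stringsAsFactors = FALSE)
    } else {
      if (frequency <= 0 || frequency >= 1)
        osv_stop("outsvd_bad_frequency", "frequency must lie in (0, 1)")
      hit <- which(matrix(stats::runif(length(eligible) * ncol(counts)),
                          length(eligible)) < frequency, arr.ind = TRUE)
      data.frame(gene = eligible[hit[, 1L]],
                 sample = colnames(counts)[hit[, 2L]],
                 stringsAsFactors = FALSE)
    }
  })
  sign <- withr::with_seed(as.integer(seed) + 1L, switch(scheme,
    overexpressed = rep(1, nrow(entries)),
    underexpressed = rep(-1, nrow(entries)),
    both = sample(c(-1, 1), nrow(entries), replace = TRUE)))
  entries$z <- sign * magnitude
  structure(list(entries = entries, scheme = scheme, magnitude = magnitude,
                 mode = mode, frequency = frequency, seed = as.integer(seed)),
            class = "outsvd_spec")
}

#' Inject planned outliers into a count matrix
#'
#' Runs the forward pipeline, replaces the noise value at each planned cell by
#' `mean_j(noise) + z * sd_j(noise)` (so the detector recovers a noise z-score
#' of about `z` there), re-adds the untouched low-rank signal, and inverts the
#' standardization back to integer counts.  With an empty plan the output is
#' bit-identical to the input.
#'
#' @param counts validated count matrix.
#' @param spec `outsvd_spec` from [plan_outliers()].
#' @return list with `counts` (new count matrix) and `truth` (logical matrix,
#'   `TRUE` at injected cells).
#' @export
inject_outliers <- function(counts, spec) {
  stopifnot(inherits(spec, "outsvd_spec"))
  validate_counts(counts)
  norm <- normalize_counts(counts)
  split <- split_signal_noise(norm$z)
  nstats <- standardize_rows(split$noise)$stats
  truth <- matrix(FALSE, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  e <- spec$entries
  if (nrow(e) > 0L) {
    jj <- match(e$gene, rownames(counts))
    ii <- match(e$sample, colnames(counts))
    if (any(is.na(jj)) || any(is.na(ii)))
      osv_stop("outsvd_bad_cell", "spec refers to unknown gene or sample IDs")
    if (anyDuplicated(cbind(jj, ii)))
      osv_stop("outsvd_bad_cell", "spec contains duplicate cells")
    if (any(nstats$degenerate[jj]))
      osv_stop("outsvd_bad_cell", "spec targets a degenerate (zero-spread) gene")
    noise <- split$noise
    noise[cbind(jj, ii)] <- nstats$mean[jj] + e$z * nstats$sd[jj]
    ztilde <- split$signal + noise
    truth[cbind(jj, ii)] <- TRUE
  } else {
    ztilde <- norm$z
  }
  k <- invert_standardization(ztilde, norm$stats, norm$size_factors)
  list(counts = k, truth = truth)
}

#' Expected extreme absolute z-score of an i.i.d. standard-normal matrix
#'
#' For `n = J * N` independent standard-normal draws the maximum of `|z|` has
#' distribution function `(2 Phi(x) - 1)^n`; its expectation is computed as
#' `integral_0^Inf (1 - (2 Phi(x) - 1)^n) dx`.  This is the natural floor for
#' injection magnitudes: planted outliers below it are indistinguishable from
#' the extremes the null already produces.
#'
#' @param J,N matrix dimensions (J * N >= 2).
#' @return the expected maximum absolute z-score (about 5 for a matrix of
#'   10^6 cells).
#' @export
expected_extreme_z <- function(J, N) {
  n <- as.numeric(J) * as.numeric(N)
  stopifnot(n >= 2)
  # survival-function form of E[max]; integrand decays like a Gaussian tail
  stats::integrate(function(x) 1 - (2 * stats::pnorm(x) - 1)^n,
                   0, Inf, rel.tol = 1e-10, abs.tol = 1e-8)$value
}

#' Write an injected dataset to TSV files
#'
#' Emits `counts.tsv`, a 0/1 `truth.tsv`, and the plan as a three-column
#' `spec.tsv` (gene, sample, signed z-magnitude).
#'
#' @param injected list from [inject_outliers()].
#' @param spec the `outsvd_spec` used.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_injection <- function(injected, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(injected$counts, file.path(dir, "counts.tsv"))
  write_matrix(injected$truth + 0, file.path(dir, "truth.tsv"))
  utils::write.table(spec$entries, file.path(dir, "spec.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
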