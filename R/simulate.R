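# Synthetic data: gene-wise negative-binomial counts with log-normal spread of
# gene means and dispersions, optional low-rank confounder structure acting
# multiplicatively on the log2 mean, and per-sample depth multipliers.

#' Simulate a negative-binomial count matrix with optional confounders
#'
#' Gene base means are drawn log-normally, negative-binomial size parameters
#' log-normally, and each count is
#' `k_ji ~ NB(mean = d_i * mu_j * 2^C_ji, size = r_j)` where `C = A B^T` is a
#' rank-`n_confounders` matrix of log2 perturbations (Gaussian loadings with
#' standard deviation `confounder_sd`) and `d_i` is a log-normal depth
#' multiplier.  Confounders are exactly low-rank in the log2 domain the
#' detector standardizes, so rank recovery is a sharp test.
#'
#' @param n_genes,n_samples matrix dimensions (J, N).
#' @param mean_log_mu,sd_log_mu natural-log mean and sd of the gene base means
#'   (defaults give a median of about 200 counts spanning roughly 10-10^4).
#' @param dispersion_log_mean,dispersion_log_sd natural-log mean and sd of the
#'   per-gene NB size parameters (defaults center on size 8, a typical bulk
#'   RNA-Seq overdispersion).
#' @param n_confounders number of planted confounder dimensions (k >= 0,
#'   k < min(J, N)).
#' @param confounder_sd scale of the Gaussian confounder loadings; the log2
#'   perturbation of a cell has standard deviation about
#'   `confounder_sd^2 * sqrt(k)`.
#' @param depth_sd log-scale spread of per-sample depth multipliers.
#' @param seed integer seed; same seed, same matrix.
#' @return list with `counts` (count matrix) and `meta` (list of all latent
#'   values: `mu`, `size`, `depth`, `confounders`, loadings `A`, `B`).
#' @export
simulate_counts <- function(n_genes = 2000L, n_samples = 100L,
                            mean_log_mu = log(200), sd_log_mu = 1,
                            dispersion_log_mean = log(8),
                            dispersion_log_sd = 0.8,
                            n_confounders = 3L, confounder_sd = 0.7,
                            depth_sd = 0.3, seed = 1L) {
  J <- as.integer(n_genes); N <- as.integer(n_samples)
  k <- as.integer(n_confounders)
  if (J < 2L || N < 2L)
    osv_stop("outsvd_bad_config", "need at least 2 genes and 2 samples")
  if (k < 0L || k >= min(J, N))
    osv_stop("outsvd_bad_config", "n_confounders must satisfy 0 <= k < min(J, N)")
  if (confounder_sd < 0 || depth_sd < 0 || sd_log_mu < 0 || dispersion_log_sd < 0)
    osv_stop("outsvd_bad_config", "scale parameters must be >= 0")
  withr::with_seed(as.integer(seed), {
    mu <- stats::rlnorm(J, mean_log_mu, sd_log_mu)
    size <- stats::rlnorm(J, dispersion_log_mean, dispersion_log_sd)
    depth <- stats::rlnorm(N, 0, depth_sd)
    if (k > 0L) {
      A <- matrix(stats::rnorm(J * k, sd = confounder_sd), J, k)
      B <- matrix(stats::rnorm(N * k, sd = confounder_sd), N, k)
      C <- A %*% t(B)
    } else {
      A <- B <- NULL
      C <- matrix(0, J, N)
    }
    m <- outer(mu, depth) * 2^C
    counts <- matrix(stats::rnbinom(J * N, mu = m, size = size), J, N)
    dimnames(counts) <- list(sprintf("gene_%05d", seq_len(J)),
                             sprintf("sample_%03d", seq_len(N)))
    list(counts = counts,
         meta = list(mu = mu, size = size, depth = depth, confounders = C,
                     A = A, B = B, seed = as.integer(seed)))
  })
}

#' Pure standard-normal z-score matrix
#'
#' A noise-only fixture: J x N independent standard-normal draws, used for
#' calibration checks of the scoring stages.
#'
#' @param J,N dimensions (both >= 2).
#' @param seed integer seed.
#' @return numeric matrix with gene/sample dimnames.
#' @export
null_zscore_matrix <- function(J, N, seed = 1L) {
  stopifnot(J >= 2L, N >= 2L)
  withr::with_seed(as.integer(seed), {
    z <- matrix(stats::rnorm(J * N), J, N)
    dimnames(z) <- list(sprintf("gene_%05d", seq_len(J)),
                        sprintf("sample_%03d", seq_len(N)))
    z
  })
}

#' Write a simulated dataset to TSV files
#'
#' Emits `counts.tsv` and a `metadata.tsv` with per-gene means, NB sizes and
#' confounder loadings, plus per-sample depths and loadings in
#' `sample_metadata.tsv`.
#'
#' @param sim list from [simulate_counts()].
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(sim$counts, file.path(dir, "counts.tsv"))
  gm <- data.frame(gene = rownames(sim$counts), mu = sim$meta$mu,
                   size = sim$meta$size)
  if (!is.null(sim$meta$A))
    gm <- cbind(gm, stats::setNames(as.data.frame(sim$meta$A),
                                    paste0("loading_", seq_len(ncol(sim$meta$A)))))
  utils::write.table(gm, file.path(dir, "gene_metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sm <- data.frame(sample = colnames(sim$counts), depth = sim$meta$depth)
  if (!is.null(sim$meta$B))
    sm <- cbind(sm, stats::setNames(as.data.frame(sim$meta$B),
                                    paste0("loading_", seq_len(ncol(sim$meta$B)))))
  utils::write.table(sm, file.path(dir, "sample_metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
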