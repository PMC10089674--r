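# Shared fixtures and independent brute-force oracles.  Oracles deliberately
# use the most literal formulation available, never the package's own code
# path.

make_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# median-of-ratios, enumerated gene by gene
oracle_size_factors <- function(k) {
  geo <- apply(k, 1L, function(row) prod(row)^(1 / length(row)))
  ok <- geo > 0
  vapply(seq_len(ncol(k)), function(i)
    median(k[ok, i] / geo[ok]), numeric(1L))
}

# Benjamini-Yekutieli step-up, direct definition
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- p[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# average precision via an explicit confusion-matrix sweep over thresholds
oracle_average_precision <- function(score, truth) {
  ord <- order(score)
  hits <- truth[ord]
  total <- 0
  for (r in which(hits)) {
    tp <- sum(hits[seq_len(r)])
    total <- total + tp / r
  }
  total / sum(truth)
}

# small NB dataset reused across tests; high means keep rounding benign
small_sim <- function(seed = 42L, k = 3L, J = 600L, N = 40L) {
  simulate_counts(n_genes = J, n_samples = N, n_confounders = k, seed = seed)
}
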