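# Low-rank confounder removal: SVD of the standardized matrix, then the
# optimal hard threshold (OHT) for singular values with unknown noise level.
# The threshold is omega(beta) * sigma_median, where sigma_median is the median
# singular value and omega(beta) = lambda(beta) / sqrt(mu_beta), mu_beta being
# the median of the Marchenko-Pastur law with aspect ratio beta.

#' Median of the Marchenko-Pastur distribution
#'
#' Solves for the median of the Marchenko-Pastur eigenvalue density with
#' aspect ratio `beta` (unit noise variance), i.e. the `t` at which the
#' integral of
#' `sqrt(((1+sqrt(beta))^2 - x) * (x - (1-sqrt(beta))^2)) / (2 pi beta x)`
#' over the support reaches 1/2.  Quadrature to 1e-9 absolute tolerance and
#' bracketed root finding within the support.
#'
#' @param beta aspect ratio in (0, 1], i.e. min(J, N) / max(J, N).
#' @return the median `mu_beta` (a value near 1 for small `beta`).
#' @export
mp_median <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0 || beta > 1)
    osv_stop("outsvd_bad_beta", "beta must lie in (0, 1], got %s", format(beta))
  lo <- (1 - sqrt(beta))^2
  hi <- (1 + sqrt(beta))^2
  dens <- function(t) sqrt(pmax((hi - t) * (t - lo), 0)) / (2 * pi * beta * t)
  cdf <- function(x)
    stats::integrate(dens, lo, x, rel.tol = 1e-10, abs.tol = 1e-9,
                     subdivisions = 500L)$value
  eps <- (hi - lo) * 1e-12
  stats::uniroot(function(x) cdf(x) - 0.5, c(lo + eps, hi - eps),
                 tol = 1e-10)$root
}

lambda_coef <- function(beta) {
  sqrt(2 * (beta + 1) + 8 * beta / ((beta + 1) + sqrt(beta^2 + 14 * beta + 1)))
}

#' Optimal hard threshold coefficient for unknown noise level
#'
#' `omega(beta) = lambda(beta) / sqrt(mu_beta)` with
#' `lambda(beta) = sqrt(2(beta+1) + 8 beta / ((beta+1) + sqrt(beta^2+14 beta+1)))`.
#' Multiplying the median singular value of a noisy matrix by `omega(beta)`
#' gives the singular-value cutoff that asymptotically minimizes the
#' reconstruction mean squared error of hard thresholding.
#'
#' @inheritParams mp_median
#' @return the coefficient `omega(beta)`; `omega(1)` is about 2.858.
#' @export
omega_coef <- function(beta) {
  lambda_coef(beta) / sqrt(mp_median(beta))
}

#' Thin SVD of a z-score matrix
#'
#' @param z numeric matrix with more rows than columns (transpose first
#'   otherwise; [split_signal_noise()] handles orientation automatically).
#' @return list with orthonormal `u` (J x m), singular values `d`
#'   (non-increasing, m = min(J, N)), and orthonormal `v` (N x m).
#' @export
svd_decompose <- function(z) {
  validate_real_matrix(z)
  if (nrow(z) < ncol(z))
    osv_stop("outsvd_bad_shape",
             "svd_decompose expects genes >= samples; transpose the input")
  s <- svd(z)
  list(u = s$u, d = s$d, v = s$v)
}

#' Select the signal rank by the optimal hard threshold
#'
#' Computes `beta = min(J,N)/max(J,N)`, the median singular value, the
#' threshold `omega(beta) * sigma_median`, and the number of singular values
#' strictly above it.
#'
#' @param sv non-increasing singular values (or the list from
#'   [svd_decompose()]).
#' @param J,N dimensions of the matrix the singular values came from.
#' @return object of class `outsvd_oht`: list with `beta`, `mp_median`,
#'   `lambda_coef`, `omega_coef`, `median_sv`, `threshold`, `rank`.
#' @export
select_rank <- function(sv, J, N) {
  if (is.list(sv)) sv <- sv$d
  m <- min(J, N)
  stopifnot(length(sv) == m, !is.unsorted(rev(sv)))
  beta <- m / max(J, N)
  mu <- mp_median(beta)
  lam <- lambda_coef(beta)
  omega <- lam / sqrt(mu)
  med <- stats::median(sv)
  thr <- omega * med
  structure(list(beta = beta, mp_median = mu, lambda_coef = lam,
                 omega_coef = omega, median_sv = med, threshold = thr,
                 rank = sum(sv > thr)),
            class = "outsvd_oht")
}

#' @export
print.outsvd_oht <- function(x, ...) {
  cat(sprintf(paste0("Optimal hard threshold: rank %d\n",
                     "  beta = %.4f, MP median = %.4f, omega = %.4f\n",
                     "  median singular value = %.4f, threshold = %.4f\n"),
              x$rank, x$beta, x$mp_median, x$omega_coef, x$median_sv,
              x$threshold))
  invisible(x)
}

#' Split a z-score matrix into low-rank signal and residual noise
#'
#' Reconstructs the signal (confounder) matrix from the singular triplets above
#' the optimal hard threshold and the noise matrix from the remainder, so that
#' `signal + noise == z` to numerical precision.  Inputs wider than tall are
#' transposed internally (the threshold formulas assume aspect ratio <= 1) and
#' transposed back.
#'
#' @param z numeric z-score matrix.
#' @param rank optional manual rank override (diagnostics, ablations); `NULL`
#'   selects the rank by [select_rank()].
#' @return list with matrices `signal` and `noise`, the `outsvd_oht` object
#'   `oht`, and the singular values `sv`.
#' @export
split_signal_noise <- function(z, rank = NULL) {
  validate_real_matrix(z)
  J <- nrow(z); N <- ncol(z)
  flip <- N > J
  zz <- if (flip) t(z) else z
  s <- svd_decompose(zz)
  oht <- select_rank(s$d, nrow(zz), ncol(zz))
  r <- if (is.null(rank)) oht$rank else {
    stopifnot(rank >= 0L, rank <= length(s$d))
    as.integer(rank)
  }
  if (!is.null(rank)) {
    oht$rank <- r
    oht$overridden <- TRUE
  }
  if (r == 0L) {
    signal <- array(0, dim(zz), dimnames = dimnames(zz))
  } else {
    signal <- s$u[, seq_len(r), drop = FALSE] %*%
      (s$d[seq_len(r)] * t(s$v[, seq_len(r), drop = FALSE]))
    dimnames(signal) <- dimnames(zz)
  }
  noise <- zz - signal
  if (flip) { signal <- t(signal); noise <- t(noise) }
  list(signal = signal, noise = noise, oht = oht, sv = s$d)
}
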