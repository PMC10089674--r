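test_that("size factors match hand values and the brute-force oracle", {
  # identical columns -> all ones
  same <- make_counts(cbind(c(3, 8, 1), c(3, 8, 1), c(3, 8, 1)))
  expect_equal(size_factors(same), c(s1 = 1, s2 = 1, s3 = 1))

  # hand evaluation: geomeans (2.828, 11.314); ratio columns constant
  k <- make_counts(rbind(c(2, 4), c(8, 16)))
  expect_equal(unname(size_factors(k)), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  set.seed(11)
  for (rep in 1:5) {
    k <- make_counts(matrix(rpois(18, 30) + 1, 6, 3))
    expect_equal(unname(size_factors(k)), oracle_size_factors(k),
                 tolerance = 1e-12)
  }
})

test_that("genes with zero counts are excluded from the size-factor median", {
  k <- make_counts(rbind(c(0, 100), c(2, 4), c(8, 16)))
  expect_equal(unname(size_factors(k)), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  all0 <- make_counts(rbind(c(0, 1), c(1, 0)))
  expect_error(size_factors(all0), class = "outsvd_no_reference_genes")
})

test_that("log fold transform matches hand evaluation and handles edge rows", {
  k <- make_counts(rbind(c(1, 3, 7), c(0, 0, 0), c(4, 4, 4)))
  lf <- log_fold_transform(k, setNames(c(1, 1, 1), colnames(k)))
  expect_equal(unname(lf$l[1, ]),
               log2(c(2, 4, 8) / (11 / 3 + 1)), tolerance = 1e-12)
  expect_equal(unname(lf$l[2, ]), c(0, 0, 0))   # all-zero gene: log2(1/1)
  expect_equal(unname(lf$l[3, ]), c(0, 0, 0))   # constant at its own mean
  expect_equal(unname(lf$baseline), c(11 / 3, 0, 4))
})

test_that("standardize_rows produces exact moments and flags degenerate rows", {
  l <- make_counts(rbind(c(1, 2, 3), c(5, 5, 5)))
  std <- standardize_rows(l)
  expect_equal(unname(std$z[1, ]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_identical(std$stats$degenerate, c(FALSE, TRUE))
  expect_equal(unname(std$z[2, ]), c(0, 0, 0))

  # population vs sample divisor
  std2 <- standardize_rows(l, sd_divisor = "sample")
  expect_equal(unname(std2$z[1, ]), c(-1, 0, 1), tolerance = 1e-12)

  set.seed(2)
  big <- make_counts(matrix(rnorm(400), 40, 10))
  s <- standardize_rows(big)
  expect_lt(max(abs(rowMeans(s$z))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(s$z^2)) - 1)), 1e-9)
})

test_that("forward/inverse normalization is the exact identity on counts", {
  for (seed in c(1L, 2L, 3L)) {
    sim <- small_sim(seed = seed, J = 300L, N = 25L)
    norm <- normalize_counts(sim$counts)
    back <- invert_standardization(norm$z, norm$stats, norm$size_factors)
    expect_identical(unname(back), unname(sim$counts + 0))
  }
})

test_that("inversion is monotone in z and degenerate rows are z-invariant", {
  sim <- small_sim(seed = 9L, J = 200L, N = 20L)
  counts <- sim$counts
  counts[1, ] <- 7     # constant controlled row only if sf == 1; force spread
  norm <- normalize_counts(counts)
  z2 <- norm$z
  pick <- which(!norm$stats$degenerate)[5]
  z2[pick, 3] <- z2[pick, 3] + 6
  back <- invert_standardization(z2, norm$stats, norm$size_factors)
  orig <- invert_standardization(norm$z, norm$stats, norm$size_factors)
  expect_gt(back[pick, 3], orig[pick, 3])
  # all other cells unchanged
  expect_identical(back[-pick, ], orig[-pick, ])

  # two constant genes: size factors are all 1, both rows degenerate
  const <- make_counts(rbind(c(5, 5, 5), c(9, 9, 9)))
  norm2 <- normalize_counts(const)
  zz <- norm2$z
  zz[1, ] <- c(-4, 0, 4)  # degenerate row ignores z
  expect_identical(invert_standardization(zz, norm2$stats, norm2$size_factors)[1, ],
                   invert_standardization(norm2$z, norm2$stats, norm2$size_factors)[1, ])
})

test_that("size factors scale with per-sample depth and z is depth-invariant", {
  sim <- small_sim(seed = 5L, J = 400L, N = 12L)
  k <- sim$counts + 50   # keep counts well above the pseudocount
  s1 <- size_factors(k)
  k2 <- k; k2[, 3] <- k2[, 3] * 4L
  s2 <- size_factors(k2)
  # scaling one sample rescales the geometric means too, so the covariance is
  # exact only for relative size factors
  expect_equal(unname((s2[3] / s2[1]) / (s1[3] / s1[1])), 4, tolerance = 1e-10)

  z1 <- normalize_counts(k)$z
  z2 <- normalize_counts(k2)$z
  expect_lt(max(abs(z1 - z2)), 0.05)
})

test_that("inversion overflow names the offending cell", {
  sim <- small_sim(seed = 1L, J = 100L, N = 10L)
  norm <- normalize_counts(sim$counts)
  z <- norm$z
  z[4, 2] <- 1e6
  err <- expect_error(invert_standardization(z, norm$stats, norm$size_factors),
                      class = "outsvd_overflow")
  expect_match(conditionMessage(err), rownames(z)[4])
})
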