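test_that("plan_outliers respects mode, scheme and magnitude constraints", {
  sim <- small_sim(seed = 61L, J = 300L, N = 119L)
  spec <- plan_outliers(sim$counts, scheme = "overexpressed", magnitude = 6,
                        seed = 2L)
  expect_identical(nrow(spec$entries), 119L)       # one per sample
  expect_identical(sort(spec$entries$sample), sort(colnames(sim$counts)))
  expect_true(all(spec$entries$z == 6))

  under <- plan_outliers(sim$counts, scheme = "underexpressed", magnitude = 7,
                         seed = 2L)
  expect_true(all(under$entries$z == -7))

  for (m in c(6, 7, 8))
    expect_s3_class(plan_outliers(sim$counts, "both", m, seed = 1L),
                    "outsvd_spec")
  expect_error(plan_outliers(sim$counts, "both", 0),
               class = "outsvd_bad_magnitude")
  expect_error(plan_outliers(sim$counts, "both", 6, mode = "frequency",
                             frequency = 2), class = "outsvd_bad_frequency")
})

test_that("the 50/50 sign split holds for scheme = both", {
  sim <- simulate_counts(n_genes = 100L, n_samples = 1000L, n_confounders = 0L,
                         seed = 62L)
  spec <- plan_outliers(sim$counts, scheme = "both", magnitude = 6, seed = 3L)
  frac_pos <- mean(spec$entries$z > 0)
  expect_gte(frac_pos, 0.42)
  expect_lte(frac_pos, 0.58)
})

test_that("frequency mode draws cells at approximately the requested rate", {
  sim <- small_sim(seed = 63L, J = 1000L, N = 100L)
  spec <- plan_outliers(sim$counts, scheme = "both", magnitude = 6,
                        mode = "frequency", frequency = 1e-3, seed = 4L)
  # 1e5 eligible cells at 1e-3: ~100 expected, Poisson-ish spread
  expect_gt(nrow(spec$entries), 50L)
  expect_lt(nrow(spec$entries), 160L)
  expect_false(anyDuplicated(spec$entries[c("gene", "sample")]) > 0)
})

test_that("plans and injections are deterministic in the seed", {
  sim <- small_sim(seed = 64L, J = 200L, N = 20L)
  s1 <- plan_outliers(sim$counts, "both", 6, seed = 9L)
  s2 <- plan_outliers(sim$counts, "both", 6, seed = 9L)
  expect_identical(s1, s2)
  expect_identical(inject_outliers(sim$counts, s1)$counts,
                   inject_outliers(sim$counts, s2)$counts)
})

test_that("inject with an empty plan is the exact identity", {
  sim <- small_sim(seed = 65L, J = 150L, N = 15L)
  spec <- plan_outliers(sim$counts, "both", 6, seed = 1L)
  spec$entries <- spec$entries[0, ]
  out <- inject_outliers(sim$counts, spec)
  expect_identical(unname(out$counts), unname(sim$counts + 0))
  expect_identical(sum(out$truth), 0L)
})

test_that("injected cells rise in count, leave neighbours nearly untouched, and are re-detected", {
  # N = 100: a planted 6-sigma cell inflates its own row's sd when the
  # detector re-standardizes, so the recovered z sits near 4.5, not 6; at
  # small N that attenuation would dominate, hence a realistic sample count
  sim <- small_sim(seed = 66L, J = 500L, N = 100L)
  spec <- plan_outliers(sim$counts, "overexpressed", 6, seed = 7L)
  out <- inject_outliers(sim$counts, spec)
  expect_identical(sum(out$truth), nrow(spec$entries))
  jj <- match(spec$entries$gene, rownames(sim$counts))
  ii <- match(spec$entries$sample, colnames(sim$counts))
  expect_true(all(out$truth[cbind(jj, ii)]))
  expect_true(all(out$counts[cbind(jj, ii)] > sim$counts[cbind(jj, ii)]))
  # non-injected cells move by at most one count (rounding)
  delta <- abs(out$counts - sim$counts)
  delta[cbind(jj, ii)] <- 0
  expect_lte(max(delta), 1)

  rep <- detect_outliers(out$counts)
  base <- rep$norm$stats$baseline[jj]
  high <- base >= 50
  expect_true(all(abs(rep$zhat[cbind(jj, ii)][high]) >= 4))
})

test_that("injection preserves the confounder rank", {
  agree <- vapply(1:20, function(seed) {
    sim <- simulate_counts(n_genes = 500L, n_samples = 40L, n_confounders = 3L,
                           seed = 400L + seed)
    r0 <- detect_outliers(sim$counts)$oht$rank
    spec <- plan_outliers(sim$counts, "both", 6, seed = seed)
    inj <- inject_outliers(sim$counts, spec)
    r1 <- detect_outliers(inj$counts)$oht$rank
    r0 == r1
  }, logical(1))
  expect_gte(sum(agree), 18L)
})

test_that("expected extreme z matches the published-scale value and a MC oracle", {
  e <- expected_extreme_z(10556L, 119L)
  expect_identical(round(e), 5)
  expect_gt(expected_extreme_z(2L * 10556L, 119L), e)

  mc <- withr::with_seed(123L, {
    mean(replicate(2000, max(abs(rnorm(1e4)))))
  })
  expect_equal(expected_extreme_z(100L, 100L), mc, tolerance = 0.01)
})

test_that("write_injection emits counts, truth and spec files", {
  sim <- small_sim(seed = 67L, J = 100L, N = 10L)
  spec <- plan_outliers(sim$counts, "both", 6, seed = 1L)
  out <- inject_outliers(sim$counts, spec)
  dir <- withr::local_tempdir()
  write_injection(out, spec, dir)
  expect_identical(read_counts(file.path(dir, "counts.tsv")), out$counts)
  tm <- read_real_matrix(file.path(dir, "truth.tsv")) != 0
  expect_identical(unname(tm), unname(out$truth))
})
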