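---
title: "Methods: outlier detection and injection by SVD hard thresholding"
author: "outsvd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outlier detection and injection by SVD hard thresholding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(outsvd)
```

## The model

An RNA-Seq cohort is a J × N matrix of counts, J genes, N same-tissue
samples, J ≫ N. The working assumption is that counts are log-normal within
a gene once sequencing depth is controlled, that unobserved confounders add
*coherent low-rank* structure to the standardized log matrix, and that true
aberrant-expression events are *sparse impulses* — too sparse to be captured
by any low-rank component, hence guaranteed to survive in the residual.

The forward pipeline:

1. **Size factors.** Median-of-ratios: `s_i = median_j k_ji / g_j`, where
   `g_j` is gene j's geometric mean across samples, computed in log space.
   Genes with any zero count have `g_j = 0` and are excluded from the
   median; at least one all-positive gene is required.
2. **Log fold changes.** `c_ji = k_ji / s_i`,
   `l_ji = log2((c_ji + 1)/(c̄_j + 1))` with `c̄_j` the gene mean of the
   controlled counts. The pseudocount is exactly 1 on both sides.
3. **Standardization.** `z̃_ji = (l_ji − μ_j)/τ_j` using the *population*
   (divisor-N) standard deviation. Rows with `τ_j = 0` are flagged
   degenerate, carried through as all-zero z rows, and never called.
4. **Confounder split.** Thin SVD of `Z̃`; the signal rank is the number of
   singular values strictly above `ω(β)·σ_median`. `signal + noise`
   reconstructs `Z̃` to machine precision.
5. **Scoring.** The residual is standardized gene-wise again (noise levels
   differ between genes), two-sided normal P-values are taken, and the whole
   J·N matrix is corrected jointly with Benjamini–Yekutieli.

## The optimal hard threshold

For a data matrix that is low-rank signal plus i.i.d. Gaussian noise of
*unknown* level, the asymptotically MSE-optimal hard threshold for singular
values is `ω(β)·σ_median` with `β = N/J ≤ 1`,

    λ(β) = sqrt(2(β+1) + 8β / ((β+1) + sqrt(β² + 14β + 1)))
    ω(β) = λ(β) / sqrt(μ_β)

and `μ_β` the median of the Marčenko–Pastur eigenvalue distribution with
aspect ratio β, obtained here by adaptive quadrature of the MP density over
its support `[(1−√β)², (1+√β)²]` and bracketed root finding (absolute
tolerance 1e-9). Using the *median* singular value makes the calibration
independent of the unknown noise scale. `λ(1) = √(16/3) ≈ 2.309`,
`ω(1) ≈ 2.858`; the test suite validates ω(1) against an independent
Monte-Carlo grid search for the AMSE-optimal threshold and `μ_β` against
empirical Wishart spectra.

Numerical choices: inputs wider than tall are transposed internally so
β ≤ 1 always holds; rank counting uses strict inequality (ties at the
threshold have probability zero); a manual rank override is available for
ablations (`rank = 0` scores the standardized matrix directly, without
confounder removal).

## Outlier injection by inversion

Every forward step retains its state (`s_i`, `c̄_j`, `μ_j`, `τ_j`), so the
pipeline can be run backwards. To plant an outlier of magnitude m at cell
(j, i): replace the residual value by `mean_j(E) + m·sd_j(E)`, re-add the
untouched low-rank signal, and invert the standardization to counts
(`round` half-to-even, clipped at zero). Expressing the magnitude in noise
z-units means the detector recovers `ẑ ≈ m` up to two attenuation effects:

* **Rounding** at low-count genes (counts must stay non-negative integers);
  negligible once the gene's mean controlled count is ≳ 50.
* **Self-inflation of the row sd**: a planted m-sigma point inflates its own
  row's standard deviation by roughly `sqrt((N−1+m²−1)/N)` in each of the
  two standardization passes. At N = 100 and m = 6 the recovered `ẑ` sits
  near 4.5; at N = 40 it can fall below 4. This is a property of any
  z-score-based detector at modest cohort sizes, not of the injection.

Magnitude 6 is the default floor because the expected extreme |z| of an
i.i.d. standard-normal matrix with about 10⁶ cells is ≈ 5
(`expected_extreme_z()`, computed from the order-statistic integral
`E[max] = ∫₀^∞ (1 − (2Φ(x)−1)ⁿ) dx`): smaller magnitudes are
indistinguishable from the null's own extremes.

Two placement modes exist because both conventions are in circulation: one
outlier per sample (the default — the single-causal-gene scenario) and
independent per-cell injection at a fixed frequency (conventionally 1e-4).
The non-injected residual cells keep the dataset's own noise values, which
preserves realism and makes the empty-plan injection an exact identity on
counts.

## The synthetic-data generator

`simulate_counts()` emulates a bulk RNA-Seq cohort:
`k_ji ~ NB(mean = d_i · μ_j · 2^{C_ji}, size = r_j)` with

* gene base means `μ_j ~ LogNormal(log 200, 1)` — median a few hundred
  counts, spanning roughly 10–10⁴, the typical spread of an expressed-gene
  panel after filtering;
* NB sizes `r_j ~ LogNormal(log 8, 0.8)` — moderate overdispersion,
  variance `μ + μ²/r`;
* depth multipliers `d_i ~ LogNormal(0, 0.3)` — a realistic factor-of-two
  spread in library size;
* confounders `C = A·Bᵀ` with Gaussian loadings of sd 0.7 (k = 3 by
  default), acting multiplicatively via `2^C` so they are *exactly* low-rank
  in the log2 domain the detector standardizes. That makes rank recovery a
  sharp parameter-recovery test: the selected rank equals k in ≥ 90% of
  seeds at J = 2000, N = 100, k ≤ 5.

What the generator does **not** emulate: zero inflation, batch-specific
dispersion, gene–gene correlation beyond the planted low-rank term,
single-cell dropout, and the long left tail of unexpressed genes (use
`filter_zero_genes()` on real data). A green injection→detection test
therefore establishes that the method removes *low-rank* confounding and
recovers *impulse* outliers under log-normal-ish noise — not that it handles
every pathology of real cohorts.

## Multiple testing

Benjamini–Yekutieli (harmonic correction factor `Σ 1/i`) rather than
Benjamini–Hochberg, because expression levels of many genes in a sample are
dependent and BY is valid under arbitrary dependence. The correction is
applied matrix-wide by default (the conservative reading; all J·N tests are
one family); a per-sample scope is available. Degenerate genes report
p = q = 1, keeping all matrices rectangular. P-values are floored at the
smallest positive normal double so `-log10(p)` stays finite for ranking.

## Evaluation conventions

AUC-PR uses the average-precision step rule (mean precision at the ranks
where true cells are hit), not trapezoidal interpolation, which is biased in
PR space; the choice is pinned by an exact confusion-matrix oracle in the
tests. Ranking is matrix-wide ascending P-value with ties broken by
descending |ẑ|; truth ranks use minimum tie rank. Bootstrap bands resample
the truth and non-truth strata with replacement and report 2.5/97.5
percentile precision on a fixed recall grid.

## Known limitations

* Size factors require at least one gene with positive counts everywhere.
* Rank selection assumes approximately Gaussian residual noise; heavy
  discreteness (very low counts) bends the log-normal approximation.
* At small N the z-score self-inflation above caps the recoverable
  magnitude of any single-cell aberration.
* The injection reuses the dataset's own residual; it does not simulate
  fresh noise unless the planted cells are the only ones you modify.
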