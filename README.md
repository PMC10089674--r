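# outsvd

Aberrant-expression outlier detection — and benchmark outlier *injection* —
for RNA-Seq gene × sample count matrices, using SVD with the optimal hard
threshold for singular values.

## The problem

In rare-disease diagnostics, a pathogenic event often shows up as a single
aberrant count: one gene, in one patient, far outside that gene's
distribution across the cohort. Finding such cells is hard because unobserved
confounders (batch, sex, ancestry, technical covariates) induce coherent
structure across samples that both mimics and masks true outliers. `outsvd`
separates the two with a deterministic, almost instantaneous linear-algebra
pipeline — no autoencoder training, no negative-binomial dispersion fitting.

## The model

For a J × N count matrix `k_ji` (J genes ≫ N samples):

1. **Depth control** — median-of-ratios size factors
   `s_i = median_j k_ji / (∏_t k_jt)^(1/N)`, controlled counts
   `c_ji = k_ji / s_i`.
2. **Log-normal z-scores** — `l_ji = log2((c_ji + 1)/(c̄_j + 1))`, then
   gene-wise standardization `z̃_ji = (l_ji − μ_j)/τ_j`.
3. **Confounder removal** — SVD `Z̃ = Ũ Σ̃ Ṽᵀ`; singular values above the
   optimal hard threshold `ω(β)·σ_median` (with `ω(β) = λ(β)/√μ_β`, `μ_β`
   the Marčenko–Pastur median at aspect ratio `β = N/J`) define the low-rank
   signal `Z` (the confounders); the residual `E = Z̃ − Z` keeps the noise
   *and any outliers*, which are too sparse and impulse-like to be signal.
4. **Scoring** — gene-wise z-scores `ẑ` of `E`, two-sided normal P-values
   `p̂ = 2·min{Φ(ẑ), 1−Φ(ẑ)}`, Benjamini–Yekutieli FDR correction.

Every step is invertible, so the pipeline run backwards plants artificial
outliers of chosen z-magnitude into the noise component and returns *integer
counts* whose planted outliers are masked by the dataset's own confounders —
a realistic benchmark that simple count-perturbation schemes cannot produce.
Magnitudes start at 6 because the expected extreme |z| of a null matrix with
~10⁶ cells is ≈ 5 (`expected_extreme_z()`).

## Worked example

```r
library(outsvd)

sim    <- simulate_counts(n_genes = 2000, n_samples = 100, n_confounders = 3, seed = 1)
spec   <- plan_outliers(sim$counts, scheme = "both", magnitude = 6, seed = 2)
inj    <- inject_outliers(sim$counts, spec)        # one masked outlier per sample
report <- detect_outliers(inj$counts, fdr_level = 0.05)
report
#> Aberrant expression report: 2000 genes x 100 samples
#>   confounder rank removed: 3 (threshold 43.889)
#>   calls at FDR < 0.05: 85
report$oht
#> Optimal hard threshold: rank 3
#>   beta = 0.0500, MP median = 0.9833, omega = 1.5193
#>   median singular value = 28.8872, threshold = 43.8894
pr_curve(report$pvalues, inj$truth, report$zhat)
#> Precision-recall curve over 200000 cells: AUC-PR (average precision) = 0.9430
```

The detector recovers exactly the 3 planted confounder dimensions, and the
100 injected outliers dominate the smallest P-values (AUC-PR 0.94; the
ablated pipeline that skips the SVD split drops far below — the confounders
mask the outliers until they are removed). Median rank of a true outlier
among all 200 000 cells here: 52.5.

## Command line

```sh
Rscript inst/scripts/outsvd simulate --genes 2000 --samples 100 --confounders 3 --seed 1 --out sim/
Rscript inst/scripts/outsvd inject sim/counts.tsv --magnitude 6 --scheme both --out inj/
Rscript inst/scripts/outsvd detect inj/counts.tsv --fdr 0.05 --out det/
Rscript inst/scripts/outsvd evaluate det/pvalues.tsv inj/truth.tsv --out eval/
```

All commands are deterministic given `--seed` and write a `run_log.txt`
beside their outputs.

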