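# frocdwi

Quantitative diffusion-weighted MRI (DWI) analysis of breast lesions
with the fractional-order-calculus (FROC) signal model alongside the
conventional mono-exponential ADC, for imaging scientists who want the
whole biomarker chain — voxel-wise model fitting, whole-lesion
segmentation, first-order histogram radiomics, and cohort statistics —
in one reproducible, fully synthetic-testable package.

## The models

The mono-exponential model describes the DWI signal as
`S(b) = S0·exp(−b·ADC)`. The FROC model generalises it to non-Gaussian
diffusion:

    S(b) = S0 · exp[ −D · μ^(2(β−1)) · (γ·G_d·δ)^(2β) · (Δ − (2β−1)/(2β+1)·δ) ]

with diffusion coefficient `D` (mm²/s), spatial fractional order
`β ∈ (0, 1]` (1 = Gaussian; lower values = more intravoxel
heterogeneity) and spatial constant `μ` (a length scale). Gradient
amplitude `G_d` follows from each b-value via the Stejskal–Tanner
relation `b = (γ·G_d·δ)²·(Δ − δ/3)`; the default protocol uses eight
b-values 0–2000 s/mm² with δ = 19.3 ms and Δ = 40.0 ms. ADC is fitted
over b ≤ 800 s/mm², FROC over the full range.

At a single diffusion time the FROC signal is exactly a stretched
exponential `S0·exp(−A·b^β)`; only `(S0, A, β)` are identifiable, so
the fitter works in two stages — a bounded multi-start
Levenberg–Marquardt fit of `(S0, A, β)`, then `D` from the low-b
Gaussian regime and `μ` in closed form from `A` — the convention this
model family uses in practice. See the methods vignette
(`vignettes/frocdwi-methods.Rmd`) for the full account.

Downstream, a 2D seed ROI on the b = 800 volume is grown into the
whole-lesion 3D ROI by fuzzy C-means, seven first-order histogram
metrics (10th/90th percentiles, mean, median, entropy, kurtosis,
skewness) summarise each parameter map over the lesion, and a
statistics layer provides Mann–Whitney (exact by enumeration for small
samples), Kruskal–Wallis with Bonferroni pairwise correction, Spearman
correlation, ICC(2,1), ROC with Youden cutoffs and DeLong
comparisons, and in-sample multivariable logistic combinations.

## Worked example

A phantom with known ground truth, end to end (this is
`analysis/02_fit_phantom.R`; the numbers below are its actual output):

```r
library(frocdwi)
out <- run_phantom_pipeline(phantom_spec(seed = 60920))
out$dice
#> [1] 1
subset(out$features, metric == "median")
```

```
Whole-lesion histogram features (reporting scale):
 model parameter    p10    p90   mean median entropy kurtosis skewness
  mono       adc  829.9 1109.4  959.6  946.5   6.070    2.592   0.3405
  froc         D  829.9 1109.4  959.6  946.5   6.070    2.592   0.3405
  froc      beta  735.1  812.1  773.8  775.1   5.917    3.599  -0.5040
  froc        mu 7674.0 7990.1 7828.3 7821.8   5.964    2.805   0.2861
```

Reading this: the lesion was segmented perfectly (Dice 1.0 against the
generating ellipsoid); ADC and D print in 10⁻⁶ mm²/s, β in 10⁻³ and μ
in 10⁻³ µm, the scales clinical tables use. The fitted lesion β-median
(775 ≈ 0.775) matches the generator's field median exactly; D equals
the ADC here because the phantom's default fit reports D through the
low-b convention described above.

On the cohort side (`analysis/03_cohort_statistics.R`,
`analysis/04_diagnostic_performance.R`), a synthetic 159-lesion cohort
drawn from the published group distributions gives, averaged over 200
replicates:

```
      metric mean_auc  sd_auc
  adc_median   0.9782 0.01364
      D_mean   0.9788 0.01256
 beta_median   0.9007 0.02907
   mu_median   0.9298 0.02216
```

i.e. ADC-median and D-mean are near-equivalent discriminators of benign
vs malignant lesions (DeLong p ≈ 0.87 on a single cohort), with the
β and μ medians close behind — the pattern the underlying clinical
tables report.

## The analysis workflow

Numbered drivers under `analysis/` run the full study and write their
tables under `results/`:

1. `01_simulate.R` — phantom (with ground-truth maps and SNR check) and
   cohort CSV;
2. `02_fit_phantom.R` — segmentation, both model fits, histogram
   features;
3. `03_cohort_statistics.R` — ICCs, benign/malignant comparison + ROC
   per metric, prognostic-label and subtype comparisons, Spearman
   matrix;
4. `04_diagnostic_performance.R` — replicate-averaged AUCs, DeLong
   comparisons, combined multivariable models.

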