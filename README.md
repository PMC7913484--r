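# honeynir

Chemometric workflow for predicting physicochemical properties of honey from
portable near-infrared (NIR) spectra and for authenticating its botanical
origin. It is aimed at food-authentication and spectroscopy researchers who
want a scriptable, tested equivalent of the classic WinISI/STATGRAPHICS
pipeline: scatter-corrected and derivatized log(1/R) spectra, modified
partial least squares (MPLS) calibration with outlier elimination and
grouped cross-validation, and linear discriminant analysis (LDA) of honey
type from physicochemical plus melissopalynological (pollen) variables.

Because raw spectra of this kind are rarely deposited, the package ships a
seeded synthetic generator that emulates the statistical structure of a
100-sample honey survey (six botanical types, 84/16 calibration/validation
split, reference constituents with realistic means and ranges, Dirichlet
pollen profiles, scatter-distorted spectra averaged over triplicate scans),
so the entire pipeline is testable end to end.

## The methods in brief

* **Preprocessing.** Working representation is absorbance `log10(1/R)`.
  Scatter corrections: SNV (per-spectrum standardization), MSC (per-spectrum
  affine regression on a reference spectrum), detrend (degree-2 polynomial
  baseline removal) and SNV-DT. Derivatives use the 4-digit gap-segment code
  `d,g,s1,s2` (derivative order, gap in channels, first and second boxcar
  smooth), e.g. `"None 1,4,4,1"` or `"SNV-DT 2,8,6,1"`.
* **Spectral outliers.** Mahalanobis H-statistic in PCA score space,
  `H = D²/k`; samples with `H > 3` do not belong to the calibration
  population and are removed.
* **Calibration.** MPLS = PLS1 (NIPALS) with X and y residuals re-scaled to
  unit SD after each factor. Factor count chosen by minimum SECV in 8-group
  cross-validation; chemical outliers removed by `T = |e|/SEC ≥ 2.5` (two
  passes). Descriptors: `SEC = √(SSE/(N−k−1))`, `RSQ = 1 − SSE/SST`,
  `SECV = √(SSE_cv/N)`, `RPD = SD/SEC`. External validation reports mean
  residual, RMSE, SEP, bias-corrected SEP(C) and the paired Student t.
* **Discrimination.** Canonical LDA via the generalized eigenproblem of
  between- vs pooled within-group scatter; per-function eigenvalue, relative
  %, canonical correlation `√(λ/(1+λ))`, Wilks' `Λ_k = Π_{i≥k} 1/(1+λ_i)`,
  Bartlett `χ² = −(N−1−(p+g)/2)·lnΛ` on `(p−k+1)(g−k)` df; nearest-centroid
  classification with priors.
* **Pollen typing.** Frequency classes (predominant > 45 %, secondary
  15–45 %, important minor 3–15 %, minor < 3 %) and rule-based honey-type
  assignment with documented thresholds.

## Worked example

```r
library(honeynir)
ds <- generate_dataset(synthetic_config(seed = 1))

cal <- run_calibration_study(ds$spectra, ds$reference, ds$split,
  parameters = c("moisture", "pfund", "phenols"),
  treatments = c("None 0,0,1,1", "SNV 1,4,4,1", "Detrend only 1,4,4,1"),
  seed = 1)
print(cal)
#>  Variable Math Treatment  N   Mean    SD Est.Min Est.Max  SEC  RSQ SECV   RPD
#>  moisture   None 0,0,1,1 84  17.97  0.61   16.14   19.81 0.36 0.67 0.42  1.69
#>     pfund   None 0,0,1,1 82 101.82 27.67   18.81  184.84 1.78 1.00 2.38 15.58
#>   phenols   None 0,0,1,1 82 126.15 40.69    4.09  248.20 1.83 1.00 2.65 22.20
```

Each row is a calibration equation: `N` retained samples after H/T
screening, the reference mean/SD, the estimated range (mean ± 3 SD, floored
at 0), and the fit (SEC, RSQ), cross-validation (SECV) and
capacity (RPD ≥ 2 good, 1.5–2 acceptable) descriptors. Moisture is
deliberately the hard case — its signal rides on the dominant water band and
is partially confounded with multiplicative scatter — while color (Pfund) and
phenols, whose bands are well resolved, are recovered almost perfectly.
External validation on the 16 held-out samples:

```r
cal$validation_table
#>  Variable Mean Residual RMSE    p
#>  moisture          0.23 0.31 0.54
#>     pfund          2.40 3.00 0.82
#>   phenols          2.04 2.42 0.68
```

All paired-t p-values exceed 0.05: the NIR predictions are statistically
comparable to the reference assays. The discriminant study on all 100
samples (11 physicochemical variables + 4 main pollen percentages, 6 honey
types, 5 discriminant functions):

```r
lda <- run_discriminant_study(ds$reference, ds$pollen, ds$labels)
lda$diagnostics[1, c("eigenvalue", "canonical_correlation", "chi_square", "df")]
#>   eigenvalue canonical_correlation chi_square df
#> 1     185.87                     1    1448.13 75
lda$confusion$overall_correct_pct
#> [1] 100
```

The synthetic world separates the six types more cleanly than real honeys
do (100 % resubstitution here), because its between-type offsets are free of
the chestnut/honeydew overlap that limits real surveys to ~88 %.

A command-line interface wraps the same steps:

```sh
Rscript -e 'honeynir::honeynir_cli()' simulate --out data --seed 1
Rscript -e 'honeynir::honeynir_cli()' calibrate --data data --out reports
Rscript -e 'honeynir::honeynir_cli()' lda --data data --out reports
```

## Package layout

`R/spectra.R` container + CSV I/O · `R/preprocess.R` treatments ·
`R/pca.R` PCA + H screening · `R/mpls.R` MPLS · `R/calibration.R`
CV/T-elimination/statistics/model selection · `R/lda.R` discriminant
analysis · `R/pollen.R` typing rules · `R/synthetic.R` generator ·
`R/workflow.R` studies + CLI. Methods details: `vignettes/honeynir-methods.Rmd`.
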