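---
title: "Models and methods behind honeynir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind honeynir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(honeynir)
```

honeynir implements the two headline analyses of portable-NIR honey
authentication — quantitative calibration of physicochemical parameters from
diffuse-reflectance spectra, and discriminant classification of botanical
type from physicochemical plus pollen variables — together with a synthetic
data generator that makes the whole pipeline testable without access to a
proprietary spectral library. This vignette explains the models, the
defaults and the numerical choices, and is explicit about what the
synthetic world does and does not establish.

## 1. Spectral representation and preprocessing

Spectra are diffuse reflectance R measured over roughly 900–1700 nm by a
linear-variable-filter instrument; the working representation is the
absorbance-like `log10(1/R)` (a white reference with R = 1 maps to 0).
The default synthetic axis is 125 evenly spaced channels over 908–1676 nm —
a 128-pixel detector loses a few edge pixels, and every algorithm here is
grid-agnostic, so the axis is configurable.

Particulate scatter in diffuse reflectance produces per-sample additive
offsets, multiplicative gain and smooth baseline curvature. The package
implements the four standard corrections as composable row-wise transforms:

* **SNV** — each spectrum is centered and scaled to unit SD (n−1
  denominator). Removes per-row affine distortion exactly:
  `snv(a + b·x) = snv(x)` for `b > 0`.
* **MSC** — each spectrum is regressed (OLS) on a reference spectrum,
  `x = a + b·ref + e`, and replaced by `(x − a)/b`. The reference defaults
  to the set mean; a calibration stores its reference so new samples are
  corrected identically.
* **Detrend** — residual from a degree-2 polynomial fit on the wavelength
  axis (the standard Barnes detrend; order configurable). **SNV-DT** is SNV
  followed by detrend.

Derivatives use the 4-digit nomenclature `d,g,s1,s2`: derivative order, gap
in channels, first and second smoothing segment. The digits are named in
the chemometric literature but the arithmetic is not; honeynir fixes it as

1. centered boxcar smooth of width `s1` (width 1 = none),
2. `d` successive gap differences, each output the difference of the two
   values `g` channels apart (a linear ramp `x_i = k·i` gives the constant
   `k·g` under `1,g,1,1`),
3. centered boxcar smooth of width `s2`.

Whether the first smoothing precedes or follows differencing differs
between legacy implementations; smooth→difference→smooth is this package's
documented choice, and the operator is linear, so the composition order
only redistributes (not creates) information. Channels without full
support are **truncated**, and the wavelength axis shrinks with them —
padding would fabricate boundary values that later feed the Mahalanobis
screen. Treatment strings follow the reporting dialect exactly:
`"None 1,4,4,1"`, `"Detrend only 1,4,4,1"`, `"SNV-DT 2,8,6,1"`.

## 2. Spectral outlier screening (H statistic)

A PCA (SVD on column-centered spectra) retains enough components to
explain 99.5 % of spectral variance (capped at 10). In score space the
squared Mahalanobis distance reduces to `D²_i = Σ_k t²_ik / var_k`, and the
H statistic is `H_i = D²_i / k`. Its mean over the calibration set is
exactly `(n−1)/n`, which the tests assert; spectra with `H > 3` (default)
are treated as not belonging to the population and are excluded before any
equation is developed. Raising the threshold can only shrink the flagged
set (monotonicity is a tested property).

## 3. MPLS calibration

Calibration is PLS1 by NIPALS with the Shenk–Westerhaus "modified"
step: after each factor is extracted and deflated, the X-residual columns
and the y residual are divided by their standard deviations, so subsequent
factors weight all remaining wavelengths evenly rather than chasing the
largest residual variance. All scalings are recorded and folded into a
single coefficient vector, so prediction is an exact linear map and the
training fit is reproduced to 1e−10 (a tested invariant). With the
modification disabled the fit equals textbook PLS1; the suite verifies this
against an independent Krylov-subspace oracle to 1e−8.

**Cross-validation.** Samples are partitioned into 8 random groups
(the reported methods value; the results narrative of the source workflow
mentions six in one place — both are exposed via `n_groups`, eight is the
default). Every sample is predicted exactly once per factor count and
`SECV(a) = √(Σe²_cv/N)`. The factor count is the smallest within 2 % of
the minimum SECV (`parsimonious = TRUE`; the plain argmin is available) —
published models report 5–9 factors without stating their rule, and the
parsimony window is the conventional guard against overfitting. The
ceiling is 16 factors.

**Chemical outliers.** After the factor count is fixed, samples with
`T = |e|/SEC ≥ 2.5` are removed and the model refitted, up to two passes.
H screening runs before the first fit and T elimination after — the two
criteria are stated independently in the source methodology and this
interleaving is the package's documented choice.

**Descriptors.** On the N retained samples:
`SEC = √(SSE/(N−k−1))` (degrees-of-freedom corrected),
`RSQ = 1 − SSE/SST`, `SECV = √(SSE_cv/N)`, and `RPD = SD/SEC`. The
literature defines RPD variously as SD/SECV or SD/RMSEC; the printed
descriptor tables this package mirrors are only consistent with SD/SEC
(e.g. 31.6/11.3 = 2.8), so that is the default and `rpd_denominator =
"SECV"` is the flagged alternative. The estimated range is mean ± 3 SD of
the retained reference values, floored at 0 for non-negative parameters
(the floor is visible in published tables as "0.0" minima). RSQ here is
1−SSE/SST on a least-squares fit with intercept, which coincides with the
squared multiple correlation.

**External validation.** On held-out pairs: mean absolute residual, RMSE,
bias, `SEP = √(Σe²/(n−1))`, bias-corrected
`SEP(C) = √(Σ(e−bias)²/(n−1))`, and the two-sided paired Student t. The
model is "comparable" to the reference assay when p > 0.05; note that for
a genuinely unbiased model this p-value is uniform on (0,1), so ~5 % of
random validation sets will fail the comparability flag by construction.

**Model selection.** Every treatment in the grid (default: the five
scatter corrections × derivative codes 0,0,1,1 / 1,4,4,1 / 2,4,4,1 /
2,8,6,1 / 2,10,10,1) runs the full pipeline; the winner has the highest
RSQ (ties at 4 dp broken by lower SECV, then fewer factors).

## 4. Linear discriminant analysis

With pooled within-group SSCP W and between-group SSCP B, the canonical
axes solve `B a = λ W a`, computed via the Cholesky reduction
`W = R'R`, eigen of the symmetric `R'^{-1} B R^{-1}`. Axes are scaled so
canonical scores have unit pooled within-group variance; the between-group
scatter of scores is then diagonal with entries λ_k (both tested). There
are `m = min(g−1, p)` functions. Per-function diagnostics:

* relative percentage `λ_k/Σλ × 100`;
* canonical correlation `√(λ_k/(1+λ_k))`;
* Wilks' `Λ_k = Π_{i≥k} 1/(1+λ_i)` (the recurrence
  `Λ_k = Λ_{k+1}/(1+λ_k)` is asserted to 1e−12);
* Bartlett's `χ² = −(N−1−(p+g)/2)·ln Λ_k` on `(p−k+1)(g−k)` df. This
  multiplier reproduces the published χ² values (432.3, 296.4) from the
  published eigenvalues with N = 100, p = 15, g = 6 — which also confirms
  p = 15: eleven physicochemical variables (color contributing Pfund plus
  L, a*, b*) and the four main pollen percentages.

Classification assigns each observation to the nearest group centroid in
canonical space, penalized by `−2·ln(prior)`; priors default to group
proportions (`"equal"` available — the source analysis does not state its
choice). The confusion matrix is reported as resubstitution, with
leave-one-out available via `loo = TRUE`; published tables of this kind are
typically resubstitution. When the within-scatter is singular
(exact collinearity) the fit aborts naming the dependent variables, or
applies a logged ridge `ε·trace(W)/p` when `ridge > 0`.

A documented inconsistency in the reference material: the chestnut row of
the published confusion table prints 83.4 % although its counts give
19/22 = 86.4 %, and the overall rate prints 88.1 % although the trace gives
88/100 = 88.0 %. honeynir always recomputes rates from counts; the
acceptance report shows the recomputed values.

## 5. Pollen typing

Frequency classes follow the melissopalynological convention: predominant
(> 45 %), secondary (15–45 %), important minor (3–15 %), minor (< 3 %),
closed on the lower side. Honey-type rules are threshold-based and run in
precedence order, under-represented taxa first: heather (*Erica* ≥ 35 %,
because *Erica* pollen is under-represented in heather honey), eucalyptus
(*Eucalyptus* ≥ 70 %) and chestnut (*Castanea* ≥ 70 %) (over-represented
taxa), blackberry (*Rubus* ≥ 45 %). Honeydew honey has no pollen signature
of its own; the stand-in rule — predominant *Castanea* below the chestnut
cutoff together with electrical conductivity ≥ 0.8 mS/cm — is a documented
approximation, not a regulatory criterion. Unmatched profiles are
multifloral. Raising any threshold can only shrink that unifloral class
(tested monotonicity), and every sample receives exactly one label with a
rule trace.

## 6. The synthetic world

The generator emulates a 100-sample survey: per-type counts 5 heather /
22 chestnut / 9 eucalyptus / 10 blackberry / 18 honeydew / 36 multifloral,
split 84/16 into calibration/validation, stratified by type.

* **Constituents.** Eleven parameters (moisture %, EC µS/cm, pH, HMF
  mg/100 g, diastase index, Pfund mm, CIELab L/a*/b*, phenols and
  flavonoids mg/100 g) are truncated-normal draws (clip-and-resample)
  whose global means, SDs and ranges equal the published calibration-set
  reference statistics. Within-type SD is 0.6× the global SD and per-type
  mean offsets (in SD units) encode the known chemistry — darker honeys
  (heather, chestnut, honeydew) higher in EC, Pfund, phenolics and lower in
  luminance; eucalyptus and blackberry the reverse; moisture type-neutral.
  The published reference table pools all types, so the offsets are
  plausible, not reproduced; they are configuration, not code.
* **Spectra.** Each constituent owns one or two Gaussian absorption bands
  (moisture the 1450/1190 nm water bands; the others single bands spread
  over the axis), with amplitudes sized so one SD of a constituent moves
  the spectrum by ~0.05 AU at its band center. A sample's clean spectrum is
  the linear mixture `Σ_j c_ij K_j(λ)`; each of 3 replicate scans distorts
  it with a multiplicative factor (SD 0.05), an additive offset (SD 0.02),
  a quadratic baseline (SD 0.01) and channel noise (SD 0.005 AU), and the
  stored spectrum is the replicate mean. These are exactly the distortions
  SNV/MSC/detrend are designed to remove, which makes preprocessing
  benefits demonstrable (a tested property under inflated scatter).
* **Pollen.** Per-type Dirichlet draws over ten taxa with mean percentages
  matching the published per-type compositions (e.g. eucalyptus honeys
  center on 72.8 % *Eucalyptus*) and precision 300 (per-draw SD of the main
  taxon ≈ 2.5 points — tight enough to be realistic, loose enough that
  heather's 35.5 % *Erica* mean straddles its 35 % typing threshold, as
  real heather honeys do).
* **Determinism.** One config seed drives everything; identical configs
  are byte-identical (tested on the serialized object).

**What a green test establishes — and what it does not.** The synthetic
world validates the *machinery*: that the pipeline recovers constituents
whose signal is present and resolvable, that screening removes constructed
outliers, that the descriptor arithmetic is right. It does not reproduce
real honey chemistry: bands are invented, constituent correlations beyond
the type structure are absent, and the six types separate more cleanly than
real surveys (LDA resubstitution here is ~100 % vs the ~88 % typical of
real chestnut/honeydew overlap). Two emergent behaviors are worth knowing:
moisture is intrinsically hard (its signal dominates the mean spectrum, so
multiplicative scatter is partially confounded with it — synthetic RSQ
~0.7–0.8, much like real surveys), while well-resolved minor constituents
(phenols, flavonoids, Pfund) calibrate almost perfectly. The acceptance
criterion for full-pipeline recovery therefore uses phenols as its spiked
constituent.

## 7. Numerical choices and degenerate inputs

* SD everywhere uses the n−1 denominator; SECV uses N (both conventional,
  and jointly consistent with SEC < SECV in published tables).
* SNV refuses constant spectra; MSC refuses a zero-variance reference;
  log(1/R) refuses R ≤ 0, naming the sample and wavelength.
* PLS factor extraction stops early (with fewer factors) if the covariance
  `X'y` vanishes; residual-scaling divisors below 1e−12 are set to 1 to
  avoid amplifying numerically-zero residuals.
* Cross-validation folds that cannot support the requested factor count
  reuse their deepest available factor.
* Eigenvalues are clipped at 0; LDA tie-breaks are deterministic by group
  order.
* `calibration_stats` refuses N ≤ k+1; a perfect fit reports RSQ 1, SEC 0
  and RPD +Inf.

## 8. Known limitations

No wavelength interpolation between instruments, no EMSC/OSC, no nonlinear
calibration, no neighborhood-distance library matching, no stepwise
variable selection, and no claim that the pollen-typing thresholds equal
any regulatory (PGI) criteria. The HMF descriptor row of the published
table (SEC printed as 0.0 with finite RPD) is only consistent with
unrounded internals and is not reproduced numerically.
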