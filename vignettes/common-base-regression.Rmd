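---
title: "Regression and ANCOVA for qPCR relative expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression and ANCOVA for qPCR relative expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrcb)
```

## The model

Quantitative PCR estimates starting template abundance through the
quantification cycle Cq: the cycle at which amplicon fluorescence
crosses a threshold. Amplicon growth is exponential with a per-cycle
amplification factor E (the efficiency; 2 is perfect doubling), so two
assays with different efficiencies are not directly comparable on the
cycle scale. The common base method resolves this by weighting each
cycle count into a base-10 log-scale quantity,

$$C_q^{(w)} = \log_{10}(E)\,C_q,$$

normalizing each target gene against the arithmetic mean of the weighted
values of one or more reference genes measured in the same sample,

$$\Delta C_q^{(w)} = C_{q,\mathrm{GOI}}^{(w)} -
  \tfrac1n \sum_i C_{q,\mathrm{REF}_i}^{(w)},$$

and only at the very end converting differences of such values
(\(\Delta\Delta C_q^{(w)}\)) to relative expression ratios
\(R = 10^{-\Delta\Delta C_q^{(w)}}\). Staying on the log scale as long
as possible is what makes parametric linear models legitimate: each
per-sample \(\Delta C_q^{(w)}\) is an independent observation, with no
pairing required. The arithmetic mean over reference genes is correct
(not the geometric mean) precisely because the values are already logs.
Higher \(\Delta C_q^{(w)}\) means *lower* expression, so expression-ratio
plots are inverted images of \(\Delta C_q^{(w)}\) plots — a recurring
source of misreading that the package's plot labels try to prevent.

The base of the logarithm is fixed at 10 everywhere and not exposed as
an option. Any consistent base would work mathematically, but a mixed
choice silently corrupts every ratio downstream, and 10 keeps weighted
values interpretable as log-decades.

### Regression cases and CI propagation

`fit_ols()` fits \(y = mx + b\) by ordinary least squares
(delegating to `lm()`), assuming linearity, homoscedasticity,
independence and normality. The key observation driving all five
transformed outputs is that a predicted
\(\widehat{\Delta\Delta C_q^{(w)}} = m(x - x_0)\) contains exactly one
random quantity: the slope. Its \(t\)-based confidence interval
\((L, U)\) — computed with the unbiased residual variance on \(n-2\)
degrees of freedom — therefore propagates through every
back-transformation by substitution:

* **Exponential** (`ratio_curve()`): \(\hat R = 10^{m(x_0-x)}\), band
  \(\{10^{L(x_0-x)}, 10^{U(x_0-x)}\}\) ordered per point.
* **Logarithmic** (`response_curve()`):
  \(\hat y = \hat y_0 - m\log_{10} R\) with \(\hat y_0 = m x_0 + b\);
  the bound order swaps with the sign of \(\log_{10} R\).
* **Power, gene on gene** (`gene_ratio_curve()`):
  \(\hat R_B = R_A^m\), band \(\{R_A^L, R_A^U\}\).
* **Power, log-transformed covariate** (`ratio_curve()` on a
  `log_x = TRUE` fit): \(\hat R = (x_0/x)^m\).
* **Power, log-transformed response** (`response_curve()` on a
  `log_y = TRUE` fit): \(\hat y = \hat y_0 R^{-m}\) with
  \(\hat y_0 = 10^{m x_0 + b}\).

Intercept and prediction variance are deliberately *not* added: the
intervals quantify uncertainty in the expression *contrast* against the
baseline, not in an absolute prediction. A consequence worth knowing is
that every band collapses to zero width at the baseline — \(R(x_0)=1\)
is exact by construction, not an estimate.

Log transforms for the two power cases are applied internally to the
raw data at full precision. Recomputing from rounded printed log columns
visibly shifts the slope (third decimal), which is why the package never
accepts pre-logged data for these modes.

### Baseline choice

The baseline \(x_0\) (`choose_baseline()`) defaults to the mean of the
observed covariate: slope uncertainty scales with \(|x - x_0|\), so the
mean minimizes and symmetrizes band widths. `min`, `max` and `custom`
policies are available for designs where an extreme or an unmanipulated
natural level is the scientifically meaningful comparison point; a
custom baseline outside the observed range is refused, for the same
reason extrapolated predictions are. For a log-covariate fit the
baseline statistics are taken on the **raw** scale (the mean cell
density, not the mean log density), which is the comparison a reader of
the raw units expects.

### Non-significant slopes

If the slope test cannot reject \(m = 0\), there is no evidence the
input affects expression, and the honest summary is \(R = 1\)
everywhere. The package flags this (`null_slope` attribute, a note in
written reports) but by default still returns the fitted curve;
`null_as_unity = TRUE` applies the collapse-to-unity convention. The
default was chosen because silently replacing a fitted curve with a
constant destroys information the analyst may need to see — the flag
plus an explicit switch keeps both behaviours one decision apart.

### Extrapolation

Evaluation outside the observed covariate range is an error by default
and a warning under `allow_extrapolation = TRUE`. The fitted linear
relationship has no empirical support outside the data, and the
exponential transform amplifies extrapolation error multiplicatively.

## ANCOVA

`fit_ancova()` implements the one-way analysis of covariance on
\(\Delta C_q^{(w)}\) with a quantitative covariate:

1. **Separate regressions** per group (`fit_group_slopes()`); if no
   group slope differs from zero the covariate is uninformative and the
   function recommends plain ANOVA.
2. **Homogeneity of slopes** (`test_slope_homogeneity()`): an
   extra-sum-of-squares F test between the separate-slopes model and the
   common-slope model, \(F\) on \((k-1,\; n-2k)\) degrees of freedom for
   \(k\) groups. This generalizes the two-group interaction \(t\) test
   to any \(k\). Noise-free parallel groups make both residual sums of
   squares vanish; the implementation reports \(F = 0, p = 1\) for that
   degenerate case rather than 0/0.
3. **Common-slope refit**: \(\hat y = m x + b_g\), where \(m\) is the
   pooled \(\sum_g S_{xy,g} / \sum_g S_{xx,g}\) (equivalently the
   \(S_{xx}\)-weighted mean of group slopes). Because the lines are
   parallel, \(b_i - b_j\) is the constant vertical gap between two
   group lines at *any* covariate value — a
   \(\widehat{\Delta\Delta C_q^{(w)}}\).
4. **Contrasts** (`expression_contrasts()`):
   \(\hat R = 10^{-(b_i-b_j)}\) with CI \((10^{-U}, 10^{-L})\) from the
   \(t\) interval of the intercept difference (bounds swap under the
   negative exponent). Standard errors come from the model covariance
   matrix, which collapses to \(\sqrt{\mathrm{MSE}(1/n_i + 1/n_j)}\)
   when groups share covariate values.

When the interaction is significant at the homogeneity threshold
(default \(\alpha = 0.05\)), the group difference genuinely varies with
the covariate and a single ratio misrepresents it: the fit refuses with
a classed error carrying the test. `force = TRUE` converts the refusal
into a warning — needed for methodological work on deliberately
heterogeneous data, and deliberately loud.

The covariate is used as supplied, uncentred: contrasts depend only on
intercept *differences* of parallel lines, which centring cannot change.

### Multiplicity

The default pairwise comparison is the unadjusted \(t\) (Fisher-LSD
style); `bonferroni` and `sidak` adjustments are available and widen
both the p-values and the interval levels over the number of requested
pairs. Tukey HSD is intentionally not offered: its studentized-range
quantiles sit outside the slope-CI propagation framework used
everywhere else, and the choice of contrast family is left to the
analyst. A ratio such as \(\hat R = 1.94\) is reported in prose as
"expression at 194% of control" — "94% higher" — wording the package's
outputs keep explicit because the two readings are easily conflated.

## Validation rules and numerical choices

* Efficiency is the amplification *factor* (doubling = 2.0). Values at
  or below 1.2 are rejected with a hint that percentage efficiencies
  must be converted as \(E = 1 + \mathrm{pct}/100\); values above 2.2
  (faster than doubling by a wide margin, almost always an unconverted
  percentage) warn in memory and error in the strict file readers.
* Technical replicates must be collapsed to one row per (sample, gene)
  before normalization; the package does not impose an averaging policy
  on raw replicates.
* All intermediates carry full double precision; rounding (default 3
  decimals, configurable) happens only in the text writers. Written
  outputs contain no timestamps, so identical inputs give byte-identical
  files.
* Exactly collinear input is a legitimate degenerate case
  (\(se_m = 0\), zero-width intervals); the advisory warning `lm` emits
  for it is muffled.
* `fit_ols()` requires \(n \ge 3\) points and at least two distinct
  covariate values; ANCOVA requires \(\ge 2\) groups with \(\ge 3\)
  points and \(\ge 2\) distinct covariate values each.

## The synthetic-data generator

`simulate_dataset()` generates data from known ground truth: an evenly
spaced covariate grid, \(y = mx + b + \varepsilon\) with Gaussian noise
on the model (possibly log) scale, back-transformed where the mode
requires it, and parallel group lines with specified intercept offsets
for the ANCOVA mode. Randomness is R's default Mersenne-Twister stream,
isolated per call when a seed is given, so a specification is fully
reproducible across platforms.

The generator emulates the structure the model assumes — linearity,
homoscedastic Gaussian noise, independent observations, exactly
parallel group lines. It does **not** emulate plate effects, technical
replicate structure, efficiency mis-estimation, non-linearity, or
heavy-tailed noise. Passing coverage tests on generated data therefore
demonstrates internal consistency of the estimator and its intervals
under the stated assumptions, not robustness of those assumptions on
real instrument data.

Test problem sizes were chosen to mirror the worked datasets: n = 10
points per regression (8 for the two log-transform cases), 8 points per
group for ANCOVA, and 2000 seeded replicates for the empirical CI
coverage batteries (slope and contrast coverage, each checked against
the nominal 95% within ±2 points). Smaller replicate counts are used in
the per-module property tests, with the full batteries run once in the
end-to-end suite.

## Known limitations

* Efficiencies are taken as given; estimating E from raw fluorescence
  curves is outside scope.
* Single covariate, one-way designs only: no multi-way ANCOVA, multiple
  covariates, or random effects (no multi-plate batch modelling — with
  plate-confounded designs the unexplained variance simply inflates and
  intervals widen).
* Doubly-exponential / doubly-logarithmic forms (log-transforming
  \(\Delta C_q^{(w)}\) itself) are not implemented; since
  \(\Delta\Delta C_q^{(w)}\) is already a log-scale quantity of \(R\),
  such forms amount to double log transforms and are rarely needed.
* Regression diagnostics are limited to reporting \(r^2\) and the slope
  test; checking the model assumptions (residual plots, normality) is
  the analyst's task, on the `lm` object kept inside every fit.
* Where covariate values are observed rather than manipulated, fitted
  relationships are predictive, not causal.
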