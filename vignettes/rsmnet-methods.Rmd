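---
title: "Response-surface and neural-network modelling with rsmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface and neural-network modelling with rsmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rsmnet` implements the complete statistical workflow behind a classical
bioprocess-optimisation study: a central composite design (CCD) in coded
factors, a second-order polynomial fitted by ordinary least squares with
the full adequacy report, desirability-based optimisation over the
design region, and a single-hidden-layer tanh neural network trained on
the same runs so that the two model families can be compared run for
run. The bundled dataset is a 30-run optimisation of gold-nanoparticle
(AuNP) biosynthesis from a cell-free *Streptomyces* supernatant — four
factors (temperature, incubation time, HAuCl~4~ concentration, initial
pH), response in µg AuNPs/mL — and every statistic in the package's
documentation is computed from those 30 rows by the code itself.

## The design and the coding

A CCD for $k$ factors consists of the $2^k$ factorial corners at coded
levels $\pm 1$, $2k$ axial points at $\pm\alpha$ on one axis at a time,
and $n_c$ replicated centre runs. Factors enter all models on the coded
scale

$$x_i = \frac{\xi_i - \xi_i^{(0)}}{\Delta_i},$$

where $\xi_i^{(0)}$ is the centre and $\Delta_i$ the step of factor
$i$; `factor_spec()` stores both so that `code_value()` /
`decode_value()` are exact inverses. `make_ccd()` defaults to the
rotatable $\alpha = (2^k)^{1/4}$, which equals 2 for $k = 4$ — the five
coded levels $-2,\dots,+2$ of the bundled study. Designs are emitted in
standard order; the original randomised run order of the bundled
experiment is preserved in its `run` column but is never regenerated,
since randomisation belongs at the bench.

The centre replicates are not decoration: they are the only source of
*pure error*, the model-free estimate of response variance that the
lack-of-fit test needs. Replicate groups are detected by exact equality
of coded settings, not by tolerance — a deliberate choice, because a
CCD's replicates are exact by construction and a tolerance would invite
accidental grouping of near-neighbours in irregular designs.

## The second-order model and its ANOVA

`fit_model()` fits, by OLS on the coded levels,

$$Y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j +
\sum_i \beta_{ii} x_i^2 + \varepsilon,$$

with the `linear` and `2fi` subsets available for the nested
fit-summary comparison. Coefficients are reported in coded units, the
convention of every response-surface ANOVA table; the actual-units
equation is recoverable through the factor specs but plays no role in
fitting or testing.

`anova()` on the fit produces Type-III (partial) sums of squares: the
increase in residual SS when a term is removed from the full model.
For the orthogonal linear and interaction columns of a full CCD this
reduces to $\beta^2 \sum x^2$ (a tested invariant); for the pure
quadratic terms, which are not orthogonal to the intercept or to each
other, the partial SS is what the standard design-of-experiments
reports print — sequential SS is intentionally not offered. Term and
model F statistics are tested against the residual mean square; lack of
fit against pure error. On the bundled data this reproduces the
published table: model F = 92.17, lack-of-fit F = 4.08 (p = 0.067,
non-significant, so the quadratic is adequate), pure-error SS ≈ 1147 on
5 df.

One transcription note: the source report prints the intercept as
575.71 in its ANOVA table but 575.17 in the in-text equation, and the
$X_1^2$ coefficient as −1.88 in the table but −1.8 in the equation. The
data decide both: the six centre responses average 575.713 and the OLS
estimate of $X_1^2$ is −1.799, so the package's documentation uses
575.71 and −1.80.

`adequacy()` adds the R² family and the signal-to-noise summary:

* `press` uses the hat-matrix shortcut
  $\mathrm{PRESS} = \sum_i \left(e_i / (1 - h_{ii})\right)^2$, which is
  algebraically identical to brute-force leave-one-out refitting (the
  test suite checks the identity to 1e-6 relative on the bundled data);
* `pred_r2` $= 1 - \mathrm{PRESS}/SS_{\mathrm{tot}}$, which may
  legitimately be negative for a poor model;
* `adeq_precision` $= (\max\hat y - \min\hat y) / \sqrt{p\,MSE/n}$,
  the adequate-precision ratio with $p$ the number of coefficients
  including the intercept.

A leverage numerically equal to 1 makes PRESS undefined for that run;
the package errors and names the run rather than silently dropping it.

## Residual diagnostics and the Box–Cox profile

`residual_diagnostics()` reports raw residuals in the actual-minus-
predicted convention, leverages, and internally/externally studentized
residuals. External studentization uses the leave-one-out error
variance; the suite verifies it against literal delete-one refits.
Normal-probability data use the $(i - 0.375)/(n + 0.25)$ plotting
positions — a conventional choice that affects only plot coordinates,
never a test statistic.

`box_cox()` profiles the power-transform parameter $\lambda$ over a
grid (default $-2$ to $3$ in steps of 0.01, with $\lambda = 0$ handled
as the log transform) using the geometric-mean-scaled transform so that
residual sums of squares are comparable across $\lambda$. One
calibration choice is deliberate: the profile is
$-\tfrac{df}{2}\log(RSS/df)$ with $df = n - p$ the residual degrees of
freedom, rather than the classical ML scale $n$. With $p = 15$
coefficients absorbing half of $n = 30$ observations, the ML profile is
far too sharp: in simulations under the bundled study's conditions
(Gaussian noise at the fitted residual SD, 500 replicates) the
$\chi^2_1$ likelihood-ratio interval on the ML profile covers the true
$\lambda = 1$ only ~84% of the time, while the residual-df profile —
a REML-type small-sample correction — covers ~95%. The location of the
maximum is identical under either scaling, so $\hat\lambda$ is
unaffected. On the bundled data the residual-df profile gives
$\hat\lambda = 1.19$ with 95% CI (0.749, 1.673) — matching, to the
printed precision, the published interval of 0.75–1.67, which the ML
profile does not reproduce. $\lambda = 1$ is comfortably inside,
supporting the published conclusion that no transformation is needed.
The source report's figure-derived point estimate ($\hat\lambda =
0.73$) lies outside its own printed interval and is not reproducible
from the printed data; the package makes no attempt to match it.

## Desirability optimisation

`optimize_desirability()` maximises the Derringer–Suich desirability of
the model prediction over the coded design region, by default the
hypercube $[-2, 2]^4$ — predictions beyond it are extrapolation.
For a maximise goal, $d(y) = \big((y - L)/(T - L)\big)^w$ clamped to
$[0, 1]$, with $L$ and $T$ defaulting to the observed response range
and weight $w = 1$. Ties in desirability (the plateau at $d = 1$) are
broken by higher predicted response, then by lexicographically smallest
coded point; because $d$ is monotone in $y$ for the maximise and
minimise directions, the search there works directly on the prediction,
which is equivalent under those tie-breaks and avoids flat clamped
regions that stall gradient steps. The optimiser is multi-start
L-BFGS-B (32 seeded starts plus the region centre by default);
dimensions pinned by equal bounds are excluded from the search because
a finite-difference gradient is undefined on a zero-width interval.
The suite checks the optimum against exhaustive grid oracles ($21^4$
over the full region; $101^2$ on every factor-pair slice) within one
response unit.

On the bundled fit the in-region maximum (≈1149 µg/mL at a corner of
the coded region) exceeds the source report's printed desirability
optimum (995.77 µg/mL at interior settings); that printed optimum is
not reproducible from the printed model equation either, so it is
documented here but deliberately not used as a reference value.

`surface_grid()` evaluates the fitted polynomial over a regular grid
for any factor pair with the remaining factors held at chosen coded
levels (centre by default) — the data behind the familiar 3D surface
panels, checked cell-by-cell against `predict()`.

## The neural network and the comparison

`train_ann()` fits a single-hidden-layer network,
$\hat y = b_2 + \sum_h w_h \tanh(\mathbf{w}_h^\top \mathbf{x} + b_h)$,
with 20 hidden nodes by default, on inputs standardized to mean 0 / SD
1 over all rows; the response stays in its own units. The reference
tool for this kind of fit trains by penalized least squares and calls
its repeated random initialisations "tours"; a learning rate is not
meaningful for such an optimizer, so the package trains each restart by
BFGS on the squared-error objective with a small L2 penalty on the
weights (default 1e-4), initialising the output layer by ridge
regression on the initial hidden activations. The holdback fraction
(default 0.2, i.e. 24 training and 6 validation rows out of 30) is
drawn once per seed as a uniform random partition — the original
study's actual split is unknown, and its own report is ambiguous
between a 0.2 holdback and a 20/10 split; both are reachable through
`ann_config()`. The best of `restarts` initialisations by validation
error (ties by training error) is kept, which makes the selected
validation error non-increasing in the number of restarts under a
fixed seed stream — a tested invariant, as is bit-for-bit
reproducibility under the seed.

With the default configuration and 200 restarts the network reaches an
overall R² above 0.99 on the 30 runs (the source reports 0.9981),
essentially interpolating the training rows; with so few runs this is
expected behaviour of a 121-parameter model, which is why the
comparison report quotes training and validation subsets separately.
`model_metrics()` supplies the shared vocabulary — SSE, RASE
$=\sqrt{SSE/n}$, AAE $=\sum|e|/n$ (the same statistic labelled MAD
when quoted per training/validation subset), and R² — and
`build_comparison()` assembles the per-run table, the metric blocks and
the verification point: at coded $(0,0,2,0)$ (35 °C, 4 days, 1000
µg/mL HAuCl~4~, pH 6) the quadratic model predicts 845.4 µg/mL against
the measured 866.29 µg/mL.

## Simulating experiments with known truth

`simulate_response()` generates responses from a known 15-term
quadratic surface plus independent homoscedastic Gaussian noise on the
response scale — the Box–Cox result above (λ = 1 inside the CI) is the
within-package justification for simulating additively without a
transform. `aunps_true_model()` packages the bundled study's reported
coefficients with its residual SD (26.47 µg/mL) as the default truth,
so synthetic experiments emulate the real one's signal-to-noise. What
the generator deliberately does not emulate: run-order drift, block
effects, heteroscedasticity, or non-Gaussian error. Tests that pass on
these simulations therefore certify the estimation machinery
(noiseless data recover all 15 coefficients to machine precision; at
the study's noise level the mean fitted substrate coefficient over 500
replicates sits within Monte-Carlo error of the truth), not robustness
to messy real-world data.

The dose-response module follows the same pattern at assay scale:
`simulate_dose_response()` draws percent-viability readings from a
four-parameter logistic on log~10~ concentration over the study's
five-dose series (100 … 0.39 µg/mL), and `fit_ic50()` recovers the
curve by Levenberg–Marquardt, reporting IC50 as the concentration at
the midpoint between the fitted asymptotes. The logistic-on-log-dose
parameterisation is the numerically stable equivalent of the
Boltzmann sigmoid quoted in assay protocols. A flat response raises a
non-identifiability error instead of returning an arbitrary IC50. The
study's own IC50 values cannot serve as references because the raw
viability readings behind them are not published; recovery is instead
certified on simulated assays (within 10% at 1% noise; bias below 5%
over 200 assays at 2% noise). Tumour volume ($A \times B^2 \times
0.5$) and tumour growth inhibition ($100\,(\bar w_{ctrl} - \bar
w_{trt})/\bar w_{ctrl}$) are exact arithmetic, included so the
downstream in-vivo summaries use audited formulas.

## Numerical choices and problem sizes

* All randomness flows from explicit integer seeds; `run_pipeline()`
  derives fixed per-stage offsets from one global seed, and equal
  configurations give byte-identical JSON/CSV reports.
* Rank deficiency is detected by QR pivoting before fitting and the
  collinear terms are named in the error.
* p-values are computed exactly via the F distribution and rendered as
  `< 0.0001` only in printed tables, never in stored values.
* Default problem sizes used by the test suite — 500-replicate
  parameter-recovery and Box–Cox coverage runs, 200 simulated assays,
  a $21^4$ grid oracle, 200 network restarts — were chosen to keep
  Monte-Carlo error well below the tolerances they certify while the
  whole suite stays comfortably interactive.

## Known limitations

Only plain CCDs are constructed (no Box–Behnken, Plackett–Burman,
D-optimal, blocked or mixed-level designs); least squares is unweighted;
a single response is optimised (no multi-response desirability); the
network has one hidden layer with no cross-validation or early
stopping; and the bioassay module fits one curve at a time without
plate normalisation or synergy modelling.
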