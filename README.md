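# rsmnet

Response-surface and neural-network modelling of bioprocess
optimisation experiments.

`rsmnet` is for experimenters who optimise a bioprocess with a central
composite design (CCD) and want the complete, reproducible statistical
workflow behind the usual report: the design itself, the second-order
model with its full adequacy diagnostics, desirability optimisation
over the design region, and a neural-network benchmark fitted to the
same runs. It ships the 30-run gold-nanoparticle (AuNP) biosynthesis
optimisation dataset — four factors (temperature, incubation time,
HAuCl4 concentration, initial pH), response in µg AuNPs/mL — and
reproduces that study's published statistics from the raw run table.

## What it computes

For a CCD with factorial (±1), axial (±α) and replicated centre points,
the package fits by ordinary least squares on coded factors
x = (actual − centre)/step the nested models

    Y = β0 + Σ βi xi                                (linear)
    Y = β0 + Σ βi xi + Σ βij xi xj                  (2FI)
    Y = β0 + Σ βi xi + Σ βij xi xj + Σ βii xi²      (quadratic)

and reports:

- **ANOVA** with Type-III (partial) sums of squares per term, model and
  residual rows, and the lack-of-fit test against pure error from the
  replicated centre points;
- **adequacy**: R², adjusted R², PRESS = Σ(eᵢ/(1−hᵢᵢ))², predicted
  R² = 1 − PRESS/SStot, adequate precision
  (max ŷ − min ŷ)/√(p·MSE/n), residual SD;
- **diagnostics**: leverages, internally/externally studentized
  residuals, normal-probability data, and the Box–Cox transformation
  profile with a likelihood-ratio confidence interval;
- **desirability optimisation** (Derringer–Suich) by multi-start
  bounded search, with 3D-surface grid data for any factor pair;
- a **single-hidden-layer tanh network** (default 20 nodes, holdback
  validation, best-of-restarts selection) and a run-by-run
  **comparison report** (R², RASE, AAE/MAD, SSE) between the
  polynomial and the network;
- **bioassay helpers** for the downstream biology: tumour volume
  A·B²·0.5, tumour growth inhibition, and four-parameter-logistic
  IC50 fitting for sigmoidal viability curves.

## Worked example

```r
library(rsmnet)

tab <- load_aunps_ccd()          # the bundled 30-run design
fit <- fit_model(tab, "quadratic")
adequacy(fit)
#> R2 0.9885  adj R2 0.9778  pred R2 0.9392
#> PRESS 55567.68  std dev 26.47  adeq precision 35.3410
```

The model explains 98.9% of the response variance, and the
leave-one-out statistics (predicted R² 0.939) say it still predicts
well for runs it has not seen. The ANOVA puts numbers on each term —
model F = 92.16 with a non-significant lack of fit (F = 4.08,
p = 0.067), so the quadratic is adequate:

```r
anova(fit)[c(1, 4, 17), c("source", "estimate", "ss", "f_value", "p_value")]
#>         source estimate        ss   f_value  p_value
#> 1        Model  575.713 903846.42  92.16474 < 0.0001
#> 4           X3  152.553 558534.37 797.34830 < 0.0001
#> 17 Lack of fit       NA   9360.44   4.08073   0.0670
```

Substrate concentration (X3) dominates: one coded step (200 µg/mL
HAuCl4) is worth 152.6 µg/mL of product. At the verification settings
(35 °C, 4 days, 1000 µg/mL, pH 6 — coded (0,0,2,0)) the surface
predicts 845.4 µg/mL against a measured 866.29 µg/mL:

```r
predict(fit, c(0, 0, 2, 0))
#> [1] 845.4067
```

The Box–Cox profile keeps λ = 1 inside its 95% interval, so no
response transformation is needed:

```r
box_cox(tab)
#> <boxcox_profile> lambda_hat 1.190, 95% CI (0.749, 1.673)
```

Desirability search over the coded region finds the settings with the
highest predicted yield, and the network benchmark compares both
models run by run:

```r
optimize_desirability(fit, seed = 1)
#> <desirability_optimum> predicted 1149 (desirability 1.0000)
#> coded:   X1=2.000, X2=-2.000, X3=2.000, X4=-0.108
#> actual:  temperature=45, time=2, haucl4=1000, ph=5.892

ann <- train_ann(tab, ann_config(restarts = 200, seed = 1))
build_comparison(tab, fit, ann)
```

The whole analysis, driven by one configuration (R list or YAML file)
and one global seed, writes a full report bundle — ANOVA, fit summary,
diagnostics, optimisation result, network weights, comparison — with
`run_pipeline()`.

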