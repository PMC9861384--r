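# lodcindex

Nonparametric association analysis for omics measurements whose missing
values come from a **limit of detection (LOD)** — the typical situation in
metabolomics, proteomics and related platforms, where a feature is
reported as missing exactly when its abundance falls below the
instrument's sensitivity.

Instead of deleting censored samples (complete-case analysis, CCA) or
filling them in (minimum / half-minimum imputation), the package works
with ranks and uses the one thing a censored value *does* tell you: it is
lower than every observed value. A pair of samples with exactly one
censored response (a *bridge pair*) can therefore still be ordered, and
only pairs with two censored responses are uninformative.

## The statistic

For response `y` (censored entries `NA`) and complete covariate `x`,
comparable pairs split into π₁ (both observed, untied) and π_b (bridge
pairs). With concordance tallies Γ(·) (x-ties count ½, y-ties are
dropped), the estimator is

    d̂_p = (Γ(π₁) + p·Γ(π_b)) / (|π₁| + p·|π_b|),   0 ≤ p ≤ 1

- `p = 1`: strict-LOD estimator — identical to a classical concordance
  index (c-index) after below-minimum imputation;
- `p = 0`: complete-case concordance;
- `p = n₁/n` (observed fraction): removes the bias caused by discarding
  the censored–censored pairs.

A **self-adjusting check** decides whether the weighting is justified:
under genuine left truncation the bridge-pair concordance d_b exceeds the
complete-pair concordance d₁ (positive association; mirrored for
negative). If the inequality fails, the missingness is not LOD-like and
the estimator falls back to complete cases. Interpretation is as for any
concordance measure: 0.5 = no association, 1 = perfect concordance,
0 = perfect discordance.

Inference: `lodc_test()` tests H₀: d = 0.5 with
`z = (d̂ − 0.5)/√((cvar + ivar)/2)`, averaging an exchangeability-based
null variance (exact at the null, conservative otherwise) and an
infinitesimal-jackknife variance (unbiased away from the null).
`conreg()` extends the estimator to several covariates through a pairwise
exponential-link likelihood with per-coefficient Wald tests (sandwich
standard errors). A simulation/benchmark framework (strict and
sigmoid-probabilistic censoring), comparator methods, high-confidence hit
construction (CCA-Wilcoxon ∪ Fisher-on-missingness), feature-table input
and PQN+log2 preprocessing round out the toolkit. See the vignette in
`vignettes/censored-concordance.Rmd` for the methodology.

## Worked example

```r
library(lodcindex)
set.seed(2024)
x <- rnorm(120)                       # outcome of interest
y <- x + 0.6 * rnorm(120)             # metabolite associated with x
y <- apply_strict_lod(y, 0.35)        # 35% censored below the LOD
lodc(y, x)
#> Concordance with LOD-censored response (mode = auto)
#>   estimate : 0.8395
#>   n = 120  observed = 78  missing = 42
#>   bridge weight p = 0.65
#>   d1 = 0.7712, db = 0.9359 -> LOD-consistent (positive direction)
```

The estimate 0.84 says a sample with higher `x` has ~84% probability of
the higher metabolite level. `d1 < db` confirms the missingness looks
LOD-like, so the bridge pairs were kept with weight p = n₁/n = 0.65
(otherwise the estimator would have reported the complete-case value).

```r
lodc_test(y, x)
#> 	Concordance z-test for LOD-censored data (mode = auto, bridge weight = 0.65)
#> data:  y and x
#> z = 10.173, p-value < 2.2e-16
#> alternative hypothesis: true concordance is not equal to 0.5
```

Multivariable, e.g. adjusting the effect of `x` for a correlated
covariate `z`:

```r
d <- simulate_multivariable(500, seed = 7)   # X, Z = X + e, Y = X + Z + 3e
d$y <- apply_strict_lod(d$y, 0.4)
summary(conreg(y ~ x + z, data = d))
#>   Estimate Std. Error z value Pr(>|z|)
#> x  0.51111    0.09322   5.483 4.19e-08 ***
#> z  0.44954    0.06281   7.157 8.22e-13 ***
#> Overall model concordance: 0.7285
```

Both partial effects are recovered as positive and significant despite
40% censoring. A command-line wrapper with `test`, `fit`, `simulate`,
`benchmark` and `hc-hits` subcommands is installed under `exec/`.

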