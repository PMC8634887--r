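# latentWMW

Rank-based two-group comparison of a **latent** outcome measured by several
error-prone indicators.

Constructs like depression or fatigue are observed only through proxy
scores (e.g. three questionnaires), each contaminated by measurement error
and often skewed with outliers. Classical latent-variable comparisons go
through factor models or SEM, which lean on normality and linearity.
`latentWMW` instead extends the Wilcoxon–Mann–Whitney (WMW) test to this
setting:

1. **Aggregate** the indicators into a composite on the pooled-standardized
   scale — either the unweighted mean, or a *maximally reliable* weighted
   composite. For the latter, each indicator's error variance is estimated
   by the triad covariance identity
   `var(e1) = var(Y1) − cov(Y1,Y2)·cov(Y1,Y3)/cov(Y2,Y3)`, and the weights
   `a` maximize the composite reliability
   `(aᵀΣa − aᵀΨa)/(aᵀΣa)` — the leading eigenvector of
   `(Σ − Ψ)a = λΣa` (closed form, no optimizer).
2. **Test** `H0: F_η = F_η*` by the WMW statistic on the composite,
   `U = (π̂ − ½)/σ0` with `σ0 = √((m+n+1)/(12mn))`, where the probabilistic
   index `π̂ = P̂(group1 < group2)` uses the mid-tie rule. Inference by
   normal approximation, exact enumeration, or seeded permutation.
3. **Design** studies with the Noether-type sample-size formula
   `N = (z_α + z_β)² / (12c(1−c)(δ−½)²)`, its power inverse, and the
   normal-shift conversion `π = Φ(d/√2)` between the probabilistic index
   and a standardized difference.
4. **Simulate**: a seeded Monte Carlo engine reproduces empirical type I
   error and power for the WMW and Welch-t competitors over a grid of
   latent distributions (normal, t₅, Laplace, centered exponential), linear
   and curvilinear measurement functions, reliabilities, sample sizes and
   error-misspecification settings.

Because only ranks enter, the test is valid under any strictly monotone
indicator–construct relation and robust to outliers; it is most attractive
when scores are skewed or heavy-tailed, where it clearly out-powers
t-based competitors.

## Worked example

A synthetic questionnaire-shaped dataset ships with the package tools
(three positively correlated, right-skewed scores and an employment-like
group factor; entirely simulated):

```r
library(latentWMW)

f <- tempfile(fileext = ".csv")
make_fixture("case_like", seed = 7, path = f)
panel <- read_panel_csv(f, "employment", reference = "employed")

latent_wmw_test(panel, strategy = "max_rel", method = "normal")
#> Wilcoxon-Mann-Whitney test for a latent variable
#>   composite: max_rel;  groups: employed (m = 273) vs unemployed (n = 182)
#>   P(employed < unemployed) = 0.5636  (probabilistic index)
#>   u = 2.2997,  p-value = 0.02146  (normal, two.sided)
```

A random unemployed subject has an estimated 56.4% probability of scoring
higher on the depression-like construct than a random employed subject
(50% would mean no group difference), significant at the 5% level. The
measurement side of the analysis:

```r
estimate_error_variances(panel)
#> Triad measurement estimates (pooled over groups)
#>             error_variance reliability truncated
#> phq_like          2.268948   0.7795638     FALSE
#> cesd_like         3.661575   0.7514491     FALSE
#> promis_like       8.633513   0.8075325     FALSE
```

Designing a new study to detect a probabilistic index of 0.65 (a medium
effect, `d ≈ 0.55`) with 80% power at one-sided α = 0.05:

```r
required_sample_size(alpha = 0.05, power = 0.80, c = 0.5, delta = 0.65)
#> [1] 92            # 46 per group
expected_power(92, 0.5, 0.65, 0.05)
#> [1] 0.8016
```

One cell of the simulation study (skewed latent variable, 50 per group,
80% reliability — note the rank tests' power advantage over the t-tests):

```r
sc <- wmw_scenario("exponential", "linear", reliability = 0.8, m = 50,
                   hypothesis = "alternative")
run_scenario(sc, n_reps = 200, seed = 1)
#>             rejection_rate  mc_se
#> wmw_max_rel          0.650 0.0337
#> wmw_mean             0.635 0.0340
#> t_max_rel            0.435 0.0351
#> t_mean               0.435 0.0351
```

A command-line front end is installed with the package
(`exec/latentwmw`): subcommands `test`, `simulate`, `power` and `fixture`,
e.g. `latentwmw test --input data.csv --group employment --strategy
max_rel --out result.json`.

See the vignette `vignettes/latent-wmw-methods.Rmd` for the measurement
model, the calibration of the simulation engine, and all numerical
conventions.

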