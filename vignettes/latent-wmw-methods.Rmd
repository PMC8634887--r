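---
title: "Rank-based two-group comparison of a latent variable: models, calibration and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based two-group comparison of a latent variable}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentWMW)
```

## The problem

Many constructs in psychology and epidemiology — depression, fatigue,
quality of life — are not observed directly. A study instead records several
*indicators* (questionnaire scores, say) that each measure the latent
construct $\eta$ with error. The measurement model assumed throughout this
package is

$$Y_p = h_p(\eta) + \varepsilon_p, \qquad p = 1, \dots, P,$$

with $h_p$ strictly monotone (not necessarily linear: floor and ceiling
effects bend the indicator–construct relation) and $\varepsilon_p$ an
additive measurement error, independent of $\eta$. The *reliability* of an
indicator is the share of its variance not due to error,
$\mathrm{Rel}(Y_p) = (\mathrm{var}(Y_p) - \mathrm{var}(\varepsilon_p)) /
\mathrm{var}(Y_p)$.

The question of interest is whether the latent distribution differs between
two groups: $H_0: F_\eta = F_{\eta^*}$ against a two-sided alternative.
Questionnaire scores are typically skewed with outliers, which makes a
rank-based test attractive. The package tests this hypothesis by applying
the Wilcoxon–Mann–Whitney (WMW) test to a single *composite* of the
indicators, and reports the **probabilistic index**
$\hat\pi = \widehat{P}(\text{group 1} < \text{group 2})$ — the probability
that a random subject of group 1 scores below a random subject of group 2
(0.5 under the null). Because only ranks enter, the test is invariant to
monotone $h_p$ distortions of the composite and robust to outliers. The key
assumption backing validity on the latent scale is that each indicator's
error distribution is the same in both groups; a location-shift alternative
makes the test unbiased.

## Aggregating indicators

All aggregation happens on the *pooled-standardized* scale: each indicator
is centered and scaled by the mean and standard deviation of the combined
sample of both groups (`standardize()`). Using pooled moments keeps the
transformation identical for the two groups, which is what makes a composite
comparable across groups at all.

Two weighting strategies are available:

* **mean** — the unweighted mean of the standardized indicators. No
  measurement-error estimates are needed.
* **max_rel** — a maximally reliable weighted composite. With $\Sigma$ the
  pooled covariance of the standardized indicators and $\Psi$ the diagonal
  matrix of their error variances, the reliability of $a^\top Z$ is
  $(a^\top\Sigma a - a^\top\Psi a)/(a^\top\Sigma a)$, and its maximizer is
  the leading eigenvector of the generalized eigenproblem
  $(\Sigma - \Psi)a = \lambda\,\Sigma a$. This is solved in closed form
  through a Cholesky factor of $\Sigma$, so the weights are deterministic —
  no optimizer, no seed. Tests verify the solution against a direct
  numerical maximization (agreement $10^{-8}$) and a $0.01$-resolution
  simplex grid search ($10^{-4}$).

The error variances that feed `max_rel` come from the *triad* estimator
(`estimate_error_variances()`): under a linear single-factor model, for any
three indicators,
$\mathrm{var}(\varepsilon_1) = \mathrm{var}(Y_1) -
\mathrm{cov}(Y_1,Y_2)\,\mathrm{cov}(Y_1,Y_3)/\mathrm{cov}(Y_2,Y_3)$,
and the index rotation gives one estimate per indicator. Design choices
made here, with rationale:

* With exactly three indicators the symmetric rotation is used; with
  $P > 3$ the estimate for indicator $p$ averages over all triads
  containing $p$ (each triad is unbiased under the linear model; averaging
  only reduces variance).
* Sampling noise can push an estimate negative or a reliability outside
  $[0,1]$; estimates are clipped (to $0$ and to $[0,1]$) and flagged, which
  keeps the downstream weight optimization well-posed.
* A pairwise covariance within $10^{-8}\,s_p s_q$ of zero makes a triad
  numerically meaningless and raises a degeneracy error naming the pair.
* Pooled moments (both groups combined, unbiased $n-1$ denominator) are
  used throughout; per-group estimation is deliberately not offered, since
  the composite must be a single group-invariant linear combination.

Weights are reported with unit Euclidean norm and positive mean loading.
The rank test is invariant to any positive rescaling of the composite, so
the normalization is purely a reproducibility convention.

## Inference

`latent_wmw_test()` splits the composite by group and standardizes
$\hat\pi$ with the tie-free null standard deviation
$\sigma_0 = \sqrt{(m+n+1)/(12mn)}$, giving $U = (\hat\pi - 0.5)/\sigma_0$.
p-values come from

* the standard normal approximation of $U$ (no continuity correction),
* exact enumeration of all $\binom{m+n}{m}$ group assignments (tie-free
  samples, $m + n \le 12$), or
* a seeded Monte Carlo permutation null, with the observed statistic
  included in numerator and denominator; when the requested number of draws
  covers all distinct assignments the enumeration is exhaustive and
  coincides with the exact method.

The default (`method = "auto"`) uses the normal approximation when both
groups have at least 20 subjects and permutation below that — small-sample
prudence that does not change large-sample behavior. Real questionnaire
data tie heavily; $\hat\pi$ always uses the mid-tie $\tfrac12$ convention,
$\sigma_0$ keeps the tie-free formula by default, and
`tie_correction = TRUE` subtracts the usual tied-group term for users who
prefer the corrected variance. Defaults match the plain standardization
above; the option matches common practice.

## Design: sample size and power

For a one-sided test at level $\alpha$, power $1-\beta$, allocation
fraction $c = m/N$ and design probabilistic index $\delta$, the
Noether-type approximation gives

$$N = \frac{(z_\alpha + z_\beta)^2}{12\,c(1-c)\,(\delta - \tfrac12)^2},$$

rounded up (`required_sample_size()`), with the inverse power relation
$1-\beta = \Phi\!\big(\sqrt{N\,12\,c(1-c)(\delta-\frac12)^2} - z_\alpha\big)$
(`expected_power()`). The two-sided variant via $\alpha/2$ is provided as a
clearly labeled convenience. $\delta$ here is the index on the composite
scale: measurement error attenuates the observable index below the latent
one, and no attenuation correction is attempted (point estimation on the
latent scale is out of scope). The normal-shift conversion
$\pi = \Phi(d/\sqrt2)$ links the index to a standardized difference $d$;
$d = 0.55$ (a medium effect) corresponds to $\pi \approx 65\%$.

## The simulation engine and what it emulates

`wmw_scenario()` / `run_scenario()` / `run_grid()` regenerate a Monte Carlo
study of empirical type I error and power. The data-generating process is

$$\eta = \zeta, \qquad \eta^* = \beta^* + \zeta^*,$$
$$Y_1 = \eta + \varepsilon_1,\quad Y_2 = h_2(\eta) + \varepsilon_2,\quad
  Y_3 = h_3(\eta) + \varepsilon_3,$$

with $\zeta, \zeta^*$ i.i.d. from one of four latent laws chosen to span
normal, heavy-tailed and skewed shapes seen in practice: $N(0,1)$; Student
$t_5$ (variance $5/3$); Laplace with scale $1.25$ (variance $3.125$); and
the standard exponential shifted to mean zero. Every rejection rate is
invariant to a joint rescaling of the DGP, so the Laplace scale convention
cannot affect results. In nonlinear scenarios $h_2, h_3$ are
$\Phi^{-1}\!\circ F_{t,df}$ sigmoids (df 1 and 3; indicator 1 stays
linear), which recreate curvilinear indicator–construct trends.

Deterministic calibrations define the study conditions:

* **Effect size.** $\beta^*$ solves $P(\eta < \eta^*) = \delta$ (default
  0.65 under the alternative, 0.5 under the null) by root-finding on the
  convolution integral $\int F(\beta + z)f(z)\,dz$ to $10^{-6}$ in the
  index. The normal case has the closed form $\sqrt2\,\Phi^{-1}(\delta)$;
  the exponential case must land on the Laplace-difference quantile
  $-\log(0.7)$, which the tests check.
* **Reliability.** The error sd solves
  $\mathrm{sd} = \sqrt{\mathrm{var}(h_p(\eta))\,(1-r)/r}$, with
  $\mathrm{var}(h_p(\eta))$ exact for the identity link and by adaptive
  quadrature otherwise. Defining reliability against the variance of the
  signal actually entering each indicator makes the target hold exactly per
  indicator, also in nonlinear scenarios. Grid values are 0.80 (adequate)
  and 0.60 (weak).
* **Misspecification settings.** Setting 1 is correctly specified (normal
  errors, identical across groups). Setting 2 inflates the group 2 error
  sds so each group 2 reliability sits exactly 5 percentage points below
  group 1's (solved against the shifted group 2 signal variance). Setting 3
  keeps variances equal but draws group 2 errors from a variance-matched
  Laplace. Setting 4 drops indicator 3's reliability to 0.20 in both
  groups. Only the group difference $\beta^* - \beta$ is identified, so
  $\beta = 0$ for group 1.

Each replicate generates a panel, builds both composites (the
maximal-reliability weights re-estimated from that replicate's triad
covariances), and applies the two-sided WMW test and the Welch $t$-test to
each composite at $\alpha = 0.05$. WMW inference inside the engine uses the
normal approximation at all sizes (the data are continuous, so ties have
probability zero); the $t$-tests switch to a seeded 1000-draw permutation
null when a group has fewer than 20 subjects, mirroring how small samples
are usually handled. A replicate whose triad estimation degenerates falls
back to equal weights and is counted in `failures`, keeping the
rejection-rate denominator honest. Seeding is counter-based: every
replicate and every scenario has a derived seed, so any cell can be
reproduced in isolation.

The grid of `scenario_grid()` — 4 distributions × 2 link shapes × 2
reliabilities × 3 group sizes (15/50/100 per group), each under settings
1–4 — has 192 cells per hypothesis. The test suite runs the full 48-cell
correctly-specified null sweep at 1,000 replicates (type I error within
binomial tolerance of 5%), reproduces seven published power cells at 1,000
replicates, and checks the qualitative orderings (rank tests dominate
$t$-tests under the skewed latent law; lower reliability always costs
power) at 2,000 replicates — sizes chosen as the package's own balance of
precision and runtime. Consistency checks use $10^5$ subjects for triad
recovery and $10^7$ draws for shift calibration.

## What the synthetic data do and do not show

The generator emulates the structure of questionnaire studies: a few
positively correlated, possibly skewed indicator scores per subject, a
binary group factor, and (in the `case_like` fixture) a floor-effect-like
nonlinearity in one indicator. It does not emulate discreteness of real
questionnaire scores (generated indicators are continuous, so ties are
absent — real data tie heavily, which is why the mid-tie rule and the
tie-corrected variance option exist), item-level structure, missing data,
or violations of unidimensionality. Passing simulations therefore support
the method's operating characteristics under a one-factor
monotone-measurement world; they cannot certify measurement invariance in
any particular dataset, which must be argued substantively or checked with
a structural model before the test's latent-scale interpretation holds.

## Numerical choices and degenerate inputs

Quadrature tolerances are $10^{-9}$ relative (variances) and effectively
$10^{-10}$ (calibration root); the eigen solve symmetrizes the whitened
matrix before decomposition; a singular standardized covariance raises a
collinear-indicators error rather than returning unstable weights; constant
indicators, empty groups, more or fewer than two group levels, and
$\delta = 0.5$ designs all raise classed errors early. If all error
variances clip to zero and indicators are exchangeable, the eigenproblem is
symmetric and the equal-weight solution is returned. Negative-average
eigenvectors are sign-flipped so the composite is positively oriented with
the indicators' mean, keeping the reported index interpretable.

## Known limitations

* The probabilistic index on the composite is attenuated toward 0.5 by
  measurement error; the package tests hypotheses but does not de-attenuate
  the point estimate.
* The triad estimator requires $P \ge 3$ indicators and linearity *among*
  indicators; with $P < 3$ only the mean-composite strategy is available.
* The design formulas operate on the composite-scale index, so sample sizes
  are calibrated to the observable, not the latent, effect.
* Nonnegativity of the maximal-reliability weights is not enforced; with
  very unequal reliabilities a weight can legitimately be near zero or
  change sign under sampling noise at small $n$.
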