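---
title: "Estimating excess mortality of chronic diseases from aggregated data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating excess mortality of chronic diseases from aggregated data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idmexcess)
```

## The model

`idmexcess` works with the three-state illness-death model for chronic,
non-remitting diseases: people move from *healthy* to *diseased* at the
age-specific incidence rate $i(a)$ (per person-year among the
disease-free), and die at rate $m_0(a)$ if non-diseased or $m_1(a)$ if
diseased.  Two summaries of the mortality contrast are of interest:

* the **excess mortality rate** $\Delta m = m_1 - m_0$ (also called the
  attributable risk), and
* the **mortality rate ratio** $R = m_1 / m_0$, which for genuine
  (positive) rates must satisfy $R > 0$.

Along a birth cohort — the unit-slope line of the Lexis plane — the
age-specific prevalence $p$ obeys

$$\partial p \;=\; (1 - p)\,\{\,i - p\,(m_1 - m_0)\,\}
   \;=\; (1-p)\Big\{\,i - m\,\frac{p\,(R-1)}{1 + p\,(R-1)}\Big\},$$

where $\partial p = (\partial_t + \partial_a)p$ is the directional
derivative along the cohort and $m = p\,m_1 + (1-p)\,m_0$ is the general
(population-wide) mortality.  The two forms are algebraically equivalent;
both assume (a) no remission and (b) that migration does not distort the
age-specific prevalence.

Solving for the mortality contrast turns aggregated surveillance data —
prevalence, incidence and general mortality, all routinely published —
into estimators of quantities that would otherwise need individual-level
follow-up:

$$\widehat{\Delta m} = \frac{\,i - \partial p/(1-p)\,}{p},
  \qquad
  \widehat{R} = 1 + \frac{1}{p}\cdot
  \frac{i\,(1-p) - \partial p}{(1-p)(m - i) + \partial p}.$$

Both are exact when their inputs are exact: feeding back the prevalence
and its analytic derivative from a forward solution of the cohort ODE
recovers $\Delta m$ and $R$ to machine precision (this round trip is a
core regression test).  The two estimators are also mutually consistent:
for any input, $\widehat{\Delta m} = (\widehat{R}-1)\,m\,/\,\{1 +
p(\widehat{R}-1)\}$, i.e. they imply the same non-diseased mortality.

Estimates are returned **verbatim**: negative or absurdly large values are
never clipped or set to missing, because exactly those values are the
scientifically interesting symptom of the instabilities discussed below.
`p = 0` or `p = 1` at an estimation age is an error (the estimators divide
by $p$ and $1-p$), not a silent `NaN`.

## Input models

The raw inputs are two prevalence cross-sections a few calendar years
apart ($t_0$, $t_1$), an incidence schedule and a general-mortality
schedule at the midpoint year.  They are smoothed by transform-linear
regressions, mirroring standard practice for claims-data schedules:

* prevalence: ordinary least squares of $\mathrm{logit}(p)$ on age;
* incidence: ordinary least squares of $\log(i)$ on age.

Both regressions are unweighted by default (a `weights` argument exists).
The default fitting range is ages 15–100.  Records that cannot be
transformed ($p \in \{0, 1\}$, $i = 0$) are dropped from the fit by
default.  Predictions are automatically inside $(0,1)$ (logit model) or
positive (log model).  The fitted coefficient pair and its OLS covariance
matrix are retained; they are the input distribution of the sensitivity
analysis.  General mortality is interpolated linearly between grid ages
and treated as fixed — only prevalence and incidence carry sampled
uncertainty downstream.

### The cohort derivative

$\partial p$ must be formed from the two cross-sections.  Two methods are
implemented in `cohort_derivative()`:

* **`analytic`** (default): the two fitted logit lines are interpolated
  linearly in calendar time, defining a logit surface $\eta(t,a)$; the
  prevalence and its directional derivative along the cohort line through
  (midpoint year, $a$) are evaluated analytically:
  $p = \mathrm{expit}\{(\eta_0(a)+\eta_1(a))/2\}$ and
  $\partial p = p(1-p)\{\bar\beta_1 + (\eta_1(a)-\eta_0(a))/(t_1-t_0)\}$
  with $\bar\beta_1$ the mean age slope.
* **`finite_difference`**: the classical symmetric difference along the
  Lexis diagonal, $\partial p = \{p_1(a+h) - p_0(a-h)\}/(t_1-t_0)$ with
  $h=(t_1-t_0)/2$, and $p$ the mean of the two endpoint predictions.

The finite difference is exact for surfaces affine on the *natural* scale;
the analytic form is exact for surfaces affine on the *logit* scale — the
assumption the input models themselves make.  The analytic method is the
default because the natural-scale difference attenuates $\widehat R - 1$
by a curvature term of order $h^2\beta_1^2$ (about one percent for a
six-year window and the logit slopes typical of chronic diseases).  That
attenuation is invisible for stable ages in absolute terms, but with
claims-scale denominators the sensitivity intervals are of the same one
percent order, so a derivative consistent with the model family matters;
with it, interval coverage in the recovery simulations is nominal.

## Probabilistic sensitivity analysis

Uncertainty is propagated by Monte Carlo: each draw samples the three
coefficient pairs from independent bivariate normal distributions (the
asymptotic OLS distribution of each fit), rebuilds $p$, $\partial p$ and
$i$ at every evaluation age, and applies both estimators.  Per age we
report the empirical median and the 2.5%/97.5% quantiles of each outcome
($\Delta m$, $\Delta m/m$, $R$) over 5000 draws by default — quantiles are
empirical, with no smoothing.  The ratio $\Delta m / m$ is reported
because it is a lower bound for $R$: since $m \ge m_0$,
$\Delta m/m \le \Delta m/m_0 = R - 1$, hence
$R \ge 1 + \Delta m/m \ge \Delta m/m$ (`check_bound_chain()` verifies the
chain where it applies, i.e. where the implied $m_0$ is positive and
$\widehat{\Delta m} \ge 0$).

Draws that hit a singular configuration (an exactly zero rate-ratio
denominator) yield non-finite outcomes; these are excluded from the
quantiles but counted per age (`n_nonfinite`), so implausible-but-finite
summaries survive — silently propagating `NaN` would destroy exactly the
rows that need reporting.  If every draw is non-finite at an age the
summary is `NaN`, not an error.  A fixed seed makes the whole analysis
bitwise reproducible.

Age-group summaries (e.g. five-year groups with an open-ended `90+`)
represent each group by its midpoint age (92.5 by default for `90+`); the
group's per-draw outcome is the outcome at that representative age, so a
group row equals the representative age's row by construction.

## Instability diagnostics

With exact inputs the estimators are exact; with noisy inputs two
mechanisms make them explode at young ages:

1. **Small prevalence.**  Both estimators carry a factor $1/p$; when
   $p < 0.01$ (i.e. $1/p > 100$, the default threshold) any absolute input
   error is amplified a hundred-fold or more.
2. **Near-singular denominator.**  The rate-ratio denominator
   $(1-p)(m-i)+\partial p$ approaches zero when the incidence is close to
   the general mortality and the prevalence derivative is small; the
   estimate then oscillates between huge positive and negative values.
   The default "near zero" margin is $0.05\cdot\max(i, m)$.

`flag_estimate()` also flags negative ratios (impossible for genuine
rates) and magnitudes above a plausibility ceiling of 50.  The ceiling is
this package's own convention — the literature describes the implausible
regime qualitatively but gives no numeric cutoff beyond the sign.  All
thresholds are configurable; flags never modify values.

## The synthetic-data generator

Because the real claims inputs live in external reports, the package
generates complete stand-ins from a known truth: the true prevalence
surface is obtained by integrating the cohort ODE (classical fixed-step
RK4, default step 0.1 years, validated against a 100-fold finer
reference), observed prevalence is binomial given per-age denominators
$n(a)$, observed incidence is Poisson given person-years $PY(a)$, and the
general mortality is emitted noise-free, matching its fixed-data role.

Two scenarios are bundled; both are built by an *exact-identity*
construction — choose the true prevalence curve and derive the remaining
rate from the illness-death identity, so the truth is internally
consistent by construction rather than approximately so:

* `scenario_constant_ratio()` — $R \equiv 2$, prevalence rising smoothly
  from about 0.015 (age 30) to 0.15 (age 90), $n = PY = 10^6$.  The true
  logit-prevalence and log-incidence are exactly linear in age and the
  non-diseased mortality is derived (it comes out Gompertz-like), so both
  input regressions are correctly specified and the scenario isolates
  pure sampling noise.  Used for coverage studies: pooled over 20
  replications, the 95% PSA intervals cover the true ratio at about 95%
  of (replication, age) pairs at ages with $p > 0.02$.  The identity
  forces the derived $m_0$ negative below roughly age 30, so the
  integration starts at 30 with the on-curve prevalence as initial value.
* `scenario_diabetes_like()` — single-year ages 15–99, cross-sections
  2009 and 2015, $n = PY = 2\times 10^6$.  The true logit-prevalence is a
  straight line *plus a young-age excess* decaying over about seven years
  of age — a stylised early-onset (type-1-like) plateau.  Prevalence stays
  below 0.005 until the mid-forties; the true ratio declines from about 7
  (age 20) to 1.3 (age 95).  The plateau is precisely the feature a
  logit-linear fit cannot represent, and below age 50 the fitted
  numerator $i(1-p) - \partial p$ — whose true value, $p\,\Delta m(1-p)$,
  is of order $10^{-6}$ there — is overwhelmed by the combination of that
  misspecification and sampling noise.  Amplified by $1/p \sim 10^3$, the
  point estimates of $R$ swing into the hundreds and negative values
  across a contiguous young-age band, while ages 60+ stay flag-free with
  $R$ between roughly 1.3 and 1.8 (slightly attenuated from the truth by
  the same young-age misspecification — deliberately so: sensitivity to
  transform-linearity is a feature of the estimators worth demonstrating,
  not a defect of the generator).

What the generator does **not** emulate: migration, diagnostic
misclassification (sensitivity/specificity of claims diagnoses), secular
changes in covariates or coding practice, remission, and individual-level
correlation structure.  Passing tests on synthetic data therefore
demonstrate the estimators' numerical behaviour under the stated sampling
models, not robustness to those real-world complications.

## Numerical choices and conventions

* Rates are per person-year, ages continuous years, prevalence a
  proportion — never a percentage — at every API boundary (`per_100k` on
  CSV read converts published per-100k rates, loudly).
* RK4 step 0.1 years; the forward solution is clipped to $[0,1]$ against
  roundoff only (for nonnegative rates the exact solution cannot leave the
  interval, and a boundedness property test checks this).
* The reported per-age `dp` of `forward_prevalence()` is the analytic
  right-hand side evaluated at the integrated prevalence, which is what
  makes the round-trip tests exact identities rather than
  discretisation-limited comparisons.
* Degenerate inputs error early and specifically: non-finite rates,
  $1 + p(R-1) \le 0$ in the ratio form, prevalence at 0 or 1 at an
  estimation age, an exactly zero rate-ratio denominator, evaluation ages
  outside a schedule's span.
* Simulation sizes in the test-suite: 20 random parameter sets for the
  round trip, $10^5$ random inputs for the consistency identity, 20
  seeded replications with 400 PSA draws each for coverage, 5 seeds for
  the instability pattern; the shipped analyses default to 5000 draws.
  These sizes give Monte-Carlo error comfortably below the margins being
  tested while keeping a full check fast.

## Known limitations

* The estimators are only as good as the transform-linearity of the true
  schedules; curvature the input models cannot represent propagates into
  biased derivatives and, at small prevalence, into arbitrarily large
  ratio errors.  The diagnostics flag the fragile region but do not
  correct it — regularisation of the unstable young-age regime is out of
  scope here.
* The PSA treats the three fitted models as independent and the general
  mortality as exact; correlation between prevalence and incidence
  uncertainty, and uncertainty in $m$, are not modelled.
* One forward solve uses one rate schedule along the whole cohort
  diagonal; period-specific rate changes within a cohort's lifetime are
  supported only through explicitly time-dependent rate functions in the
  generator, not in the estimation path.
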