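---
title: "Immune correlates and immunogenicity-based vaccine efficacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune correlates and immunogenicity-based vaccine efficacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxcop)
```

## The estimation problem

A vaccine trial follows subjects from a post-vaccination landmark visit
(when the immunogenicity biomarker is measured) to disease, dropout, or the
end of follow-up. Vaccine efficacy (VE) in a subgroup is one minus the
vaccinated-to-control ratio of disease risk, times 100. With few cases per
subgroup, case-counting — the ratio of incidence rates — is noisy, and a
hazard model with a vaccination-status indicator inherits the same case-only
information. When the biomarker is predictive of the hazard, however, the
risk model can be evaluated at every subject's own biomarker value, so the
*titer distribution* of each arm, not just its case count, informs the VE
estimate. `vaxcop` implements that estimator together with the two
screening questions that must be answered before it is trusted: is the
biomarker a correlate of risk (CoR), and a correlate of protection (CoP)?

## Risk models

The workhorse is the Cox proportional-hazards model

$$\lambda(t \mid X_i) = \lambda_0(t)\,\exp(\beta_1 x_{i1} + \cdots + \beta_L x_{iL})
  = \lambda_0(t)\,\exp(lp_i),$$

fitted by maximising the partial likelihood with the Efron tie correction
(`fit_cox()`). The immunogenicity variable $T$ may enter linearly, as a
quadratic polynomial $\beta_1 T + \beta_2 T^2$, or through a log or
square-root transform (`design_spec()`); covariates are reference-coded and
may interact with $T$. Interactions of $T$ with a baseline covariate encode
subgroup-specific risk curves (e.g. a different slope in seropositive and
seronegative subjects).

With competing event causes (e.g. disease caused by different serotypes),
two standard extensions are provided. The *cause-specific* Cox model
(`fit_cause_specific()`) censors competing events at their times, which is
valid for the cause-specific hazard under non-informative competing
censoring. The *Fine–Gray* model (`fit_fine_gray()`) targets the hazard of
the cumulative incidence function (CIF): subjects failing from competing
causes remain in the risk set after their event, down-weighted by the
Kaplan–Meier estimate of the censoring survival, $G(t)/G(s)$, pooled across
arms. Fitting is delegated to `cmprsk::crr()`; `estimate_cif()` provides the
Aalen–Johansen CIFs, which satisfy
$\hat S(t) + \sum_c \widehat{\mathrm{CIF}}_c(t) = 1$ at every step.

The proportional-hazards assumption is checked by the score test of zero
slope in the regression of scaled Schoenfeld residuals on time
(`ph_test()`). The identity time transform is the default and is recorded
in the output, since different transforms (KM, rank) give different
p-values for the same data.

## Correlate-of-risk selection

`assess_cor()` encodes a two-stage, AIC-guided selection:

1. **Functional form.** Linear and quadratic biomarker-only models are
   fitted. The lower-AIC form is kept *unless* the AIC difference is at
   most 2, in which case the form with fewer parameters is kept. The guard
   is deliberately inclusive: an AIC reduction of exactly 2 is what a
   single extra parameter buys for free under the AIC penalty, so it is not
   evidence for the larger model. This margin (default 2) is the
   `parsimony_margin` argument.
2. **Adjustment.** The kept form is fitted unadjusted and adjusted for all
   supplied covariates plus their interactions with $T$; the same
   AIC-with-parsimony rule picks the final model.

Every attempted candidate is recorded in a ledger (label, parameter count,
log partial likelihood, AIC, convergence), so the selection is auditable
and re-running on the same table is bit-reproducible. The CoR verdict is a
joint likelihood-ratio test of *all* $T$-involving terms in the final model
(the quadratic term, interactions with $T$, and so on) at level $\alpha$
(default 0.05). For the linear single-term model this coincides
asymptotically with the usual Wald test on the one coefficient. When the
final model carries $T$-by-covariate interactions, per-subgroup verdicts
are added: a joint Wald test of the $T$ terms evaluated at each covariate
level, labelled as such in the output.

## Correlate of protection: the Prentice test

`prentice_test()` adds a vaccination-status indicator to the final CoR
model. The biomarker is a CoP when (i) its terms remain jointly significant
in the augmented model and (ii) the likelihood-ratio test of the added
vaccination term is *not* significant — conditional on the biomarker, the
arm carries no further information about the hazard. Both p-values are
reported; the verdict is their conjunction at $\alpha$.

Two caveats are inherent to the framework and not repaired here. First, a
non-significant vaccination term can reflect lack of power (few cases in
the vaccinated arm) rather than full mediation. Second, for Fine–Gray fits
the likelihood-ratio statistic is computed on the weighted pseudo-partial
likelihood; this mirrors the Cox-based procedure exactly but is an
approximation, and the Wald test from `model_tests()` is available as a
cross-check.

## Risk curves and immunogenicity-based VE

The risk curve is the hazard ratio as a function of the biomarker,

$$\rho(T \mid X) = \frac{\lambda(t \mid T, X)}{\lambda(t \mid T_\mathrm{ref}, X)}
 = \exp\{lp(T, X) - lp(T_\mathrm{ref}, X)\},$$

with the baseline hazard cancelling. `risk_curve()` defaults
$T_\mathrm{ref}$ to the median observed biomarker value — a display choice
only, since every downstream VE quantity is invariant to it. Pointwise
intervals use the delta method on $lp(T) - lp(T_\mathrm{ref})$.

Subgroup VE averages $\rho$ over each arm's observed biomarker values,
each subject contributing their own covariate vector:

$$\mathrm{VE} = \left(1 -
  \frac{\tfrac1I \sum_i \rho(T_i^{\mathrm{vacc}} \mid X_i)}
       {\tfrac1M \sum_m \rho(T_m^{\mathrm{ctrl}} \mid X_m)}\right)\cdot 100 .$$

Subgroup membership is defined by the conditioning covariate only; within
the subgroup, each subject's full record is used. If the supplied fit
contains a vaccination-status term (an augmented CoP model), that indicator
is evaluated at 0 for every subject, so the averages compare arms through
immunogenicity and covariates alone; the intended input is the final CoR
model, which has no such term. Because only ratios of hazards enter, the
estimator is invariant to $T_\mathrm{ref}$ and to any rescaling of
$\lambda_0$ — both invariances are asserted to $10^{-10}$ in the test
suite.

For arm-specific normal biomarker laws and a linear link, the population
value has the closed form (via the normal moment-generating function)

$$\mathrm{VE}_\mathrm{true} = \left(1 - e^{\beta(\mu_v - \mu_c) +
  \beta^2(\sigma_v^2 - \sigma_c^2)/2}\right)\cdot 100,$$

implemented in `true_ve()` (quadrature for the quadratic link) and used as
the recovery oracle throughout the tests.

### The hybrid confidence interval

`ve_confidence_interval()` propagates the two sources of uncertainty
jointly. Each of `n_bootstrap` (default 1000) replicates: (a) resamples
subjects with replacement *within each arm* of the subgroup, carrying each
selected subject's biomarker and covariates; (b) draws one coefficient
vector from $\mathcal N(\hat\beta, \hat\Sigma)$; and (c) recomputes the VE.
The interval is the 2.5th and 97.5th empirical percentile of the replicate
values, using the inverse-ECDF quantile convention (type 1), which is
recorded in the result together with the seed. Stratifying the bootstrap by
arm keeps both averages defined in every replicate — an unstratified
subject bootstrap can empty an arm in small subgroups; the stratification
is a documented implementation choice. One parameter draw per replicate
couples the two uncertainty sources rather than nesting them. A covariance
matrix that cannot be factored falls back, with a warning, to a point mass
at $\hat\beta$ (pure data bootstrap). The point estimate always comes from
the original data and $\hat\beta$, so with a degenerate covariance and
within-arm-constant data the interval has width exactly zero.

### Comparators

`case_count_ve()` is the incidence-rate comparator. Its interval uses the
exact conditional-binomial construction: given the total case count, the
vaccinated-arm count is binomial with success probability
$\theta p_v / (\theta p_v + p_c)$ where $\theta$ is the rate ratio and
$p_v, p_c$ the person-years; a Clopper–Pearson interval for the proportion
maps monotonically back to VE. The method is a documented choice (swappable
in principle), selected because it is exact at the tiny case counts where
the comparison matters, and it handles the boundary cases gracefully: zero
vaccinated cases give an upper limit of 100%, zero control cases a point
estimate of $-\infty$, and zero cases overall an explicit "undefined" flag
rather than a fabricated number. `ve_from_vaccination_status()` is the
conventional model-based comparator (vaccination × subgroup Cox model, Wald
interval on the log hazard ratio).

## The synthetic-trial generator

`simulate_trial()` generates the structure the analyses assume: two arms
with arm-dependent normal biomarkers on the log2 scale (optionally
degenerate at 0 in the control arm, reproducing the fold-rise convention in
which placebo recipients are assigned a fold rise of 1), a binary baseline
covariate, event times drawn by inverse transform from
exponential-baseline proportional-hazards models per cause, independent
competing causes, exponential dropout, and administrative censoring. The
exponential baseline is a convenience — every estimator in the package
depends on hazard ratios only — and makes the inverse transform closed-form.

The defaults are the package's reference study conditions: 600 subjects per
arm, two-year horizon, a one-log2 mean immunogenicity advantage in the
vaccinated arm with unit standard deviation in both arms, hazard halving
per log2 unit ($\beta = \ln 0.5$), no direct vaccination effect (full
mediation, true VE 50%), baseline hazard $7\times10^{-5}$ per day and
dropout $5\times10^{-5}$ per day — yielding a few dozen cases per trial,
the regime where precision comparisons between case-counting and
model-based estimation are informative.

What the generator does *not* emulate: assay measurement error and
censoring of titers at the limit of detection, seasonal or otherwise
time-varying incidence, time-varying biomarker effects (non-proportional
hazards), within-subject biomarker trajectories, and informative dropout.
Tests passing on these simulations therefore validate the estimators under
their stated assumptions; they do not certify behaviour under assay
artefacts or non-proportional hazards, which is why the PH diagnostic is
part of the workflow.

## Numerical choices

* **Ties.** Efron's correction for Cox fits (day-granularity event times
  make ties likely in real trials); `cmprsk::crr` handles ties in the
  Breslow manner, so oracle-equivalence tests use tie-free data.
* **Convergence.** Partial-likelihood maximisation runs to a relative
  log-likelihood change below $10^{-10}$ with at most 50 iterations;
  monotone likelihood (risk separation) is flagged `converged = FALSE`
  with a warning, never returned silently.
* **Centering/scaling.** Sample standard deviation with the $n-1$
  denominator; constant columns are an error, not a silent zero-division.
* **Normality screen.** `compare_groups()` uses the Kolmogorov–Smirnov
  test with estimated moments, i.e. the Lilliefors correction
  (`nortest::lillie.test`); a naive KS test with plug-in moments is badly
  anti-conservative. Groups of exactly 3 observations (untestable) route
  to the rank test.
* **Complete cases.** Rows missing a required, covariate, or biomarker
  value are dropped on read and the count reported; no imputation.
* **Missing baseline titers.** A fold rise cannot be formed without a
  baseline, so such rows are incomplete cases (dropped and counted), not
  clamped.
* **Unknown-cause events** are a distinct competing cause code: they
  censor cause-specific fits of other causes, and the choice is visible in
  the data rather than hard-coded.
* **Degenerate inputs.** Empty arms, all-censored tables, absent cause
  codes, non-nested model pairs, and singular covariances all raise (or
  warn with a stated fallback) rather than propagate NaN.

## Test and verification sizes

The test suite validates each estimator against an independent oracle:
grid-scan maximisation of a hand-coded partial likelihood for `fit_cox()`
(instances of at most 8 subjects, grid step $10^{-4}$), a hand-coded
weighted pseudo-likelihood for `fit_fine_gray()` on two-cause data without
censoring, loop-arithmetic CIFs, and the closed-form `true_ve()` for the
end-to-end recovery. The stochastic checks use 100 trials of 1500/arm for
coefficient recovery, one 20000/arm trial for large-sample VE convergence,
200 trials with 200-replicate bootstraps for interval coverage, 500 null
trials of 150/arm for LRT and PH-diagnostic calibration, and 100
default-size trials for the precision comparison — sizes chosen so the full
suite runs in well under a minute of simulation time while leaving the
binomial acceptance bands meaningful.

## Limitations

The package estimates VE from a *time-fixed* biomarker measured at a
landmark visit; durability analyses with time-dependent biomarkers, models
with time-varying coefficients, stratified baselines, frailty terms, and
causal-mediation decompositions of the vaccine effect are out of scope.
The Prentice criterion is a screening test, not proof of mediation, and
its power limitations at high VE (few vaccinated cases) apply to any user
of this package.
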