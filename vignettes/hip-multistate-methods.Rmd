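---
title: "Interval-censored multi-state models for hip osteoarthritis panel data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-censored multi-state models for hip osteoarthritis panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipmsm)
```

## The model

`hipmsm` fits continuous-time Markov multi-state models to cohort panel
data on hip osteoarthritis (OA).  Five states are modeled per person:

* **A** — no radiographic hip OA (rHOA) and no hip symptoms,
* **B** — asymptomatic rHOA (Kellgren–Lawrence grade ≥ 2, no symptoms),
* **C** — hip symptoms only (pain/aching/stiffness on most days, no rHOA),
* **D** — symptomatic hip OA (rHOA plus symptoms in the same hip),
* **E** — death, an absorbing state.

Ten instantaneous transitions are allowed: development of rHOA
(A→B, C→D), development of symptoms (A→C, B→D), resolution of symptoms
(C→A, D→B), and death from each living state.  The diagonal moves A→D and
C→B are *not* allowed as single jumps — they were rare in the motivating
cohort and are parsimoniously explained as two jumps through an
intermediate state — but observed A/D or C/B panel pairs keep positive
probability through those multi-jump paths, so such records stay in the
likelihood.

Living states are observed only at study visits roughly six years apart:
the transition times are interval-censored, and the likelihood works with
transition *probabilities* over whole intervals rather than event times.
For a generator matrix $Q$ (off-diagonal entries $q_{rs} \ge 0$, rows
summing to zero) held constant over an interval of length $t$, the
transition probability matrix is $P(t) = e^{Qt}$.  Death times, by
contrast, come from registry linkage and are treated as exactly observed.

### Covariates and the age-65 changepoint

Each transition intensity follows a log-linear proportional-intensity
model,

$$ q_{rs}(z, a) \;=\; q^{0}_{rs}\,
   \exp\!\big(\beta_{rs}^\top z + \gamma_{rs}\, \mathbf 1[a \ge 65]\big), $$

so $e^{\beta}$ is the adjusted hazard ratio (aHR) of a covariate on that
transition and $e^{\gamma}$ a transition-specific multiplier that switches
on when the subject's *current* age crosses 65.  This coding was chosen
over fully separate parameter sets per age band: it is the equivalent
parameterization with fewer degenerate cells when a transition is rare in
one band.  The proportional (log-linear) form is forced by the fact that
effects are reported as per-transition hazard ratios; it is also the
standard multi-state convention.

Covariates are either static (baseline age, sex, race, education, cohort
membership, mean-centered birth year) or time-dependent (obesity,
diabetes, cardiovascular disease, hip injury), the latter assumed to
change only at observed visits: the value recorded at a visit is carried
forward across the following interval (LOCF).  A consequence worth
stating: perturbing the covariate recorded at the *end* of an interval
cannot change that interval's likelihood contribution, and the unit tests
assert exactly that.

On the time-scale question (study time versus age): because the
intensities depend on time only through the age-65 indicator and the
baseline-age covariate — never through study time itself — the two clocks
give the same model here, and no separate "age scale" switch is needed.
The changepoint age is an argument (`age_threshold`, default 65)
throughout.

### Likelihood

For consecutive visits at $t_0 < t_1$ with observed states $s_0, s_1$,
the contribution is $\log [\,\prod_j e^{Q_j \Delta_j}\,]_{s_0 s_1}$, the
product running over the (at most two) constant-intensity segments of the
interval — split at the instant the subject turns 65, half-open
convention $[65, \infty)$.  A death at exact time $t_d$ after a last
visit at $t_\ell$ in state $s_\ell$ contributes the density

$$ \sum_{k \in \{A,B,C,D\}}
   P_{s_\ell k}(t_\ell, t_d)\; q_{kE}(z, a_{t_d}), $$

survival in any living state times the instantaneous death intensity,
with covariates carried forward from the last visit.

Because vital status is ascertained by registry linkage for *everyone*,
not only for visit attendees, a subject known alive at the ascertainment
time $T$ with last visit at $t_\ell$ additionally contributes
$\log \sum_{k \in \{A,B,C,D\}} P_{s_\ell k}(t_\ell, T)$ — the
probability of still being in some living state.  This term is not
optional decoration: deaths occurring after the last visit enter the
likelihood as events, so the matching survival exposure of subjects who
*did not* die over the same span must enter too — omitting it counts the
events but not the person-time and biases every death intensity upward.
The panel schema carries this as an optional
`alive_until_years` column; with no vital-status follow-up recorded, the
likelihood reduces to the plain panel form, where right-censoring at the
last visit genuinely contributes nothing further.  Subjects with a single
time point and no death or vital-status record carry no information and
are dropped with a warning; records that are structurally impossible
(e.g. a B→A panel pair, unreachable in this structure) abort the fit with
a per-subject diagnostic rather than being dropped silently.

## Numerical choices

* **Matrix exponential.** The user-facing `transition_probability()` uses
  the scaling-and-squaring Padé algorithm (via `Matrix::expm`), which is
  accurate for the non-symmetric, possibly defective generators that
  arise here; eigendecomposition alone would not be.
* **Likelihood core.** Only one *row* of each $P$ is ever needed, so the
  C++ likelihood propagates a state row vector by uniformization,
  $vP = \sum_k \mathrm{Pois}(k; \Lambda t)\, v M^k$ with
  $M = I + Q/\Lambda$, truncated when the Poisson tail falls below
  $10^{-14}$; long or stiff segments are split so $\Lambda t \le 40$ per
  piece.  A test asserts agreement with the independent
  `Matrix::expm` route to $10^{-9}$ on simulated cohorts.
* **Gradient.** Exact, by reverse-mode differentiation of the
  uniformization recursion (an adjoint pass per interval), which makes
  the gradient cost a small multiple of one likelihood evaluation
  regardless of the parameter count.  A central-finite-difference check
  (relative error $< 10^{-3}$) is part of the test suite.
* **Optimization.** BFGS on the unconstrained working scale (log
  intensities, raw coefficients), then Newton/chord polishing on a
  central-difference Hessian (step $10^{-4}$) until the gradient
  max-norm is below $10^{-5}$; a fit reports `converged = TRUE` only
  past that gate.  The optimizer is seed-free and deterministic given
  data and initialization.
* **Initialization.** Crude rates: observed pair counts over person-time
  in the source state, with a floor of $10^{-3}$/year for empty cells;
  transitions with *no* supporting pairs are frozen at the floor (their
  covariate and changepoint coefficients are fixed at 0) and flagged,
  rather than estimated into degeneracy.
* **Uncertainty.** Wald 95% intervals on the log scale,
  $\exp(\hat\beta \pm 1.96\,\mathrm{SE})$, SE from the inverse observed
  information; "significant" means the 95% CI excludes 1, with no
  multiple-testing correction — both conventions follow the motivating
  analysis.

## The synthetic cohort generator

The motivating data (a community cohort of 3857 adults followed for up to
~18 years over four visits) are not publicly released, so the package
ships a generator that emulates the *structure* of such a cohort and
serves as the test bed for every other module.  Defaults are calibrated
once, to the published descriptive tables, and frozen:

* demographics: 33% African American, 39% men, 37% with < 12 years of
  education, 29% enrichment-cohort members, baseline age
  $\mathcal N(62.2, 9.8^2)$ truncated at 45;
* baseline states A/B/C/D = 45/19/25/11%;
* comorbidities: obesity 40% at baseline with per-visit onset 0.10 and
  remission 0.05 (reversible, drifting toward ~49%); diabetes 14% with
  onset 0.06 and CVD 22% with onset 0.125 (develop-only, roughly doubling
  by the third follow-up); hip injury 6%, absorbing, onset 0.02;
* visits: three follow-ups spaced $\mathcal N(6.0, 1.2^2)$ years
  (minimum 2), administrative horizon 19 years; per-visit dropout
  0.22/0.25/0.45, reproducing the observed attendance decline
  (≈ 3857/2300/1340/420);
* true intensities (per person-year, below 65, reference covariates):
  A→B 0.017, A→C 0.034, C→A 0.110, C→D 0.028, B→D 0.020, D→B 0.100,
  deaths 0.018–0.034; age-65 multipliers 1.3 (progression), 0.9
  (resolution), 1.8 (death); planted covariate effects taken from the
  published individually-modeled point estimates (e.g. obesity 1.33 on
  A→C).  The development/resolution pairs (A→C vs C→A, and the
  death-adjacent rates) were chosen so that about 26% of subjects
  starting in state A are observed transitioning to a living OA state
  over full follow-up and the per-visit state mix drifts as published;
  matching the near-balanced development/resolution pair counts forces
  the resolution rates (C→A, D→B) well above the development rates,
  because state C holds a much smaller pool than state A.

Simulation is exact (competing exponential sojourns within each
constant-intensity segment), not discretized.  Two deliberate design
choices: (i) comorbidity paths advance at the visits a subject actually
attends, so the carried-forward covariate model *is* the generating
model and parameter-recovery studies test the estimator rather than a
misspecification; (ii) death is ascertained up to the administrative
horizon regardless of dropout, emulating registry linkage.  What the
generator does **not** emulate: radiographic measurement error and grade
misclassification, hip-level (as opposed to person-level) processes,
informative dropout, and total-hip-replacement events.  Tests passing on
these cohorts therefore demonstrate correctness of the estimator under
the stated model, not robustness to those real-data features.

## Validation and the scales used

The acceptance-grade checks (in `tests/testthat/test-acceptance.R` and
recomputed by `scripts/acceptance.R`) are property-based, since the
original cohort is unavailable:

1. matrix-exponential probabilities agree with a Kolmogorov-forward ODE
   oracle to $10^{-8}$ over 100 random generators, $dt \in [0.1, 20]$;
2. closed forms: $P(0) = I$, two-state survival to $10^{-12}$, the
   semigroup property to $10^{-9}$;
3. interval pair probabilities and exact-death window probabilities
   (the integrated `death_loglik` density) agree with $10^6$-chain exact
   simulations within 3 Monte-Carlo SEs, for 10 random parameter sets;
4. a planted obesity log-HR of $\ln 1.33$ on A→C is recovered across 100
   cohorts of $n = 2000$ with mean bias $< 0.05$ and Wald coverage in
   $[0.90, 0.98]$; separately, mean baseline-intensity relative bias is
   $< 10\%$ across all ten transitions over 40 cohorts of $n = 4000$
   (the larger size matters on the intensity scale: the pre-65 baseline
   rates are weakly identified in a cohort entering around age 62, and
   $e^{\hat\theta}$ carries a finite-sample convexity term
   $\approx e^{\sigma^2/2}$ that only the larger cohorts make
   negligible);
5. with all comorbidity effects planted at HR 1 (12 cohorts at the
   study's own $n = 3857$, individual joint model), the share of 95% CIs
   excluding 1 is binomially consistent with 5% at $\alpha = 0.01$;
6. the seeded generate→analyze pipeline (on a dropout-free cohort; see
   below) yields a complete bundle whose count columns match an
   independent brute-force tally exactly and whose truth-expected
   prevalence curves track the observed ones within binomial noise;
7. identical (config, seed) reproduces cohorts byte-identically and fits
   to $10^{-8}$.

The replicate counts and cohort sizes above (and the smaller ones used in
the ordinary unit tests) are the package's chosen simulation scales; the
statistical thresholds come from the corresponding binomial or normal
sampling distributions at those scales.  The analysis drivers under
`analysis/` run the full suite at the study's own scale, $n = 3857$.

### A caveat on the prevalence convention

The observed-prevalence denominator removes subjects who are past their
last visit and not known dead, while registry deaths always count in E.
Under heavy dropout this convention is *not* self-consistent: alive
dropouts carry model death-probability mass that leaves the expected
curve but their eventual observed deaths still enter the observed one,
so the expected death share sits systematically below the observed share
even at the generating truth.  The assessment is qualitative, as
intended; the quantitative self-consistency checks therefore run on
dropout-free cohorts, where the convention is exact.

## Known limitations

* The Markov assumption: future transitions depend only on the current
  state; sojourn-time (semi-Markov) effects and hidden-state
  misclassification are out of scope.
* Exactly one time-inhomogeneity band boundary (the age threshold) is
  supported, matching the analysis design; more general piecewise bands
  are not.
* Wald intervals can be poorly calibrated for transitions with very few
  events; the engine freezes empty cells but does not profile sparse
  ones.  Bootstrap or profile-likelihood intervals are not provided.
* Dropout is assumed non-informative; the sensitivity analysis
  (restriction to subjects with ≥ 2 follow-ups) probes, but cannot prove,
  robustness to it.

## A worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n_subjects = 800, seed = 1)
coh <- generate_cohort(cfg)
cv <- msm_covariates(c("obesity", "dm", "cvd", "age0_c", "male"),
                     mask = "living")
fit <- fit_msm(coh, covariates = cv)
hazard_ratio_table(fit, "obesity", cohort = coh)
plot_prevalence(prevalence_curves(fit, coh))
```
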