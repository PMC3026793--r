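---
title: "Single-case abnormality scores and phenotypic subtyping for recognition-memory cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-case abnormality scores and phenotypic subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Case-control studies of congenital prosopagnosia (CP) ask two questions
that ordinary group statistics answer badly. First, *which individual*
cases are impaired on which test, relative to what a control with the same
age and covariates would be expected to score — a single-case question
posed against a small control sample. Second, whether the individual
deficit profiles, assembled across a battery of perceptual, associative
and mnestic (memory) tests, fall into coherent phenotypic subtypes rather
than varying idiosyncratically.

cpmem implements the full chain: a generative simulator for trial-level
recognition cohorts, signal-detection scoring, binomial logistic
mixed-model (GLMM) inference, leave-one-out single-case abnormality
z-scores with modified t-test deficit calls, nonparametric group tests,
and complete-linkage clustering of deficit profiles. Because raw
participant data from such studies are typically not public, the simulator
is a first-class, tested component: every downstream stage is exercised on
cohorts whose true generative structure is known.

## The generative model

A participant $i$ with covariates $x_{ij}$ on trial $j$ responds correctly
with probability

$$\Pr(y_{ij} = 1 \mid b_i) = \mathrm{logit}^{-1}\!\left(x_{ij}^\top \beta + z_{ij}^\top b_i\right),
\qquad b_i \sim \mathcal{N}(0, \Sigma),$$

with fixed effects for age (centred at 37.3 years), trial type (target vs
distractor), image rotation, case status, and case-by-condition
interactions; $b_i$ is a per-participant random intercept, optionally with
a random slope on trial type (used for the object-recognition experiment,
where the influence of trial type varies across participants).

The default study design mirrors a one-year recognition-memory test: two
parts of $8 \times (4 + 16) = 160$ presentations each, part one rotated
and part two frontal, four illumination labels on target trials of which
one matches the familiarisation condition. Defaults for the case effects
are the published posterior estimates for this paradigm (faces:
$\beta_{CP} = -1.04$, $\beta_{CP\times trial} = -1.63$,
$\beta_{CP\times rotation} = 0.31$; shoes: $\beta_{CP} = -0.40$;
famous-face recall: $\beta_{CP} = -0.67$ with media-consumption
interactions $-0.12$ and $-0.30$).

Choices the data could not pin down, made once and kept:

* **Ages** are truncated normal, mean 37.3, sd 17.9, support [18, 80] —
  consistent with the printed cohort range (20–68) and summary moments.
* **Gender and media-consumption bands** are categorical draws with
  configurable probabilities, uniform by default; no distribution is
  reported for them.
* **Baseline accuracy**: the control intercept is 3.0 logits, which
  yields a mean control error rate near 7%, matching the printed control
  median of 6.3%; the condition effects (−0.5 trial type, −0.6 rotation,
  −0.015/year age) spread cell accuracies over a plausible 85–95% band.
* **Latent heterogeneity**: the random-intercept sd is 0.5 logits, which
  spreads control error rates over roughly 2–12% — the kind of
  several-fold spread such cohorts show.
* **Questionnaire**: 15 items rated 1–5; case totals are tied to the
  participant's latent ability through a Gaussian copula (default
  $\rho = 0.6$) so that self-assessment correlates negatively with
  measured performance, qualitatively reproducing the published
  questionnaire-versus-deficit correlation.
* **Randomization**: schedules are unconstrained permutations (no
  constraint against immediate stimulus repeats is reported, so none is
  imposed), with every stimulus appearing exactly `repetitionsPerPart`
  times per part.

What the simulator does *not* emulate: compensatory strategies that make
real CP performance non-stationary across a session, serial position or
fatigue effects, stimulus-level difficulty variation (no crossed random
effect for stimuli), and reaction-time generation. Passing tests on
simulated cohorts therefore demonstrate that the *statistical machinery*
is correct and calibrated under the stated model, not that the model
captures every feature of real data.

## Model fitting

`fitGlmm()` maximises the Laplace-approximated marginal likelihood of the
binomial logit GLMM. The implementation is built for the workload this
pipeline creates — the leave-one-out procedure refits the control model
once per control, and the calibration studies repeat that thousands of
times — so the random-effect modes are solved by a damped Newton iteration
vectorised over participants, the Laplace objective has an analytic
gradient, and warm refits reuse the Hessian of a reference fit as a fixed
quasi-Newton metric. Trial-level tables are aggregated to binomial counts
per participant and covariate cell first, which leaves the likelihood
unchanged and makes each refit take milliseconds. Models without random
terms (the famous-face recall model) are fitted by IRLS via `stats::glm`.
The test suite verifies agreement with `lme4::glmer` (coefficients,
random-effect sd and log-likelihood) on shared data for both the
random-intercept and the intercept-plus-slope models.

Nested models are compared with `lrTest()` by the deviance difference
against a $\chi^2$ reference with degrees of freedom equal to the
parameter-count difference. For fixed effects in mixed models this
reference is known to be slightly liberal; the package therefore follows
the practice of reporting Bayesian posterior summaries for selected
(interaction) effects alongside. `posteriorSummary()` samples the joint
posterior by adaptive random-walk Metropolis-within-Gibbs — a multivariate
normal block proposal for the fixed effects shaped by the Laplace
covariance, vectorised participant-wise random-effect updates, and a
conjugate inverse-Wishart Gibbs draw for the random-effect (co)variance —
under the stated priors: fixed effects $\mathcal{N}(0, 10^{10})$,
random-effect variance inverse Wishart with one degree of freedom and
inverse scale equal to the unconditional response variance. Posterior
modes are kernel-density peaks of the marginal chains; intervals are
shortest 95% sample intervals (HPDI). Convergence is monitored by the
split-chain $\widehat{R}$ (threshold 1.05) and checked in the tests by a
Bernstein–von Mises comparison of posterior mode and Laplace MLE.

## Abnormality scores

Expected performance for a participant is the trial-weighted mean of
marginal predicted probabilities, where marginalisation over the random
effects uses 20-point Gauss–Hermite quadrature (conditioning the
prediction at $b = 0$ is available as an option; it is *not* the default
because observed proportions are marginal quantities and the inverse logit
is nonlinear). A participant's residual is observed minus expected
proportion correct — the response scale, matching how performance
differences are reported in this literature.

Cases are scored against the control model fitted on all controls.
Controls are scored against *individualized* models: for control $i$ the
model is refitted on all controls except $i$, and $i$'s residual is taken
under that fit. This leave-one-out step removes in-sample optimism — with
a plug-in fit each control's idiosyncrasies leak into its own expectation
and the control residual variance underestimates what a genuinely new
participant would show; the tests verify both that LOO residuals are mean
zero and that their variance exceeds the plug-in variance.

Residuals become z-scores by centring and scaling with the control
residual mean and sd. The *unconditional* control variance is used
deliberately (not a variance conditional on the covariate values as in the
classical single-case regression approach): the priority here is
comparability of one individual's scores across many tests, at the cost of
slightly exaggerated abnormality for participants with unusual covariates.
Category aggregates (perceptual, associative, mnestic, faces-total,
shoes-total, overall) are means of available member z-scores,
re-standardized against the control distribution of that mean; the
membership map is configurable because the exact aggregate composition is
a reporting-layout convention. Direction-reversed external measures
(reaction times, presentation-time thresholds) are sign-flipped at
ingestion so worse performance is negative everywhere.

A score is called a deficit when it falls below the one-sided 5% cutoff of
the modified t-test, $t = z/\sqrt{(n+1)/n}$ with $n-1$ degrees of freedom
for $n$ controls — the finite-control-sample correction for comparing one
case with a small normative sample. Only the deficit direction is tested
(supra-normal performance is not flagged), and no multiplicity correction
is applied across the battery, matching the reporting convention the
package reproduces.

### Calibration, and a known limitation

`deficitFalsePositiveRate()` measures the classifier's type-I error by
simulating null cohorts (controls only), holding one control-like
participant out, and running the full score-and-test chain on it. Under
the default generative conditions the measured rate sits reproducibly
*above* the nominal 5% — typically between 6 and 7% over 2000
replicates. The mechanism is distributional rather than an
implementation artifact, and it weakens as the latent heterogeneity
shrinks: accuracy proportions near ceiling are
left-skewed — a normal latent effect passed through the inverse logit
compresses the upper tail and stretches the lower one — so a one-sided
lower-tail t cutoff catches more than 5% of healthy controls. Working on
the link (logit) scale would largely restore normality and calibration,
but response-scale residuals are kept as the default because that is the
scale on which performance differences are defined and reported in this
setting. Users should read the 5% cutoff as approximate for
near-ceiling binomial scores, and expect the modified t-test to be
mildly anti-conservative there.

## Group comparisons and subtyping

Group differences in error rate, d′ and residuals use the Wilcoxon
rank-sum test (exact by enumeration for small tie-free samples, normal
approximation with continuity and tie corrections otherwise; the reported
`W` is the Mann–Whitney U of the first sample). d′ is
$\Phi^{-1}(H) - \Phi^{-1}(F)$ with extreme rates corrected by the
$1/(2N)$ rule by default (a log-linear rule is selectable); no single
correction is canonical in this literature, and both are standard
signal-detection practice.
The self-assessment correlation uses Spearman's $\rho$ (the published
symbol; Pearson is available as an option).

Subtyping clusters participants by their aggregate z-score profiles:
Euclidean distance over the columns both participants completed, rescaled
by $\sqrt{K/K_{shared}}$ so incomplete pairs are on the same scale
(the rescaled distances may violate the triangle inequality, which
complete linkage tolerates), followed by complete-linkage agglomeration.
The cluster count is not fixed — the dendrogram is the result — but a
k-cut is available, and the recovery test plants three archetypes
(a perceptual→associative→mnestic cascade, a mnestic-only deficit, and a
combined face-and-object deficit) and requires the 3-cut to recover them.

## Numerical choices

* Inner Newton for random-effect modes: gradient tolerance $10^{-10}$
  with step halving; outer `nlminb` relative tolerance $10^{-11}$;
  terminations labelled "false/singular convergence" are accepted only
  when the gradient is small on the likelihood scale.
* Leave-one-out refits: fixed-metric Newton warm-started at the
  all-controls optimum, falling back to the full optimizer when the
  gradient criterion is not met within 40 steps; fold non-convergence is
  reported per fold, never silent.
* MCMC: 1500 adaptation iterations (proposal scale tuned to a 23.4%
  acceptance target), 4000 kept samples by default, seeded and
  reproducible.
* Ties in clustering are broken deterministically by the stable
  participant ordering; identical seeds reproduce identical pipelines
  byte for byte.
* Degenerate inputs fail loudly: zero control residual variance, empty
  samples, constant correlation inputs, participants sharing no profile
  columns, aggregates with no members.

## Problem sizes used by the packaged studies

The calibration and recovery studies are sized to run on a desk machine:
2000 replicates for the single-case false-positive rate (25 controls
each), 500 null fits for the LR-test type-I error, 100 cohorts at the
study's design size (25 controls, 13 cases, 320 trials per participant
per experiment) for effect recovery, and 100 replicates of the planted
three-archetype recovery. The simulation loops draw responses at the
binomial-cell level, which is distributionally identical to drawing every
trial (the cells are complete sufficient statistics) and keeps a full
calibration run in minutes.

## Limitations

* The modified t-test's mild anti-conservatism near ceiling, above.
* No stimulus-level (crossed) random effects: the paradigm reuses the
  same 20 stimuli for everyone, so stimulus difficulty is absorbed into
  the condition means.
* The Bayesian sampler targets the stated weakly-informative priors only;
  it is not a general-purpose GLMM sampler.
* External short-term test columns are ingested as given (already
  standardized elsewhere) and only re-anchored to the control rows; their
  internal models are out of scope.
* Media-consumption bands enter the famous-face model as ordinal numerics
  1–4 by default (categorical coding is available), since the band
  spacing is roughly log-hours and the data cannot distinguish the two.
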