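---
title: "Modelling ultimatum-game responders with a drift-diffusion model"
author: "ugddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ultimatum-game responders with a drift-diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The task and the data

A responder in the ultimatum game sees a proposed split of a ¥500 pie —
self-reward SR for themselves, other-reward OR for the proposer — and has
10 s to accept or reject. The task uses seven base splits, labelled by their
SR:OR ratio (7/3, 3/2, 1/1, 2/3, 3/7, 1/4, 1/9, i.e. ¥350–150 down to
¥50–450), each perturbed on every trial by independent jitter of up to ±¥25
and presented 8 times, for 56 trials per run. Trials without a response
inside the deadline are kept in the data files but excluded from every
likelihood, mirroring how error trials are handled in practice.

A trial table is a plain CSV with columns `participant_id`, `trial_index`,
`sr_yen`, `or_yen`, `choice` (`accept`/`reject`/`timeout`) and `rt_s`;
`read_trials()` validates it row by row (response times must lie in (0, 10]
seconds for decided trials) and infers the base condition of each offer.

Two inequity regressors are derived per trial,

\[
\mathrm{DI}_t = \max(\mathrm{OR}_t - \mathrm{SR}_t,\, 0), \qquad
\mathrm{AI}_t = \max(\mathrm{SR}_t - \mathrm{OR}_t,\, 0),
\]

so exactly one of the two is positive on any unequal offer, and
\(\mathrm{DI}_t - \mathrm{AI}_t = \mathrm{OR}_t - \mathrm{SR}_t\) always.
`design_diagnostics()` reports variance inflation factors and the regressor
correlation matrix; SR and DI are strongly (negatively) correlated by
construction of the task, which matters later for interpreting fitted
coefficients.

### Monetary scale

Regressors enter the model in units of ¥100 (`scale_yen = 100`), so SR spans
roughly 0.25–3.75 model units. This puts plausible drift coefficients well
inside the uniform (−3, 3) prior support — on a raw-yen scale the same
behavior would need coefficients of order 10^-2 at the edge of numerical
comfort, and published group means (e.g. a self-reward weight near −0.9)
only make sense on the ¥100 scale. The scale is an explicit argument
everywhere, never an implicit constant.

## The decision model

Evidence accumulates as a Wiener process with unit diffusion between an
accept boundary at 0 and a reject boundary at \(\alpha > 0\) (rejection is
the *upper* boundary throughout), starting at \(z\alpha\) with
\(z \in (0,1)\). The drift rate is linear in the task regressors,

\[
\delta_t = \sum_{X \in S} \beta(X)\, X_t ,
\]

for a regressor subset \(S\), or a free constant for the constant-only
model. Response time is first-passage time plus a nondecision time
\(\tau\) (stimulus encoding and motor execution). The trial likelihood is
the exact first-passage-time density at the observed boundary and time.

Nine drift specifications are admissible: SR, AI, DI, SR+AI, SR+DI, AI+DI,
SR+OR, SR+AI+DI, and constant-only (`drift_specs()`). Because
OR = SR + DI − AI exactly, the SR+OR model spans the same drift space as an
SR + (DI−AI) model; separating DI from AI is exactly what distinguishes the
full model from it.

### Numerical evaluation of the likelihood

The first-passage density is computed by the classic dual series: a
small-time image sum and a large-time eigenfunction expansion, choosing per
evaluation whichever needs fewer terms at truncation tolerance `eps = 1e-7`.
Densities at \(t \le \tau\) are zero (log-density −Inf). The upper-boundary
density is obtained from the lower-boundary form under the reflection
\((v, w) \to (-v, 1-w)\). Two closed forms complement the density: the
absorption probability at the rejection boundary,

\[
P(\text{reject}) = \frac{1 - e^{-2 v \alpha z}}{1 - e^{-2 v \alpha}}
\quad (v \neq 0), \qquad P = z \ \ (v = 0),
\]

computed through `expm1` with a mirrored branch for negative drift to avoid
catastrophic cancellation, and the unconditional mean decision time
\(E[T] = (\alpha P - z\alpha)/v\) (limit \(\alpha^2 z (1-z)\) at zero
drift). The tests verify that upper + lower densities integrate to 1 within
1e-6 over a 27-point parameter grid, that the closed-form probability
matches the density integral within 1e-5, and that a 10^5-path simulation
agrees with both.

### Simulation

`simulate_trial()`/`simulate_dataset()` use Euler–Maruyama with step
`dt = 1e-4` s; trials whose nondecision + first-passage time would exceed
the 10-s deadline are censored as timeouts. At this step size the
discretization bias is below Monte-Carlo noise at the sample sizes used in
the tests (Kolmogorov distance to the analytic density < 0.01 at 10^5
paths). Each trial is seeded from (seed, trial index), so a simulated
dataset is reproducible and individual trials do not depend on their
neighbours' path lengths.

## Inference

Priors follow the analysis the package reimplements: half-normal(σ = 2) on
\(\alpha\) and \(\tau\), uniform(0, 1) on \(z\), uniform(−3, 3) on every
drift coefficient. Sampling is adaptive Metropolis-within-Gibbs over the
3 + |S| parameters: Gaussian random-walk proposals per parameter, scales
adapted toward 0.44 acceptance during burn-in only (Robbins-Monro), so the
retained draws come from a fixed-kernel Markov chain. During sampling
\(\tau\) is additionally restricted to \((0,\, 0.99 \cdot \min \mathrm{rt})\):
the likelihood is identically zero for \(\tau \ge \min \mathrm{rt}\), and
the restriction keeps chains off that plateau. Chains initialize from
overdispersed uniform draws, re-drawing (up to 200 times) until the
posterior is finite.

Defaults are 4 chains, 2 000 burn-in and 2 000 retained draws — a
deliberate scale-down of the original setting (4 chains, 15 000 burn-in,
5 000 draws), which remains available through the arguments. On 56-trial
datasets the scaled-down setting converges comfortably (split-chain R-hat
typically below 1.05; the conventional threshold is 1.1, checked by
`gelman_rubin()`, which also reports an effective sample size from Geyer's
initial positive sequence). The point-estimate convention everywhere
downstream is the posterior mean (`posterior_means()`).

Fits are per participant and independent. The toolbox family this analysis
descends from advertises approximate *hierarchical* inference without
specifying the group structure used; independent fits are the transparent
choice, are what the per-participant Table-2-style summaries assume, and
keep every downstream quantity (WAIC sums, recovery, cross-validation)
well-defined per participant. A hierarchical extension would be a
straightforward layer on top of the same likelihood but is deliberately out
of scope.

## Model comparison

`waic()` computes the trial-wise widely applicable information criterion
from the stored per-trial log-likelihood draws:
\(\mathrm{lppd} = \sum_t \log \frac1D \sum_d e^{\ell_{td}}\) (log-sum-exp
stabilized), the variance-form penalty
\(p_\mathrm{waic} = \sum_t \mathrm{Var}_d(\ell_{td})\), and
\(\mathrm{WAIC} = -2(\mathrm{lppd} - p_\mathrm{waic})\) on the deviance
scale, matching the magnitude convention of the published totals.
`run_selection()` fits all nine specifications to every participant, sums
WAIC over trials and participants, and declares the smallest total best; a
failed cell degrades to NA rather than aborting the run. On synthetic
cohorts generated from the SR+AI+DI model, selection recovers the
generating specification in at least 8 of 10 replicate 20-participant
cohorts at reduced sampler settings (3 chains, 400 + 400).

The value-based alternative is a logistic model of choice:
\(v(t) = \gamma_0 (g_{t,\text{reject}} - g_{t,\text{accept}}) +
\gamma_{AI}\mathrm{AI}_t + \gamma_{DI}\mathrm{DI}_t\) with
\(g_{t,\text{reject}} = 0\), \(g_{t,\text{accept}} = \mathrm{SR}_t\), and
\(P(\text{reject}) = 1/(1+e^{-v})\). It is estimated by Firth-penalized
(bias-reduced) likelihood — Newton scoring with the hat-value-adjusted
score and step-halving — so estimates stay finite under the complete
separation that small ultimatum datasets routinely produce (participants
who accept everything). `compare_choice_only()` scores both families on the
Bernoulli likelihood of choices alone via WAIC; the logistic side gets wide
normal(0, 10²) coefficient priors sampled by random-walk Metropolis. When
response times are pure noise, the logistic fit is never worse — choices
alone are its native territory — which is exactly the comparison's point.

## Validation battery

* **Parameter recovery** (`parameter_recovery()`): simulate 56 trials from a
  known agent (fresh jittered offers each repeat), refit, record posterior
  means; report bias and RMSE. Canonical agents: a *reward seeker*
  (\(\beta(SR) = -1.5\), inequity weights 0) and an *inequity avoider*
  (\(\beta(DI) = 1.0, \beta(AI) = 0.5, \beta(SR) = -0.5\)), both with
  \(\alpha = 2, z = 0.5, \tau = 0.5\) s — configuration values, not claims
  about any real cohort. Default 20 repeats (the full-scale experiment uses
  100). Truths beyond the ±3 prior support are recovered saturated near the
  bound, as they must be.
* **Response-time cross-validation** (`loo_cv_rt()`): 8 folds, one held-out
  trial per condition per fold; refit on the remaining 49 trials; predict
  the held-out response time as posterior-mean \(\tau\) plus the analytic
  mean decision time at the held-out offer's drift. The analytic predictor
  is deterministic and testable; a simulation-based posterior-predictive
  draw would add Monte-Carlo noise without changing the comparison.
  Pearson correlations per condition are Holm-adjusted over the 7
  conditions.
* **Posterior-predictive simulation** (`posterior_predictive()`): simulate
  behavior from per-participant (posterior-mean) parameters over a common
  offer set and tabulate per-condition rejection rates and choice-wise mean
  response times in the same shape as the observed tables.

## The synthetic cohort generator

`make_cohort()` draws each agent's parameters from independent truncated
normals anchored at the published group-level estimates (boundary
2.16 ± 0.680, bias 0.543 ± 0.0962, nondecision time 0.591 ± 0.266 s,
β(SR) −0.930 ± 0.504, β(DI) 0.371 ± 0.481, β(AI) 0.254 ± 0.868), truncated
to valid supports, and simulates a fresh 56-trial run per agent. A
configurable fraction of "all-accept-like" agents (β(DI) ≈ 0, strongly
negative β(SR)) emulates the sizeable minority of responders who accept
every offer; the default fraction is 0 so that the base generator is purely
the published moments. The truncated-normal family and the independence of
draws are modelling choices — only the marginal means/SDs are published.

Cohorts generated this way reproduce the group-level behavioral structure
the analysis pipeline must detect: rejection rising monotonically with
disadvantageous inequity (about 70 % rejection of 1/9 offers versus about
17 % of 2/3 offers at the anchor moments), near-universal acceptance of
advantageous offers, slower acceptances than rejections for strongly
disadvantageous offers (and the reverse for advantageous ones — both are
mixture effects of a bias z slightly toward rejection plus heterogeneous
drifts), and a strong positive correlation between an agent's β(DI) and its
rejection rate, recoverable end-to-end through fitting.

### What the generator does not emulate

Independent draws carry no correlation *between* parameters across agents.
Consequences worth knowing: the observed negative correlation between
β(SR) estimates and rejection rates in real cohorts cannot arise here — under
independence, raising β(SR) toward zero weakens the accept drive and
mechanically *raises* rejection, so the synthetic correlation is positive.
The empirical negative sign implies coupling among participants' parameters
(e.g. overall drift-gain differences inducing a strong negative
β(SR)–β(DI) correlation) that is not derivable from published marginal
moments. Tests that assert the real cohort's full sign pattern on synthetic
cohorts therefore fail on exactly that panel, and this is informative, not
a defect: passing tests on this generator demonstrate the pipeline's
mechanics, not the joint parameter distribution of any real population.
Similarly, real response-time data contain contaminants (lapses, fast
guesses) and possible trial-to-trial parameter variability that the plain
four-parameter model deliberately omits.

## Problem sizes and runtime choices

The package's own test battery uses: a 27-point parameter grid for density
normalization; 10^5 simulated paths for simulator-vs-density agreement;
20 repeats × 56 trials for recovery (with 4 × 800 + 800 sampling);
10 replicate cohorts × 20 participants × 9 specifications at 3 × 400 + 400
for selection recovery; and 63-participant cohorts for behavioral pattern
checks — sizes chosen so the full battery runs on a single CPU in minutes
while keeping Monte-Carlo error well below every asserted margin.

## Known limitations

* Plain four-parameter Wiener model: no collapsing bounds, no
  trial-to-trial variability parameters, no contaminant mixture.
* Independent per-participant fits; no partial pooling.
* Euler simulation has O(√dt) boundary-overshoot bias; at dt = 1e-4 s this
  is negligible for the tested regimes, but very small boundaries with very
  large drifts would warrant a smaller step.
* The Firth-vs-ML bias comparison and all recovery statements are
  statements about 56-trial ultimatum designs, not general claims.
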