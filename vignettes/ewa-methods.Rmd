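---
title: "Methods: hierarchical EWA models of social learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical EWA models of social learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ewalearn)
```

This vignette documents the modelling choices in `ewalearn`: the forward
learning model, the construction of social information from attendance
records, the hierarchical Bayesian machinery, the synthetic-data generator,
and the numerical decisions that a careful reader will want stated
explicitly.

## The forward model

Each individual *j* carries an attraction score A_ij for every technique
*i*, initialised at 0 for all techniques. After a bout with realised payoff
π ∈ {0, 1} (success/failure of the manipulation), only the chosen
technique's attraction is updated:

A_ij,t+1 = (1 − φ_j) A_ij,t + φ_j π_ij,t.

Two conventions here are genuinely open and were fixed as follows:

* **Initial attractions are 0** for all techniques, so a naive animal's
  first asocial choice is uniform under any λ. This is the natural
  symmetry for subjects that have never seen the task.
* **Only the experienced technique updates.** The update rule indexes the
  payoff actually received; unchosen techniques retain their scores rather
  than decaying towards zero. The alternative (decaying all techniques
  every bout) changes the meaning of φ and is not implemented.

Asocial choice is a multinomial logit over attractions with sensitivity
λ_j ≥ 0 (λ = 0 gives uniform choice), computed with max-subtraction so that
large λ·A cannot overflow. No ceiling is imposed on λ beyond prior
regularisation.

Social choice weighs each technique by N^{f_c} exp(B), where N counts
attended demonstrations of the technique in the cue window and B is a
linear combination of windowed cue means. A technique never observed in
the window has weight exactly 0 (0^{f_c} = 0 for f_c > 0). When *nothing*
was observed in the window the social kernel is a 0/0 and is treated as
undefined: the bout is modelled as a purely individual choice rather than
dropped, which keeps the pointwise log-likelihood comparable across model
specs whose social kernels would otherwise lose different event subsets.

The final choice probability is the convex combination
(1 − γ_j) I + γ_j S with γ_j ∈ [0, 1].

Model variants: the single-bias specs (`payoff_bias`, `rank_bias`,
`kin_bias`, `female_bias`, `sex_bias`) activate exactly one cue
coefficient and fix f_c = 1, so their social kernels are proportional
imitation tilted by one cue; `freq_dep` frees f_c with no trait cues; the
`global` spec frees f_c and all five coefficients.

## Social-cue windows

For every choice, social information is computed from the events the actor
attended in the half-open interval [t − W, t) of the *same session*, with
W = 20 minutes by default and 5/10/30 supported for robustness checks.
Decisions:

* **Half-open window.** An event at exactly *t* (in particular the focal
  event itself) can never inform the choice at *t* — causality.
* **Within-session only.** Sessions are separated by hours or days in the
  field design, so a minutes-scale window never spans sessions; times are
  stored as minutes from session start.
* **Own events are excluded by default.** An individual's own past
  manipulations influence it through its attractions; counting them again
  as "social" information would double-count personal experience. Since
  the original analysis does not state this convention, it is configurable
  (`cue_window_config(include_own_events = TRUE)`).
* **Cue scales.** Cues enter on their natural scales — rank and
  relatedness in [0, 1], success and demonstrator-class indicators as 0/1
  — without centring or standardisation, matching their literal
  definitions. The "female-bias" cue counts only *adult* female
  demonstrators.
* **Observed payoff is the binary outcome** of the attended event, so the
  per-technique payoff cue is the windowed success proportion of that
  technique.

## Hierarchical inference

Parameters are estimated on link scales chosen to enforce their domains:
log for λ and f_c, logit for φ and γ, identity for the β coefficients. The
linear predictor of each parameter for individual *j* is

population mean + juvenile offset + male offset + individual effect +
group effect,

with adult females the reference cell. Infants are merged into the
juvenile class at load time (the raw age string is preserved). Reported
age-class summaries marginalise over the empirical sex distribution of
that class and vice versa; four free age-by-sex cells per parameter would
not be identifiable alongside individual and group effects at typical
sample sizes.

Individual and group varying effects are non-centred: each block is
σ ⊙ (L z) with z standard normal, σ given unit-rate exponential priors,
and L the Cholesky factor of a correlation matrix with an LKJ(4) prior.
All of a spec's hierarchical parameters are correlated within each block;
the triangular factorisation is over the unconstrained
partial-correlation transform. Population means and offsets have standard
normal priors on the link scale — regularising priors sceptical of
extreme effects.

**Group effects require at least two groups.** With a single group the
group effect is exactly confounded with the population mean (the data
constrain only their sum, and the scale parameter inflates to absorb the
ridge), so single-group designs are fitted without the group level. Joint
fits of two or more groups estimate it, as in the two-group field design.

### The sampler

The posterior is sampled by an adaptive Metropolis-within-Gibbs scheme
implemented in C++:

* scalar random-walk updates for each population mean, offset and log
  scale (target acceptance 0.44, Robbins–Monro adaptation during warmup);
* block updates for each individual's varying-effect vector — these touch
  only that individual's events, since the likelihood factorises over
  individuals — and for each group's vector and each correlation block
  (target 0.25);
* **interweaving (ancillarity–sufficiency) moves** that translate mass
  between a population mean and the corresponding varying effects, and
  between a log-scale and its effects, while keeping every linear
  predictor fixed. These moves cost no likelihood evaluation (only the
  priors and, for the scale moves, an analytic Jacobian enter the
  acceptance ratio) and are what make the mean/varying-effect ridge and
  the scale funnel mix acceptably for a random-walk sampler.

Chains are initialised at a maximum a posteriori fit of the homogeneous
(no-varying-effects) model plus jitter, with bounded re-initialisation if
the posterior is not finite at the start. Runs are exactly reproducible
under a fixed seed and chain count. Convergence is monitored by split-R̂
and an autocorrelation-based effective sample size per parameter, plus
mean acceptance rates; there is no divergence diagnostic because the
sampler is not gradient-based. Pointwise log-likelihoods are stored per
retained draw for WAIC.

Default runs use 4 chains × 1000 post-warmup draws; the package's own
test suite uses 2 chains × 500 draws after 1000 warmup iterations at a
problem size of one 30-animal group and roughly 2000 events, which keeps a
full parameter-recovery study (five simulated worlds, two fits each) in
the minutes range on one CPU.

## Model comparison and prediction

WAIC is computed on the deviance scale, −2(lppd − p_WAIC), with
p_WAIC = Σ_e var_draws(log-likelihood) and the pointwise-variance standard
error √(n · var_e(−2 elpd_e)); paired standard errors of WAIC differences
are not reported. Comparison weights are exp(−ΔWAIC/2), normalised.
Models are only comparable when fitted to identical event sets; the
comparison refuses mismatched event counts.

The HPDI of a draw vector is the narrowest contiguous interval of sorted
draws containing ⌈mass·n⌉ draws (default mass 0.89), ties broken towards
the lowest lower bound.

Posterior predictions are one-step-ahead by default: for each retained
draw the forward model is replayed along each individual's *observed*
sequence (attractions updated with realised outcomes, cues as observed),
and per-bout technique probabilities are aggregated to population-daily,
individual-daily or per-bout resolution with raw daily frequencies for
overlay. A free-running mode (choices sampled from the model, payoffs
drawn from empirical success rates) is available behind a flag for
visualising model-implied trajectories; it is an approximation, since the
true payoff process of unchosen counterfactual techniques is unobserved.

## The synthetic-data generator

`simulate_diffusion()` is the package's ground-truth machine. It emulates
the statistical structure the analysis assumes:

* **Population.** Two groups of 34 and 19 by default (adult/juvenile ×
  female/male cells as in the field groups, with infants folded into
  juveniles); each adult female founds a matriline, juveniles are
  attached to adult females as offspring (relatedness 0.5 to the mother,
  0.25 within matriline, 0 otherwise), adult males carry no matriline.
  Ranks are distinct normalised values spanning [0, 1] within group.
* **Sessions.** 11 and 10 sessions per group of ~46.8 minutes; bout
  counts are Poisson around a configurable mean with uniformly scattered
  bout times. Default means (320 and 15 per session) reproduce the
  order-of-magnitude participation imbalance between a large habituated
  group and a small one.
* **Participation and attendance.** The actor of each bout is drawn with
  probability ∝ rank^s (default s = 1), reflecting that high rankers
  manipulate more; each other group member attends with probability
  base × rank_demonstrator^a (defaults 0.25 and 0.5), reflecting that
  high rankers are watched more. The field attendance process is
  unobserved, so this rank-scaled Bernoulli model is an explicit
  assumption, exposed in the configuration.
* **Choice and payoff.** The actor's technique is drawn from exactly the
  same combined choice rule the likelihood evaluates (the simulator and
  the likelihood share the step function, and the per-event probability
  ledger is bit-identical to a likelihood replay under the true
  parameters). Payoffs are Bernoulli per technique with fixed success
  probabilities, default (0.47, 0.08, 0.05) for (CMS, CMT, CH) following
  the observed ordering of technique success in the motivating
  experiment. Innovation is emergent — the first success arises from
  exploration, there is no trained demonstrator.

What the generator does *not* emulate: spatial structure and box
monopolisation, demographic turnover, attention dependent on observer
identity (only the demonstrator's rank matters), non-stationary success
probabilities, and observation error in attendance coding. Passing
parameter-recovery tests on this generator therefore demonstrates that
the inference machinery is correct and well calibrated for data satisfying
the model's assumptions, not that field data satisfy them.

Default generating parameters (λ = 8, φ = 0.06, γ ≈ 0.2, f_c ≈ 1.15,
β_pay ≈ 0.9, β_rank ≈ 1) sit in the region reported for this model family
in field studies; recovery studies in the test suite use the payoff-bias
spec with γ = 0.3, β_pay = 1, φ = 0.06, λ = 8.

## Descriptive summaries

`summarize_log()` reports per-individual success/attempt/manipulation
counts and the latency of first success as *cumulative exposure*: the sum
of elapsed session time (a session's last event time) over all earlier
sessions plus the event time within the session of first success. This
matches multi-session latencies that exceed any single session's length;
wall-clock latency within the experiment is not computed. Group-level
technique success rates use the all-manipulations denominator, so the
per-technique rates of a group sum to its overall success proportion.

## Known limitations

* The sampler is random-walk based; for the global spec (nine
  hierarchical parameters) effective sample sizes per iteration are
  modest, and long runs are advisable for publication-grade intervals.
  Split-R̂ is reported per parameter and should be checked.
* WAIC is the only information criterion implemented (no PSIS-LOO).
* The model describes choice frequencies; it makes no mechanistic claim
  about imitation or emulation.
* β coefficients of rarely varying cues (e.g. kinship in a population
  where most demonstrators are unrelated) are weakly identified and lean
  on their priors; this is visible in their wide intervals rather than
  hidden.
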