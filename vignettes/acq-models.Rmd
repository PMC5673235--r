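---
title: "Actor/critic and Q-learning hybrid models for a two-stage Markov decision task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Actor/critic and Q-learning hybrid models for a two-stage Markov decision task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acqrl)
```

## The task

The package simulates and analyzes a sequential instrumental-learning task
built on a two-stage Markov decision process with interleaved passive and
active trials. Four first-stage states occur equally often in randomized
quartets: two *passive* fractal cues (`P1`, `P2`) that transition on their
own, and two *active* cues (`A1`, `A2`) requiring a left- or right-hand
response. Either route leads to one of two shared second-stage passive
states (`S1`, `S2`), which in turn probabilistically yield a fixed monetary
reward or nothing. The transition structure is symmetric: the two
second-stage reward probabilities are complements of one another, the two
passive first-stage rows are complements, and the action-to-outcome mapping
is inverted across the two active states, so whenever one hand is best in
one active state the other hand is best in the other. A session of 200
trials contains one 80-trial block followed by two 60-trial blocks, each
block boundary defined by a reversal of the transition probabilities at the
first or the second stage (counterbalanced); 50-trial scanning runs are
deliberately decoupled from block boundaries. Intertrial intervals are drawn
without replacement per run from the 51-point grid of 4–8 s in 80-ms steps.

The published task description never states the numeric transition
probabilities, so the package defaults every stochastic row to 0.7/0.3 — a
typical level for probabilistic-reversal designs — and keeps all of them
configurable (`build_task()`); all downstream code is probability-agnostic.
Because only the swap of rows is described for reversals, later blocks reuse
the first block's probability magnitudes. Rewards are coded `r = 1`
internally, with the monetary magnitude kept as display metadata.

## The model family

Every trial is one episode of two temporal-difference steps — first stage to
second stage (no reward), then second stage to terminal (reward `r`) — and
eligibility traces never cross trial boundaries. The discount factor is
omitted (`gamma = 1`): exactly one reward can occur per trial at a fixed
delay. All values start at zero, and terminal states carry value 0 by
construction, so the outcome-stage error is exactly `r - V(second)`.

* **Critic** (state values): `dV = r + V(s') - V(s)`; every state `n` steps
  back in the episode receives `alpha * lambda^n * dV`.
* **Actor** (preferences `p(s, a)`): updated by the *same* state-value
  error, with the same eligibility weighting. Preferences are neither
  bounded nor renormalized — no normalization is specified for them, and the
  softmax is invariant to their common offset only through the temperature,
  so we leave them free.
* **Q-learner** (action values): `dQ = r + max_a' Q(s', a') - Q(s, a)`. At
  action-less states a formal *pseudoaction* `A0` makes the notation
  uniform: `Q(s, A0)` is an alias of `V(s)`. In the critic/Q hybrids the
  second-stage error therefore updates the post-action state value and, via
  the eligibility trace, the preceding action's Q entry. The *pure* Q(0)
  model has no state values at all; it learns through a single bridged
  update `dQ = r - Q(first, a)` applied at outcome delivery — the only
  update that lets it learn across the action-less gap, and the reading
  under which this model is fittable at all.
* **Model-based planner**: learns the transition function from
  state-prediction errors `d* = 1 - T(s, a, s')` (observed row entry moves
  up by `alpha* d*`, all others shrink by `1 - alpha*`, so rows stay
  normalized from their uniform 1/2 prior), and replans all action values on
  every trial by backward induction over the episode's acyclic graph.

Net action weights combine the modules:
`W = w_Q Q + (1 - w_Q) p` and `W* = w* Q* + (1 - w*) W`, so the actor/critic
(`w_Q = 0`), critic/Q-learner (`w_Q = 1`), pure planner (`w* = 1`) and every
intermediate hybrid are nested in one parameterization. Choice follows a
softmax with temperature `tau` over `W*` plus two internal biases: a
constant rightward bias `beta_R` and a perseveration bias that adds
`beta_0 * lambda_beta^n` for the action chosen `n` visits ago in the same
state (decay is per visit, not per trial; negative `beta_0` produces
alternation). The learning-free *hysteresis* model retains the softmax and
both biases with all learning rates at zero; the *null* model is a constant
`P(A1)`. The hysteresis model keeps its printed four free parameters even
though `tau` is redundant with the scale of the betas when no learned values
enter the softmax; the redundancy is documented rather than removed so that
complexity penalties use the published parameter counts.

The factorial registry (`model_registry()`) enumerates 21 learning models —
Q(0); AC/CQ/ACQ each with eligibility fixed at 0, fixed at 1, or free; the
planner; and each model-free variant plus the planner — which together with
hysteresis form the 22 comparison alternatives, with the null intercept
model as baseline. Free-parameter counts follow the same bookkeeping
(ACQ(lambda): 7; ACQ(lambda)+MB: 9; hysteresis: 4; null: 1).

## Fitting and comparison

`fit_subject()` maximizes the choice likelihood (valid active trials only;
error trials contribute neither likelihood nor updates, because an aborted
trial shows no transition) by Nelder-Mead on an unconstrained
reparameterization: logistic transforms for unit-interval parameters, log
for the temperature. Defaults: 20 randomized start points drawn uniformly in
transformed space under the given seed, relative function tolerance 1e-9,
iteration cap growing with dimensionality; the one-parameter null model uses
golden-section search instead, as the simplex is unreliable in one
dimension. Model comparison uses AICc with `n` equal to the number of valid
choices — the likelihood-bearing observations — since the criterion's sample
size is otherwise ambiguous; ties in AICc break toward fewer parameters.
`sensitivity()` summarizes fitted parameters as `log(alpha (1 + lambda) /
tau)`, and `classify_subject()` labels subjects Good (accuracy above the 50%
chance level by a one-tailed exact binomial test at 0.05), Poor, or
Nonperformer (a Poor learner whose lowest-AICc model is hysteresis).

Accuracy excludes error trials, blocks in which the two actions tie, and
the first encounter of each active state. The exclusion is block-scoped by
default — contingencies reset at each reversal, so the first post-reversal
encounter is equally uninformative — with a session-scoped variant
available.

## Synthetic cohorts

`generate_cohort()` simulates agents in closed loop (policy samples the
choice, the task samples the outcome, latents update online). Generative
parameters default to independent truncated normals with the fitted
Good-learner group means and standard deviations (`generative_param_priors()`);
correlations between parameters are not modeled because only means and
spreads are reported. The default 3% miss rate mirrors the handful of missed
trials real subjects produce (about 6 of 200); recovery analyses should
tolerate them. Reaction times are plumbing only — lognormal draws sped up
by about 100 ms per unit of normalized choice difficulty, the order of the
published RT effect — since no RT process model is fitted. Yoked replays
(`simulate_yoked()`) keep the observed schedule, passive trials and error
trials, and resample only the choices (with active-trial outcomes drawn
from the true contingencies for the chosen action).

Simulated agents at fitted-parameter levels score lower than the human
Good-learner group average: a softmax agent's asymptotic accuracy is capped
by `logistic(dEV / tau)` plus bias effects, and simulation-versus-fit gaps
of this kind are expected. Passing recovery tests therefore shows the
estimation machinery is sound under the model's own assumptions, not that
real behavior is fully captured.

## fMRI regressors

For design construction (not for behavioral fitting), the critic's state
space is extended with the intertrial fixation and the two pre-trial cues,
chained ITI → cue → first stage → second stage → terminal. The extra
upstream states receive eligibility credit but never alter a downstream
value, so the fractal-state values and errors are bit-identical to the
behavioral pass (a property the tests check). Four parametric regressors are
built: state value and state-value-prediction error at every passive event,
action value and an action-value-prediction error extended to the states
during and immediately following active states. Value boxcars persist
through the following interstimulus interval (expectations should not
change while nothing happens); prediction-error boxcars span the stimulus
that completes the transition. Unmodulated indicator regressors cover both
cue types, passive fractals, active states split by chosen hand, both
outcome types, fixation onsets, and error trials as separate events.
Modulators are mean-centered per regressor and run (the standard
parametric-modulator convention), convolved on a 10-ms grid with a canonical
double-gamma response (peak shape 6, undershoot 16, ratio 6, unit rate —
the standard constants), and sampled at TR = 2.770 s. The correlation
between the convolved state-value and action-value error regressors
(`modulator_collinearity()`) is reported as a diagnostic; no
orthogonalization is applied anywhere. Error trials emit only their cue,
fixation and error events: an aborted trial shows no transition, so no
modulated event is defined for it. Durations that are not printed anywhere
(the outcome stimulus, the ITI "state") default to the stimulus duration and
the sampled ITI respectively, both configurable.

## Numerical choices and test scale

Transition rows are validated to 1e-12 after construction, reversal and
every planner update. Exact ties in `better_action()` return a sentinel and
are excluded from scoring. The softmax subtracts the maximum before
exponentiation. Degenerate regressions (all-zero weight differences,
constant difficulty, empty RT sets) raise errors rather than returning
numbers. The test suite runs its recovery studies at desk scale chosen to
balance statistical resolution against runtime: 20 simulated subjects with
20 restarts for parameter recovery, 12 subjects with 12 restarts across all
22 alternatives for model recovery, 1,000 chance-level agents for classifier
calibration, and a 48,000-trial session (about 48,000 scored choices in the
acceptance script's 96,000-trial variant) for the chance-level accuracy
check.

## Limitations

The behavioral likelihood treats each trial as an isolated episode; signals
spanning trials (beyond perseveration) are not modeled. SARSA variants,
discounting, successor representations and Dyna-style architectures are out
of scope, as are MRI preprocessing, GLM estimation on BOLD data, and any
group-level imaging statistics. The synthetic cohorts emulate the
statistical structure the analyses assume — softmax choice, truncated-normal
parameter spread, a constant miss rate — and none of the richer structure of
human data (fatigue, attention lapses, parameter drift), so recovery results
bound what the pipeline can do under its own assumptions only.
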