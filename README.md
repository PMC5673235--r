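# acqrl

Reinforcement-learning models for a two-stage Markov decision task with
interleaved passive and active trials — the kind of design used to
dissociate the two classical teaching signals of model-free learning in the
brain: the **state-value-prediction error** (SVPE) of an actor/critic,

> δ<sup>V</sup> = r + V(s′) − V(s),

which is computed regardless of actions, and the **action-value-prediction
error** (AVPE) of a Q-learner,

> δ<sup>Q</sup> = r + max<sub>a′</sub> Q(s′, a′) − Q(s, a).

The package is for computational cognitive neuroscientists who need the
whole analysis chain around such a task in one tested place:

* a configurable simulator of the task itself — symmetric probabilistic
  transitions, within-session reversals (blocks of 80/60/60 trials),
  randomized quartets of the four initial states, 4–8 s intertrial
  intervals drawn without replacement from an 80-ms grid, four 50-trial
  runs decoupled from block boundaries;
* the full nested model family: actor/critic, Q-learning, critic/Q and
  actor/critic/Q hybrids (net weights `W = w_Q Q + (1 − w_Q) p`) with
  TD(λ) eligibility traces confined to each trial's episode, an optional
  model-based planner learned from state-prediction errors and mixed in as
  `W* = w* Q* + (1 − w*) W`, and an augmented softmax policy with a
  constant side bias and a per-visit exponentially decaying perseveration
  bias — 21 learning models plus hysteresis and null baselines;
* per-subject maximum-likelihood fitting (Nelder-Mead with randomized
  restarts on transformed parameters), AICc factorial comparison over the
  22 alternatives, the sensitivity index log(α(1+λ)/τ), and
  Good/Poor/Nonperformer classification;
* behavioral statistics: accuracy with first-encounter and error
  exclusions, exact binomial chance tests, model-derived choice and
  stay/switch logistic regressions, RT-difficulty regression, binned
  choice curves;
* closed-loop and yoked synthetic cohorts for parameter- and
  model-recovery studies;
* model-based fMRI design construction: the four parametric regressors
  (SVPE, V, AVPE, Q) with the published boxcar conventions, unmodulated
  event regressors, canonical double-gamma convolution at TR = 2.77 s, and
  the SVPE–AVPE collinearity diagnostic.

## Worked example

Simulate one Good-learner-like agent, analyze its behavior, refit it, and
build its first-level design:

```r
library(acqrl)

task <- build_task()                      # 0.7/0.3 contingencies, 200 trials
pars <- c(alpha = 0.588, lambda = 0.682, w_q = 0.661, tau = 0.404,
          beta_0 = 0.093, lambda_beta = 0.621, beta_r = 0.230)
sim  <- simulate_agent("ACQ(lambda)", pars, task, seed = 6, miss_rate = 0.03)

behavior_report(sim$session, sim$forward$trace, task)
#> Accuracy 67.4% over 92 scored choices (p = 0.0005555) -> Good
#>   choice ~ dW slope: 3.625 (one-tailed p = 5.25e-07)
#>   RT ~ |dW| slope: -121.8 ms (one-tailed p = 0.0122)

fit <- fit_subject("ACQ(lambda)", sim$session, n_restarts = 20, seed = 1)
fit
#> Fit of ACQ(lambda): NLL = 44.239, k = 7, n = 98, AICc = 103.723
#>       alpha      lambda         w_q         tau      beta_r      beta_0
#>      0.7082      0.4364      0.8378      0.3579      0.1629      0.2110
#> lambda_beta
#>      0.1362
sensitivity(fit$params)
#> [1] 1.045

des <- build_design_matrix("ACQ(lambda)", fit$params, sim$session)
modulator_collinearity(des)
#> [1] 0.629
```

The accuracy line says this agent chose the objectively better hand in
67.4% of its scorable choices — above the 50% chance level by an exact
binomial test, hence the Good-learner label. The positive choice-regression
slope shows choices tracking the model's net action-weight difference, the
negative RT slope shows easier discriminations being answered faster, and
the refitted parameters sit near the generating ones. The last number is
the correlation between the two convolved prediction-error regressors:
well below 1, so the design can dissociate them without orthogonalization.

For the full factorial comparison, fit all models and tabulate:

```r
fits <- fit_all_models(sim$session, n_restarts = 12, seed = 2)
compare_models(fits)    # per-model NLL / AICc vs the hysteresis benchmark
```

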