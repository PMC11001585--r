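# ruleswitch

Simulation and analysis tools for studying how striatal dopamine signals
track cue–action–outcome learning under changing task rules.

In the task this package models, a head-fixed mouse hears an auditory cue
that varies along two dimensions — speaker location (left/right) and
frequency (low/high) — and licks one of two spouts for a water reward.
Which spout is correct depends on an implicit rule (`location`,
`frequency`, or `frequency_reversed`) that switches once the animal has
performed two consecutive sessions at criterion (≥ 80% correct overall
and ≥ 60% correct in each of the four cue conditions). Dopamine
transients recorded by fiber photometry in striatal subregions (VS, DMS,
DLS) behave like reward prediction errors (RPEs), and the interesting
phenomena live around the rule switches: cue-evoked and outcome-evoked
signals can become *uncoupled* from each other and from performance.

`ruleswitch` re-implements the computational core of this paradigm as a
tested, reusable pipeline:

- **Task environment** (`make_environment()`, `env_step()`,
  `generate_schedule()`): a 22-state episodic environment per rule
  (initial → cue → action → outcome → end), with a probabilistic variant
  in which outcomes flip in 10% of trials, and blocked pseudorandom
  trial schedules (32-trial blocks, each condition 8×).
- **TD agents** (`agent_params()`, `run_protocol()`, `extract_rpes()`):
  on-policy SARSA, off-policy Q-learning and a state-value learner with
  softmax action selection plus a session-decaying side bias. TD errors

      δ_t = r_{t+1} + γ Q(s_{t+1}, a_{t+1}) − Q(s_t, a_t)        (SARSA)
      δ_t = r_{t+1} + γ max_a Q(s_{t+1}, a) − Q(s_t, a_t)        (Q-learning)

  are logged at every state entry and serve as model RPEs. At each rule
  switch the value table is reset (`none`, `complete`, or `partial`,
  which retains only the choice-guiding cue-state action values).
  Standard parameters: α = 0.003 (0.015 for state values), γ = 1,
  β = 6, β_bias0 = 0.4, λ_bias = 0.4, 300 trials per session.
- **Behavioral metrics** (`session_summary()`, `response_bias()`,
  `learning_rate()`, `truncate_session()`, `stay_switch_performance()`):
  accuracy, response-bias index, novice/intermediate/expert staging,
  acquisition criterion, satiety truncation, and stay/switch splits
  (conditions whose correct response survives a rule switch vs not).
- **Choice model** (`build_regressors()`, `fit_logistic()`,
  `crossval_accuracy()`, `compare_models()`): session-based logistic
  regression of trial-by-trial choice,
  `P(right) = 1 / (1 + exp(−(Σ_p β_p x_p + β_0)))`, fit by gradient
  descent on the negative log-likelihood with no regularization, with
  ten-fold cross-validated accuracy and reduced/alternative model
  comparison. Regressors include cue location/frequency (±1), the
  per-spout exponentially weighted reward-rate difference, choice
  history, win-stay/lose-switch, and more.
- **Photometry chain** (`process_photometry()` and its parts): 50-ms
  smoothing and downsampling to 50 Hz, per-trial ΔF/F against a 500-ms
  pre-trial baseline, robust z-scoring (median/MAD), and signed
  prominence-based peak extraction in region-specific epoch windows
  (cue 1,000 ms; spouts 340 ms; outcome 840/740/380 ms with 160/160/140
  ms latency for VS/DMS/DLS).
- **Synthetic data** (`simulate_photometry()`,
  `simulate_behavior_parametric()`, `make_fixture_dataset()`):
  generators with known ground truth — RPE-driven fluorescence traces
  with region-specific kinetics, drift and noise, and parametric
  behavior for choice-model recovery.

Everything takes and returns tibbles, so results chain with the pipe;
fitted objects have `tidy()`/`glance()` methods and `autoplot()`s.

## Worked example

Simulate five SARSA agents with a partial value reset through the first
rule switch, and look at the uncoupling signature:

```r
library(ruleswitch)

prot <- run_protocol(agent_params("sarsa", reset_mode = "partial"),
                     rules = c("location", "frequency"),
                     n_agents = 5, seed = 1)
glance(prot)
#> # A tibble: 1 × 6
#>   algorithm reset_mode n_agents n_sessions n_trials all_converged
#> 1 sarsa     partial           5         75    22500 TRUE

head(tidy(prot)[, c("agent", "rule", "session_in_rule",
                    "fraction_correct", "stage")], 5)
#>   agent rule     session_in_rule fraction_correct stage
#> 1     1 location               1            0.52  novice
#> 2     1 location               2            0.55  novice
#> 3     1 location               3            0.573 novice
#> 4     1 location               4            0.71  intermediate
#> 5     1 location               5            0.77  intermediate
```

Agents start near chance (the decaying side bias holds them there for a
few sessions), then acquire the rule. In the first session after the
switch to the frequency rule, cue-epoch RPEs on correct trials separate
by stay/switch condition while outcome-epoch RPEs do not:

```r
rpe <- function(ep, cls)
  mean(extract_rpes(prot, ep, correct = TRUE, rule = "frequency",
                    session_in_rule = 1, stay_switch = cls)$delta)
rpe("cue", "stay"); rpe("cue", "switch")
#> 0.19  -0.20      # cue RPEs track the retained cue-state values
rpe("outcome", "stay"); rpe("outcome", "switch")
#> 0.90   0.99      # outcome RPEs rise equally: expectations were reset
```

Fit the session-based choice model to synthetic behavior with known
weights (cue 2.0, bias 0.5, choice history 0.3):

```r
trials <- simulate_behavior_parametric(n_trials = 500, w_cue_location = 2,
                                       w_bias = 0.5, w_history = 0.3, seed = 2)
fit_logistic(build_regressors(trials))
#> <choice_fit> 500 trials, J = 0.299, 108 iterations
#>       (Intercept)      cue_location     cue_frequency delta_reward_rate
#>            0.8279            2.4710            0.1472           -0.1695
crossval_accuracy(build_regressors(trials), seed = 1)
#> 0.9
```

Process a synthetic photometry session end to end:

```r
fx <- make_fixture_dataset(seed = 1, n_photometry_trials = 20)
ps <- process_photometry(fx$photometry$VS$trace, fx$photometry$VS$events,
                         region = "VS")
head(tidy(ps), 4)
#>   trial epoch   amplitude latency_ms n_samples
#> 1     1 cue         4.26        140.        51
#> 2     1 spouts     -0.662       160.        18
#> 3     1 outcome   -10.6         180.        42
#> 4     2 cue         4.27        140.        51
```

Amplitudes are in robust-z units of the session's ΔF/F; trial 1 here is
a post-switch error trial, hence the deep negative outcome transient.

See the methods vignette (`vignettes/ruleswitch-methods.Rmd`) for the
model definitions, parameter choices and known limitations.

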