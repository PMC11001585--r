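---
title: "Models and methods in ruleswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ruleswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruleswitch)
```

This vignette documents the models implemented in `ruleswitch`, the
parameters that matter, the numerical and design choices that were
genuinely open, and what the synthetic-data tests do and do not show
about real data.

## The task and its state space

The modeled task is a two-alternative auditory decision task for
head-fixed mice. Each trial presents a cue defined by location
(left/right speaker) and frequency (low/high noise band), giving four
conditions. The correct response is set by an implicit rule —
`location` (respond on the cued side), `frequency` (low→left,
high→right) or `frequency_reversed` (high→left, low→right) — that
switches after two consecutive criterion sessions. After the first
switch (location→frequency) two conditions keep their correct response
("stay") and two do not ("switch"); after the second switch all four
switch. Behavioral trials are scheduled in 32-trial blocks with each
condition drawn 8 times without replacement per block.

Each trial is one episode through 22 states: one initial state, four
cue states, eight action states (condition × chosen side), eight
outcome states (condition × reward/no-reward) and one terminal end
state whose value is fixed at 0. Entering the reward state pays +1,
entering the no-reward state pays −1; rewards are zero elsewhere. In
the probabilistic variant, the action→outcome transition is inverted
with probability 0.1 per trial (a correct action can land in the
no-reward state and vice versa).

Two sequence regimes are provided deliberately: agent simulations draw
the condition uniformly at random each trial (the initial state
transitions to each cue state with probability 1/4), while
behavior-like logs can use the blocked schedule via
`generate_schedule()`. Only full blocks guarantee exact condition
balance; truncated schedules are balanced per completed block.

## Temporal-difference agents

Agents learn state-action values Q(s, a), initialized to 0, by
`Q(s_t, a_t) ← Q(s_t, a_t) + α δ_t` with TD error

- SARSA (on-policy): `δ_t = r_{t+1} + γ Q(s_{t+1}, a_{t+1}) − Q(s_t, a_t)`,
  bootstrapping from the action actually chosen next;
- Q-learning (off-policy): `δ_t = r_{t+1} + γ max_a Q(s_{t+1}, a) − Q(s_t, a_t)`;
- state-value learner: `δ_t = r_{t+1} + γ V(s_{t+1}) − V(s_t)`.

Actions only matter in the cue states; elsewhere a dummy action is
taken and both action slots are set equal after the update. RPEs are
the TD errors of entering a state, so each episode logs one δ at the
cue, action, outcome and end entries. With γ = 1 these telescope
exactly: their sum equals the episode's total reward minus the initial
state's prediction, which the test suite asserts to 1e−12.

Action selection is softmax over biased values,
`P(left) = exp(β(Q_L + b_L)) / (exp(β(Q_L + b_L)) + exp(β(Q_R + b_R)))`,
computed through the logistic identity so it cannot overflow. The side
bias b starts at β_bias0 on one side (0 on the other) and decays to 0
across sessions within a rule. Defaults for all simulations:
α = 0.003 for state-action learning and 0.015 for state values, γ = 1,
β = 6, β_bias0 = 0.4, λ_bias = 0.4, 300 trials per session.

Design choices that were open:

- **Bias decay form.** λ_bias is described as a decay constant, so the
  primary form is exponential, `β_bias(k) = β_bias0 exp(−λ_bias k)`
  with k the 0-based session index within the rule; a geometric
  alternative `β_bias0 (1 − λ_bias)^k` sits behind
  `agent_params(bias_decay = "geometric")`.
- **Bias side.** Configurable left/right/random; `random` draws once
  per agent from its policy stream.
- **Bias activation.** The bias operates during initial learning
  (location rule) and when performance collapses below chance through
  perseveration (frequency_reversed rule). A literal
  "below chance" trigger is circular at session granularity — the
  first post-switch session cannot be classified until it has been
  simulated — so the reversal rule enables the bias from its first
  session, where performance necessarily falls below chance.
- **Terminal bootstrapping.** The end state's value is pinned at 0, so
  the outcome-entry δ converges to `r − Q(action)` as outcome-state
  values settle at 0.
- **Criterion in the model.** The same thresholds as behavior (≥ 80%
  overall and ≥ 60% per condition, evaluated over the 300-trial
  session); the rule switches after two consecutive criterion
  sessions.
- **Resets.** At each switch: `none` (keep everything), `complete`
  (zero everything), or `partial` (zero everything except the
  cue-state action values Q_L/Q_R — the choice-guiding associations).
  Partial reset is the configuration that uncouples cue from outcome
  RPEs: outcome expectations are wiped (outcome δ rises equally for
  stay and switch conditions) while cue values persist (cue δ on
  correct trials separates stay > switch, because SARSA's cue-entry δ
  depends on the value of the action actually chosen). Q-learning
  bootstraps from the cue state's maximum, which is similar for stay
  and switch conditions, so it shows no such separation — the
  on-policy/off-policy contrast the simulations test.
- **Cue-epoch RPE.** "The TD error of entering a state" leaves open
  whether the cue-epoch RPE is the δ of entering the cue state or the
  action state; both are logged (`delta_cue`, `delta_action`) and the
  cue entry is the default reported by `extract_rpes(epoch = "cue")`.
- **State-value RPEs.** The state-value learner observes episodes
  generated by a SARSA policy learner with the standard settings
  (α = 0.003 for the policy, 0.015 for V), since pure state values
  cannot themselves select actions.

Each agent owns two RNG streams derived from the master seed — policy
(action sampling, bias side) and environment (condition draws, outcome
flips) — so behavior and environment randomness are independently
reproducible; protocols are bit-identical under the same seed.

## Behavioral metrics

- **Staging.** Sessions are novice below 60% correct, intermediate from
  60% up to criterion, expert at criterion. The acquisition criterion
  is ≥ 80% correct overall *and* ≥ 60% in each condition; a session
  above 80% overall that fails the per-condition clause is classed
  intermediate. Defining expert as criterion-equivalent (boundary
  inclusive) keeps `meets_criterion ⇒ expert` exact; the boundary case
  (exactly 80%) is ambiguous in prose and had to be assigned
  somewhere.
- **Response bias.** With fcl/fcr the fraction correct among left- and
  right-cued trials, the primary index is `fcl / (fcl + fcr)` and the
  absolute bias `|index − 0.5| ∈ [0, 0.5]`. The alternative printed
  form `(fcl − fcr) / fcl` is retained behind `method = "printed"`,
  but it yields 0 (not 0.5) for unbiased behavior, so its
  `|· − 0.5|` transform violates the stated [0, 0.5] range — the ratio
  form is the reading under which an indifferent animal scores 0 and a
  one-sided responder 0.5.
- **Learning rate.** Least-squares slope of per-session accuracy from
  the first session to the first criterion session. For the location
  rule two fits are used (first→last novice; first intermediate→first
  criterion) because the strong early response bias flattens the
  novice segment. Segments with fewer than two sessions give `NA`.
- **Session truncation.** Sessions are cut at the first miss trial
  after 90% of trials, and further cut if windowed performance slumps
  in the trailing 15%. The windowing is not dictated by the
  definition; `truncate_session()` uses 20-trial rolling windows,
  compares trailing windows to the whole-session mean − 1.5 s.d. of
  windowed performance, and never removes more than the final 15%.
  This choice is documented rather than derived.

## The session-based choice model

Choice is modeled as `ŷ = 1/(1 + e^{−z})`. The linear predictor is
implemented as `z = Σ_p β_p x_p + β_0`: the compact printed form
`z = Σ_p β_p + β_0` omits the predictor values and would make the
regressors irrelevant, so the product form is the only meaningful
reading. Weights minimize the negative log-likelihood
`J = −(1/m) Σ_i [y_i log ŷ_i + (1 − y_i) log(1 − ŷ_i)]` by batch
gradient descent, with no regularization.

Numerical choices: the step-size schedule is a fixed step with
backtracking halving on any loss increase and mild re-growth after
accepted steps (`max_iter` 50,000); optimization stops when the loss
falls below 1e−4 (which also ends perfectly separable fits, whose
likelihood has no finite optimum), when the gradient infinity-norm
falls below 1e−7, or at the iteration cap (flagged non-converged).
Fits agree with `stats::glm` maximum-likelihood estimates to |Δβ| <
1e−3 on the test fixtures. Single-class sessions are flagged
degenerate. Probabilities exactly at 0.5 round to class 1 — an
arbitrary, seed-independent convention.

Regressors are coded in [−1, +1] and not standardized. History terms
at lags that precede the first trial are set to 0. The per-spout
reward rate is a ten-trial exponentially weighted average (smoothing
factor 2/11) of a reward indicator that is 1 when that spout was
chosen and rewarded and 0 otherwise — including trials where the other
spout was chosen; whether unchosen-spout trials should instead be
excluded from the average is not specified, and the indicator reading
is the one that keeps ΔRate within [−1, 1] and 0 at the start.

Cross-validation uses ten folds stratified by response class (so short
or biased sessions cannot produce single-class training folds); every
trial is tested exactly once and fold assignment is a deterministic
function of the seed, so model comparisons (`compare_models()`) share
identical partitions across models.

## Photometry processing

Raw 1-kHz traces are smoothed with a centered 50-ms running average
and decimated by 20 to 50 samples/s. The alignment and edge handling
are unstated in prose; the implementation centers the window and lets
it shrink at the edges, which keeps constants exact everywhere. ΔF/F
uses the mean of a 500-ms pre-trial window as baseline B,
`(F − B)/B` per sample; non-positive baselines flag the trial invalid.
Session normalization is a robust z-score, `(x − median)/MAD`
(unscaled MAD), computed over the concatenated analyzed trial segments
(baseline-only or whole-session references are minor variants; a zero
MAD flags the session degenerate).

Epoch amplitudes are the signed dominant extremum per window: the
local peak and local valley with the largest prominence are computed
(valleys via sign inversion) and the more prominent one is returned;
ties go to the peak. No minimum prominence threshold is applied. A
window containing no interior extremum — a monotone flank, which
happens when the outcome window opens after the transient maximum —
is treated as the tail of a peak (falling) or valley (rising) anchored
at its first sample. Windows: cue 1,000 ms from cue onset (anchoring
at onset rather than trial start follows from the signal being
cue-locked); spouts 340 ms from cue offset; outcome 840/740/380 ms for
VS/DMS/DLS starting 160/160/140 ms after the instrumental lick. Plain
window means are available as a cross-check variant
(`method = "mean"`). The pipeline is invariant to positive rescaling
of the raw trace, since ΔF/F and the robust z are both scale-free.

## Synthetic data and what the tests show

`simulate_photometry()` builds 1-kHz traces by placing impulses at cue
onset, spout presentation and outcome, scaled by the logged TD errors
(the spout impulse carries an additional fixed Pavlovian component so
early-learning spout signals have a synthetic analogue), convolving
with a double-exponential sensor kernel, and adding a constant
baseline, slow sinusoidal drift and white noise. Trial timing follows
the task: cue 1,000 ms after trial start, 1,000 ms long, lick 600 ms
after cue offset, 4,000-ms intertrial interval. Kernel defaults
(rise/decay 60/400, 60/350, 70/250 ms for VS/DMS/DLS) are chosen so
the transient has decayed substantially by the end of each region's
outcome window — motivated by, not fitted to, the window table — and
are not a biophysical sensor model. The generator's ground-truth table
reports, per trial and epoch, the amplitude and latency a perfect
detector would read from the clean (noise- and drift-free) superposed
signal, so recovery tests validate the measurement chain without
requiring it to unmix overlapping kernel tails.

`simulate_behavior_parametric()` draws choices from a lapse-mixed
logistic policy over cue, bias and previous-choice terms, which is
exactly the choice model's generative form at lapse 0; fitting the
model to 2,000 generated trials recovers every weight's sign and
magnitudes within 25%.

What passing tests show — and do not. The synthetic generators emulate
trial-locked transients, region-specific kinetics, slow drift,
additive noise, and parametric behavioral strategies with known
weights. They do not emulate photobleaching, hemodynamic or movement
artifacts, sensor nonlinearity, licking-related signals, or
within-session strategy drift; ground-truth recovery therefore
validates the processing chain's correctness, not its robustness to
every artifact of real recordings. Likewise the agents are not fit to
animal data — parameters are fixed at the standard values and the
simulations reproduce qualitative signatures (acquisition at
criterion, perseveration after switches, RPE uncoupling under partial
reset, its absence under Q-learning), not quantitative behavioral
curves.

## Problem sizes and runtime choices

The test suite simulates 20-agent cohorts through the first rule
switch for the signature checks, 5-agent cohorts for acquisition,
5,000-trial runs for convergence properties, 10,000 draws for the
probabilistic flip rate, 2,000-trial sessions for parameter recovery,
and 10–40-trial synthetic photometry sessions (about 4–5 minutes of
1-kHz trace per region). These sizes give stable statistics for every
asserted property while keeping a full run of the suite around a
minute or two on one CPU.

## Known limitations

- Learning speed at the standard parameters is faster than real mice
  (criterion in roughly 5–10 sessions); the qualitative staging and
  switch signatures, not session counts, are the modeled quantities.
- Miss trials are not generated by the simulator (they are negligible
  in the paradigm); `truncate_session()` accepts them in real logs.
- The trial-based fluctuating-weight choice model is out of scope; the
  session-based model captures across-session strategy changes only.
- `truncate_session()` is idempotent on stable sessions with a planted
  terminal slump (the tested regime) but, like any
  threshold-re-estimation rule, is not guaranteed idempotent for
  arbitrary pathological performance curves.
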