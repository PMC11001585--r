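#' Synthetic fluorescence sensor kernel
#'
#' Double-exponential impulse response
#' `k(t) = gain * (exp(-t / tau_decay) - exp(-t / tau_rise))`, normalized
#' so its peak equals `gain`. Region defaults are chosen so the transient
#' has decayed substantially by the end of that region's outcome analysis
#' window (slowest in the VS, fastest in the DLS), mirroring the ordering
#' of the region-specific epoch windows; they are not a biophysical
#' sensor model.
#'
#' @param region `"VS"`, `"DMS"` or `"DLS"`.
#' @param tau_rise_ms,tau_decay_ms Time constants in ms (positive;
#'   rise < decay).
#' @param gain Peak amplitude in fluorescence units per unit TD error.
#' @return Object of class `sensor_kernel`.
#' @export
#' @examples
#' sensor_kernel("DLS")
sensor_kernel <- function(region = c("VS", "DMS", "DLS"),
                          tau_rise_ms = NULL, tau_decay_ms = NULL,
                          gain = 1) {
  region <- match.arg(region)
  defaults <- list(VS = c(60, 400), DMS = c(60, 350), DLS = c(70, 250))[[region]]
  tau_rise_ms <- tau_rise_ms %||% defaults[1]
  tau_decay_ms <- tau_decay_ms %||% defaults[2]
  stopifnot(tau_rise_ms > 0, tau_decay_ms > tau_rise_ms, gain > 0)
  structure(list(region = region, tau_rise_ms = tau_rise_ms,
                 tau_decay_ms = tau_decay_ms, gain = gain),
            class = "sensor_kernel")
}

#' @describeIn sensor_kernel Time of the kernel peak, in ms.
#' @param kernel A `sensor_kernel`.
#' @export
kernel_peak_ms <- function(kernel) {
  tr <- kernel$tau_rise_ms
  td <- kernel$tau_decay_ms
  tr * td / (td - tr) * log(td / tr)
}

kernel_samples <- function(kernel, fs = 1000) {
  t_ms <- seq(0, 6 * kernel$tau_decay_ms, by = 1000 / fs)
  k <- exp(-t_ms / kernel$tau_decay_ms) - exp(-t_ms / kernel$tau_rise_ms)
  kernel$gain * k / max(k)
}

#' Simulate a raw photometry trace from episode logs
#'
#' Generates a 1-kHz fluorescence trace with trial-locked transients:
#' impulses at the cue onset, spout presentation (cue offset) and outcome
#' (instrumental lick) scaled by the logged TD errors (the spout impulse
#' additionally carries a fixed Pavlovian component), convolved with the
#' region's double-exponential sensor kernel, on top of a constant
#' baseline, a slow sinusoidal drift, and white noise. Trial timing
#' follows the task: the auditory cue starts 1,000 ms after trial start
#' and lasts 1,000 ms; the instrumental lick follows the cue offset by
#' `response_latency_s`; the intertrial interval is 4,000 ms.
#'
#' @param episode_logs Tibble with one row per trial and columns
#'   `delta_cue`, `delta_action`, `delta_outcome` (e.g. from
#'   [run_protocol()] trials or built by hand).
#' @param region Striatal subregion (selects the default kernel).
#' @param kernel A [sensor_kernel()].
#' @param noise_sd White-noise s.d. in fluorescence units.
#' @param drift_amplitude,drift_period_s Sinusoidal drift parameters.
#' @param baseline Constant baseline fluorescence (> 0).
#' @param pavlovian Fixed spout-presentation impulse component.
#' @param response_latency_s Lick latency after cue offset (default 0.6).
#' @param iti_s Intertrial interval (default 4).
#' @param seed Integer seed (same seed, identical trace).
#' @return List with `trace` (tibble `time`, `value` at 1 kHz), `events`
#'   (per-trial event times), `truth` (per trial and epoch: the injected
#'   impulse amplitude, plus the ground-truth dF/F amplitude and latency
#'   a perfect detector would report in that epoch's analysis window --
#'   the extremum of the clean noise- and drift-free superposed signal,
#'   which accounts for kernel tails of neighboring transients), and the
#'   `kernel`.
#' @export
simulate_photometry <- function(episode_logs, region = c("VS", "DMS", "DLS"),
                                kernel = sensor_kernel(region),
                                noise_sd = 0.01, drift_amplitude = 0.01,
                                drift_period_s = 300, baseline = 1,
                                pavlovian = 0.3, response_latency_s = 0.6,
                                iti_s = 4, seed = 1) {
  region <- match.arg(region)
  stopifnot(baseline > 0)
  n_trials <- nrow(episode_logs)
  if (iti_s < 1) {
    abort("intertrial interval too short: trials would overlap the pre-trial baseline",
          class = "ruleswitch_generation_error")
  }
  fs <- 1000
  trial_span <- 1 + 1 + response_latency_s + iti_s
  trial_start <- 1 + (seq_len(n_trials) - 1) * trial_span
  cue_onset <- trial_start + 1
  cue_offset <- cue_onset + 1
  lick <- cue_offset + response_latency_s
  total <- max(lick) + iti_s
  n <- ceiling(total * fs)
  time <- (seq_len(n) - 1) / fs

  k <- kernel_samples(kernel, fs)
  signal <- numeric(n + length(k))
  add_impulse <- function(sig, t0, amp) {
    if (amp == 0) return(sig)
    i0 <- round(t0 * fs) + 1L
    idx <- i0:(i0 + length(k) - 1L)
    sig[idx] <- sig[idx] + amp * k
    sig
  }
  for (i in seq_len(n_trials)) {
    signal <- add_impulse(signal, cue_onset[i],
                          kernel$gain * episode_logs$delta_cue[i])
    signal <- add_impulse(signal, cue_offset[i],
                          kernel$gain * (pavlovian + episode_logs$delta_action[i]))
    signal <- add_impulse(signal, lick[i],
                          kernel$gain * episode_logs$delta_outcome[i])
  }
  signal <- signal[seq_len(n)]

  # ground truth: extremum of the clean signal within each epoch window
  win <- epoch_windows(region)
  truth <- list()
  for (i in seq_len(n_trials)) {
    inj <- kernel$gain * c(episode_logs$delta_cue[i],
                           pavlovian + episode_logs$delta_action[i],
                           episode_logs$delta_outcome[i])
    anchors <- c(cue_onset[i], cue_offset[i], lick[i])
    amp <- lat <- numeric(3)
    for (j in 1:3) {
      idx <- which(time >= anchors[j] + win$start_ms[j] / 1000 &
                     time <= anchors[j] + win$end_ms[j] / 1000)
      ext <- if (inj[j] >= 0) idx[which.max(signal[idx])]
             else idx[which.min(signal[idx])]
      amp[j] <- signal[ext] / baseline
      lat[j] <- (time[ext] - anchors[j]) * 1000
    }
    truth[[i]] <- tibble(
      trial = i, epoch = win$epoch, event_time = anchors,
      injected = inj, expected_dff = amp, expected_latency_ms = lat
    )
  }
  stream <- rng_stream(derive_seed(seed, 11L))
  value <- baseline + signal +
    drift_amplitude * sin(2 * pi * time / drift_period_s) +
    noise_sd * stream$rnorm(n)
  list(
    trace = tibble(time = time, value = value),
    events = tibble(trial = seq_len(n_trials), trial_start = trial_start,
                    cue_onset = cue_onset, cue_offset = cue_offset,
                    lick = lick),
    truth = bind_rows(truth),
    kernel = kernel
  )
}

#' Simulate behavior with a known parametric strategy
#'
#' Generates a session of choices from a lapse-mixed logistic policy,
#' `P(right) = lapse + (1 - 2 lapse) * plogis(z)` with
#' `z = w_cue_location x_loc + w_cue_frequency x_freq + w_bias +
#' w_history x_prev_choice` (predictors coded -1/+1 as in
#' [build_regressors()]). Outcomes are assigned by the active task rule.
#' Used for choice-model parameter recovery with known ground truth.
#'
#' @param n_trials Number of trials.
#' @param rule Task rule assigning correct responses.
#' @param w_cue_location,w_cue_frequency Cue weights.
#' @param w_bias Signed side bias (positive favors right).
#' @param w_history Previous-choice weight.
#' @param lapse Lapse rate in `[0, 0.5]`.
#' @param seed Integer seed.
#' @param schedule Optional schedule from [generate_schedule()]; by
#'   default a blocked schedule is generated from `seed`.
#' @return Trial tibble: `trial`, `block`, `condition`, `cue_location`,
#'   `cue_frequency`, `rule`, `choice`, `correct`, `rewarded`, with the
#'   generating weights in attribute `weights`.
#' @export
#' @examples
#' trials <- simulate_behavior_parametric(200, w_cue_location = 3, seed = 1)
#' mean(trials$correct)
simulate_behavior_parametric <- function(n_trials = 500, rule = "location",
                                         w_cue_location = 2,
                                         w_cue_frequency = 0,
                                         w_bias = 0, w_history = 0,
                                         lapse = 0.02, seed = 1,
                                         schedule = NULL) {
  assert_rule(rule)
  stopifnot(lapse >= 0, lapse <= 0.5)
  if (is.null(schedule)) {
    schedule <- generate_schedule(n_trials, seed = derive_seed(seed, 21L))
  }
  stopifnot(nrow(schedule) == n_trials)
  loc <- ifelse(schedule$cue_location == "right", 1, -1)
  freq <- ifelse(schedule$cue_frequency == "high", 1, -1)
  stream <- rng_stream(derive_seed(seed, 22L))
  u <- stream$runif(n_trials)
  choice <- character(n_trials)
  prev <- 0
  for (t in seq_len(n_trials)) {
    z <- w_cue_location * loc[t] + w_cue_frequency * freq[t] +
      w_bias + w_history * prev
    p_right <- lapse + (1 - 2 * lapse) * stats::plogis(z)
    choice[t] <- if (u[t] < p_right) "right" else "left"
    prev <- if (choice[t] == "right") 1 else -1
  }
  correct <- choice == correct_action(rule, schedule$cue_location,
                                      schedule$cue_frequency)
  out <- schedule %>%
    mutate(rule = rule, choice = choice, correct = correct,
           rewarded = correct)
  attr(out, "weights") <- c(cue_location = w_cue_location,
                            cue_frequency = w_cue_frequency,
                            bias = w_bias, history = w_history,
                            lapse = lapse)
  out
}

#' End-to-end synthetic fixture dataset
#'
#' Builds a complete small dataset with known ground truth for tests and
#' documentation: a SARSA partial-reset protocol across all three rules
#' (one agent), a parametric behavioral session, and RPE-driven synthetic
#' photometry traces for all three striatal subregions generated from the
#' first post-switch frequency session.
#'
#' @param seed Master seed.
#' @param n_photometry_trials Trials per synthetic trace (default 40).
#' @return List with `protocol` (an `rl_protocol`), `behavior` (a
#'   parametric session) and `photometry` (named list of
#'   [simulate_photometry()] outputs for VS, DMS, DLS).
#' @export
make_fixture_dataset <- function(seed = 1, n_photometry_trials = 40) {
  protocol <- run_protocol(agent_params("sarsa", reset_mode = "partial"),
                           n_agents = 1, max_sessions_per_rule = 60,
                           seed = derive_seed(seed, 31L))
  behavior <- simulate_behavior_parametric(
    n_trials = 480, w_cue_location = 2, w_bias = 0.5, w_history = 0.3,
    seed = derive_seed(seed, 32L))
  logs <- protocol$trials %>%
    filter(.data$rule == "frequency", .data$session_in_rule == 1) %>%
    head(n_photometry_trials)
  photometry <- lapply(setNames(nm = c("VS", "DMS", "DLS")), function(rg) {
    simulate_photometry(logs, region = rg, seed = derive_seed(seed, 33L))
  })
  list(protocol = protocol, behavior = behavior, photometry = photometry)
}
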