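#' The four trial conditions of the auditory rule-switch task
#'
#' Each trial presents an auditory cue defined along two dimensions:
#' location (left/right speaker) and frequency (low/high band-passed
#' noise). The cartesian product gives exactly four conditions.
#'
#' @return A tibble with columns `condition` (label, e.g. `"left-low"`),
#'   `cue_location` and `cue_frequency`.
#' @export
#' @examples
#' task_conditions()
task_conditions <- function() {
  tibble(
    condition     = c("left-low", "left-high", "right-low", "right-high"),
    cue_location  = c("left", "left", "right", "right"),
    cue_frequency = c("low", "high", "low", "high")
  )
}

#' Task rule names
#'
#' Three implicit rules map the cue to the rewarded spout: `location`
#' (lick the side the sound came from), `frequency` (low -> left,
#' high -> right) and `frequency_reversed` (high -> left, low -> right).
#'
#' @return Character vector of the three rule names in training order.
#' @export
task_rule_names <- function() c("location", "frequency", "frequency_reversed")

assert_rule <- function(rule) {
  if (length(rule) != 1L || !rule %in% task_rule_names()) {
    abort(paste0("unknown task rule: ", paste(rule, collapse = ", ")),
          class = "ruleswitch_config_error")
  }
  rule
}

#' Correct action under a task rule
#'
#' @param rule One of [task_rule_names()].
#' @param cue_location `"left"` or `"right"` (vectorized).
#' @param cue_frequency `"low"` or `"high"` (vectorized).
#' @return Character vector of rewarded actions (`"left"`/`"right"`).
#' @export
#' @examples
#' correct_action("location", "left", "low")
#' correct_action("frequency_reversed", c("left", "right"), c("low", "high"))
correct_action <- function(rule, cue_location, cue_frequency) {
  assert_rule(rule)
  stopifnot(all(cue_location %in% c("left", "right")),
            all(cue_frequency %in% c("low", "high")))
  switch(rule,
    location  = cue_location,
    frequency = ifelse(cue_frequency == "low", "left", "right"),
    frequency_reversed = ifelse(cue_frequency == "high", "left", "right")
  )
}

#' Classify conditions as stay or switch across a rule change
#'
#' A condition is a *stay* condition when the correct response is the same
#' under the new rule as under the previous rule, and a *switch* condition
#' otherwise. After the first switch (location -> frequency) two conditions
#' stay and two switch; after the second (frequency -> frequency_reversed)
#' all four switch.
#'
#' @param prev_rule,new_rule Distinct rule names.
#' @inheritParams correct_action
#' @return Character vector, `"stay"` or `"switch"`.
#' @export
#' @examples
#' classify_stay_switch("location", "frequency", "left", "low")
classify_stay_switch <- function(prev_rule, new_rule, cue_location, cue_frequency) {
  assert_rule(prev_rule)
  assert_rule(new_rule)
  if (identical(prev_rule, new_rule)) {
    abort("prev_rule and new_rule must differ", class = "ruleswitch_argument_error")
  }
  same <- correct_action(prev_rule, cue_location, cue_frequency) ==
    correct_action(new_rule, cue_location, cue_frequency)
  ifelse(same, "stay", "switch")
}

#' Generate a blocked pseudorandom trial schedule
#'
#' Trials are presented in blocks of `block_size` trials; within each block
#' the four conditions are drawn randomly without replacement, so each
#' condition occurs exactly `block_size / 4` times per block. If `n_trials`
#' is not a multiple of `block_size`, whole blocks are generated and the
#' sequence truncated, so only complete blocks are exactly balanced.
#'
#' @param n_trials Number of trials.
#' @param block_size Block length; must be divisible by 4. Default 32.
#' @param seed Integer seed; schedules are deterministic given the seed.
#' @return A tibble with columns `trial`, `block`, `condition`,
#'   `cue_location`, `cue_frequency`.
#' @export
#' @examples
#' generate_schedule(64, seed = 1)
generate_schedule <- function(n_trials, block_size = 32, seed) {
  if (block_size %% 4 != 0) {
    abort("block_size must be divisible by 4", class = "ruleswitch_argument_error")
  }
  stopifnot(n_trials >= 1)
  n_blocks <- ceiling(n_trials / block_size)
  stream <- rng_stream(seed)
  per_cond <- block_size %/% 4L
  conds <- task_conditions()
  idx <- unlist(lapply(seq_len(n_blocks), function(b) {
    stream$permute(rep(1:4, each = per_cond))
  }))
  idx <- idx[seq_len(n_trials)]
  tibble(
    trial = seq_len(n_trials),
    block = (seq_len(n_trials) - 1L) %/% block_size + 1L,
    condition = conds$condition[idx],
    cue_location = conds$cue_location[idx],
    cue_frequency = conds$cue_frequency[idx]
  )
}

# State index layout (22 states):
#   1        initial
#   2..5     cue states, one per condition
#   6..13    action states, (condition, side): 5 + (cond-1)*2 + side
#   14..21   outcome states, (condition, outcome): 13 + (cond-1)*2 + out
#            out = 1 reward, out = 2 no-reward
#   22       end (terminal, value fixed at 0)
state_labels <- function() {
  conds <- task_conditions()$condition
  c("initial",
    paste0("cue:", conds),
    as.vector(t(outer(conds, c("left", "right"),
                      function(c, a) paste0("action:", c, ":", a)))),
    as.vector(t(outer(conds, c("reward", "noreward"),
                      function(c, o) paste0("outcome:", c, ":", o)))),
    "end")
}

cue_index <- function(cond) 1L + cond
action_index <- function(cond, side) 5L + (cond - 1L) * 2L + side
outcome_index <- function(cond, out) 13L + (cond - 1L) * 2L + out

#' Construct a task environment
#'
#' Builds the 22-state episodic environment for one task rule: one initial
#' state, four cue states (one per condition), eight action states
#' (condition x side), eight outcome states (condition x reward/no-reward)
#' and one terminal end state. Entering the reward state yields +1,
#' entering the no-reward state yields -1. In the probabilistic variant
#' the action -> outcome transition is flipped with probability `p_flip`
#' (a correct action then leads to the no-reward state and vice versa).
#'
#' @param rule Task rule name.
#' @param probabilistic Logical; use the probabilistic outcome variant.
#' @param p_flip Flip probability for the probabilistic variant (default 0.1).
#' @return An object of class `task_env`: a list with the rule, the state
#'   table, per-condition correct actions, and outcome parameters.
#' @export
#' @examples
#' env <- make_environment("location")
#' env$states
make_environment <- function(rule, probabilistic = FALSE, p_flip = 0.1) {
  assert_rule(rule)
  stopifnot(p_flip >= 0, p_flip <= 1)
  conds <- task_conditions()
  labels <- state_labels()
  states <- tibble(
    state = seq_along(labels),
    label = labels,
    epoch = c("initial", rep("cue", 4), rep("action", 8), rep("outcome", 8), "end")
  )
  structure(
    list(
      rule = rule,
      states = states,
      n_states = length(labels),
      correct = match(correct_action(rule, conds$cue_location, conds$cue_frequency),
                      c("left", "right")),
      probabilistic = probabilistic,
      p_flip = if (probabilistic) p_flip else 0,
      reward = c(reward = 1, noreward = -1)
    ),
    class = "task_env"
  )
}

#' @export
print.task_env <- function(x, ...) {
  cat("<task_env> rule:", x$rule,
      if (x$probabilistic) sprintf("(probabilistic, p_flip = %g)", x$p_flip)
      else "(deterministic)", "\n")
  cat("  ", x$n_states, "states;",
      "correct actions:", paste(c("left", "right")[x$correct], collapse = ", "), "\n")
  invisible(x)
}

#' Single environment transition
#'
#' Advances the environment by one state transition. From the initial state
#' a cue state is drawn uniformly; in a cue state the supplied action
#' determines the action state; from an action state the outcome state is
#' reached (flipped with probability `p_flip` in the probabilistic
#' variant); from an outcome state the episode ends. Reward is nonzero only
#' on entering an outcome state: +1 (reward state) or -1 (no-reward state).
#'
#' @param env A [make_environment()] object.
#' @param state Current state index (1..22), non-terminal.
#' @param action `"left"`/`"right"` when `state` is a cue state; `NULL`
#'   (dummy) otherwise.
#' @param stream Optional [rng_stream()]; defaults to the global RNG.
#' @return List with `state` (next state index) and `reward`.
#' @export
#' @examples
#' env <- make_environment("location")
#' step1 <- env_step(env, 1)             # initial -> some cue state
#' env_step(env, step1$state, "left")    # cue -> action state
env_step <- function(env, state, action = NULL, stream = NULL) {
  stopifnot(inherits(env, "task_env"))
  runif1 <- if (is.null(stream)) function() runif(1) else function() stream$runif(1)
  epoch <- env$states$epoch[state]
  if (epoch == "end") {
    abort("end state is terminal", class = "ruleswitch_contract_error")
  }
  if (epoch == "cue") {
    if (is.null(action) || !action %in% c("left", "right")) {
      abort("a left/right action is required in a cue state",
            class = "ruleswitch_contract_error")
    }
  } else if (!is.null(action)) {
    abort("action supplied in a non-cue state", class = "ruleswitch_contract_error")
  }
  if (epoch == "initial") {
    cond <- ceiling(runif1() * 4)
    return(list(state = cue_index(cond), reward = 0))
  }
  if (epoch == "cue") {
    cond <- state - 1L
    side <- match(action, c("left", "right"))
    return(list(state = action_index(cond, side), reward = 0))
  }
  if (epoch == "action") {
    cond <- (state - 6L) %/% 2L + 1L
    side <- (state - 6L) %% 2L + 1L
    out <- if (side == env$correct[cond]) 1L else 2L
    if (env$probabilistic && runif1() < env$p_flip) out <- 3L - out
    r <- if (out == 1L) env$reward[["reward"]] else env$reward[["noreward"]]
    return(list(state = outcome_index(cond, out), reward = r))
  }
  # outcome -> end
  list(state = env$n_states, reward = 0)
}

#' Read / write an environment configuration
#'
#' Plain-text YAML holding the rule, the probabilistic flag and `p_flip`.
#'
#' @param env A `task_env` object (for writing).
#' @param path File path.
#' @return `read_env_config()` returns a `task_env`;
#'   `write_env_config()` returns `path` invisibly.
#' @export
write_env_config <- function(env, path) {
  stopifnot(inherits(env, "task_env"))
  yaml::write_yaml(
    list(rule = env$rule, probabilistic = env$probabilistic, p_flip = env$p_flip),
    path
  )
  invisible(path)
}

#' @rdname write_env_config
#' @export
read_env_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  make_environment(cfg$rule,
                   probabilistic = isTRUE(cfg$probabilistic),
                   p_flip = cfg$p_flip %||% 0.1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
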