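#' Run one simulated session
#'
#' Simulates `n_trials` episodes with online learning. Trial conditions
#' are drawn uniformly from the environment stream (the agent's initial
#' state transitions to each cue state with probability 1/4), unless a
#' blocked `schedule` is supplied.
#'
#' @param table A `value_table` (updated online; returned).
#' @param env A `task_env`.
#' @param params An [agent_params()].
#' @param bias Length-2 `(bias_left, bias_right)` for this session.
#' @param n_trials Number of trials (default 300).
#' @param policy_stream,env_stream [rng_stream()]s for action sampling and
#'   environment randomness (condition draws, outcome flips).
#' @param schedule Optional tibble from [generate_schedule()]; overrides
#'   the uniform condition draws.
#' @return List with the updated `table` and a tibble `trials` (one row
#'   per trial: condition, choice, correctness, reward, choice
#'   probability, and the TD error at each state entry).
#' @export
run_session <- function(table, env, params, bias = c(0, 0), n_trials = 300,
                        policy_stream, env_stream, schedule = NULL) {
  stopifnot(inherits(table, "value_table"), inherits(env, "task_env"))
  conds <- if (!is.null(schedule)) {
    stopifnot(nrow(schedule) == n_trials)
    match(schedule$condition, task_conditions()$condition)
  } else {
    env_stream$sample_int(4L, n_trials)
  }
  u_flip <- env_stream$runif(n_trials)
  u_choice <- policy_stream$runif(n_trials)

  Q <- table$Q
  V <- table$V
  choice <- integer(n_trials)
  correct <- logical(n_trials)
  rewarded <- logical(n_trials)
  r <- numeric(n_trials)
  p_left <- numeric(n_trials)
  d_cue <- numeric(n_trials); d_action <- numeric(n_trials)
  d_outcome <- numeric(n_trials); d_end <- numeric(n_trials)
  sv <- params$algorithm == "state_value"
  for (t in seq_len(n_trials)) {
    st <- trial_step(Q, V, env, params, bias[1], bias[2], conds[t],
                     u_choice[t], u_flip[t])
    Q <- st$Q; V <- st$V
    choice[t] <- st$choice; correct[t] <- st$correct
    rewarded[t] <- st$rewarded; r[t] <- st$r; p_left[t] <- st$p_left
    if (sv) {
      d_cue[t] <- st$v_cue; d_action[t] <- st$v_action
      d_outcome[t] <- st$v_outcome; d_end[t] <- st$v_end
    } else {
      d_cue[t] <- st$d_cue; d_action[t] <- st$d_action
      d_outcome[t] <- st$d_outcome; d_end[t] <- st$d_end
    }
  }
  table$Q <- Q
  table$V <- V
  cond_tbl <- task_conditions()
  trials <- tibble(
    trial = seq_len(n_trials),
    condition = cond_tbl$condition[conds],
    cue_location = cond_tbl$cue_location[conds],
    cue_frequency = cond_tbl$cue_frequency[conds],
    choice = c("left", "right")[choice],
    correct = correct, rewarded = rewarded, r = r, p_left = p_left,
    delta_cue = d_cue, delta_action = d_action,
    delta_outcome = d_outcome, delta_end = d_end
  )
  list(table = table, trials = trials)
}

#' Simulate a multi-rule training protocol
#'
#' Runs `n_agents` independent agents through the rule sequence. Within
#' each rule, 300-trial sessions are simulated until the agent has
#' performed two consecutive sessions at criterion (>= 80% correct overall
#' and >= 60% correct in each condition), after which the value reset
#' (`params$reset_mode`) is applied and the next rule begins. The
#' action-selection side bias is active during initial learning (location
#' rule) and after the within-dimension reversal (frequency_reversed rule,
#' where performance necessarily falls below chance), decaying across
#' sessions within the rule.
#'
#' Each agent draws from two independent RNG streams derived from `seed`:
#' a policy stream (action sampling, bias side) and an environment stream
#' (condition draws, probabilistic outcome flips).
#'
#' @param params An [agent_params()].
#' @param rules Ordered rule sequence (default all three rules).
#' @param n_trials_per_session Trials per session (default 300).
#' @param n_agents Number of agents (default 5).
#' @param max_sessions_per_rule Cap on sessions within one rule; an agent
#'   that fails to reach criterion is flagged non-convergent and its
#'   partial log returned.
#' @param criterion_sessions Consecutive criterion sessions required
#'   before the rule switches (default 2).
#' @param probabilistic,p_flip Outcome-flip variant of the environment.
#' @param seed Master seed; identical seeds give identical protocols.
#' @return An object of class `rl_protocol`: list with tibbles `trials`
#'   (per-trial logs with rule/session/stay-switch labels) and `sessions`
#'   (per-session summaries with stage and criterion flags), plus
#'   `params`, `converged` per agent, and `seed`.
#' @export
#' @examples
#' \donttest{
#' prot <- run_protocol(agent_params(), rules = "location",
#'                      max_sessions_per_rule = 10, n_agents = 2, seed = 1)
#' tidy(prot)
#' }
run_protocol <- function(params = agent_params(),
                         rules = task_rule_names(),
                         n_trials_per_session = 300, n_agents = 5,
                         max_sessions_per_rule = 50,
                         criterion_sessions = 2,
                         probabilistic = FALSE, p_flip = 0.1, seed = 1) {
  stopifnot(inherits(params, "agent_params"))
  for (r in rules) assert_rule(r)
  trial_logs <- list()
  session_logs <- list()
  converged <- setNames(logical(n_agents), paste0("agent", seq_len(n_agents)))

  for (ag in seq_len(n_agents)) {
    policy_stream <- rng_stream(derive_seed(seed, ag, 1L))
    env_stream <- rng_stream(derive_seed(seed, ag, 2L))
    side <- switch(params$bias_side,
      left = 1L, right = 2L,
      random = if (policy_stream$runif(1) < 0.5) 1L else 2L)
    table <- new_value_table()
    session_global <- 0L
    agent_ok <- TRUE

    for (ri in seq_along(rules)) {
      rule <- rules[ri]
      env <- make_environment(rule, probabilistic = probabilistic,
                              p_flip = p_flip)
      bias_active <- rule %in% c("location", "frequency_reversed")
      stay_map <- if (ri > 1) {
        conds <- task_conditions()
        setNames(classify_stay_switch(rules[ri - 1], rule,
                                      conds$cue_location, conds$cue_frequency),
                 conds$condition)
      } else NULL
      crit_run <- 0L
      k <- 0L
      reached <- FALSE
      while (k < max_sessions_per_rule) {
        bmag <- bias_magnitude(k, params$beta_bias0, params$lambda_bias,
                               active = bias_active, form = params$bias_decay)
        bias <- c(0, 0)
        bias[side] <- bmag
        out <- run_session(table, env, params, bias = bias,
                           n_trials = n_trials_per_session,
                           policy_stream = policy_stream,
                           env_stream = env_stream)
        table <- out$table
        k <- k + 1L
        session_global <- session_global + 1L
        tr <- out$trials
        tr$agent <- ag
        tr$rule <- rule
        tr$session <- session_global
        tr$session_in_rule <- k
        tr$stay_switch <- if (!is.null(stay_map)) {
          unname(stay_map[tr$condition])
        } else NA_character_
        trial_logs[[length(trial_logs) + 1L]] <- tr

        summ <- session_summary(tr)
        crit <- summ$criterion
        crit_run <- if (crit) crit_run + 1L else 0L
        session_logs[[length(session_logs) + 1L]] <- tibble(
          agent = ag, rule = rule, session = session_global,
          session_in_rule = k, n_trials = n_trials_per_session,
          fraction_correct = summ$fraction_correct,
          min_condition_correct = summ$min_condition_correct,
          stage = summ$stage, criterion = crit,
          bias_magnitude = bmag,
          abs_response_bias = summ$abs_response_bias
        )
        if (crit_run >= criterion_sessions) {
          reached <- TRUE
          break
        }
      }
      if (!reached) {
        agent_ok <- FALSE
        break  # partial log for this agent
      }
      if (ri < length(rules)) table <- apply_reset(table, params$reset_mode)
    }
    converged[ag] <- agent_ok
  }

  trials <- bind_rows(trial_logs)
  trials <- trials[, c("agent", "rule", "session", "session_in_rule",
                       "trial", "condition", "cue_location", "cue_frequency",
                       "stay_switch", "choice", "correct", "rewarded", "r",
                       "p_left", "delta_cue", "delta_action",
                       "delta_outcome", "delta_end")]
  structure(
    list(trials = trials, sessions = bind_rows(session_logs),
         params = params, converged = converged, seed = seed,
         rules = rules),
    class = "rl_protocol"
  )
}

#' @export
print.rl_protocol <- function(x, ...) {
  cat(sprintf("<rl_protocol> %s / %s reset: %d agents, %d sessions, %d trials\n",
              x$params$algorithm, x$params$reset_mode,
              length(x$converged), nrow(x$sessions), nrow(x$trials)))
  if (!all(x$converged)) {
    cat("  non-convergent agents:",
        paste(which(!x$converged), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn run_protocol Per-session summary tibble (accuracy, stage,
#'   criterion, bias magnitude).
#' @param x An `rl_protocol`.
#' @param ... Unused.
#' @method tidy rl_protocol
#' @export
tidy.rl_protocol <- function(x, ...) x$sessions

#' @describeIn run_protocol One-row overview of the simulated protocol.
#' @method glance rl_protocol
#' @export
glance.rl_protocol <- function(x, ...) {
  tibble(
    algorithm = x$params$algorithm, reset_mode = x$params$reset_mode,
    n_agents = length(x$converged), n_sessions = nrow(x$sessions),
    n_trials = nrow(x$trials), all_converged = all(x$converged)
  )
}

#' Extract reward prediction errors from a protocol
#'
#' Selects per-trial TD errors for one trial epoch, with exact filtering
#' on the logged labels (correctness, stay/switch class, session stage,
#' rule). Averaging is left to the caller.
#'
#' @param protocol An [run_protocol()] result.
#' @param epoch `"cue"`, `"action"`, `"outcome"` or `"end"`. Cue-epoch
#'   RPEs are the TD errors of entering the cue state.
#' @param correct Optional logical filter on trial correctness.
#' @param stay_switch Optional `"stay"`/`"switch"` filter.
#' @param stage Optional stage filter (`"novice"`, `"intermediate"`,
#'   `"expert"`).
#' @param rule Optional rule filter.
#' @param session_in_rule Optional session-within-rule filter (e.g. `1`
#'   for the first post-switch session).
#' @return Tibble with trial identifiers, labels and the selected `delta`.
#' @export
extract_rpes <- function(protocol, epoch = c("cue", "outcome", "action", "end"),
                         correct = NULL, stay_switch = NULL, stage = NULL,
                         rule = NULL, session_in_rule = NULL) {
  stopifnot(inherits(protocol, "rl_protocol"))
  epoch <- match.arg(epoch)
  col <- paste0("delta_", epoch)
  df <- protocol$trials %>%
    left_join(protocol$sessions %>% select("agent", "session", "stage"),
              by = c("agent", "session"))
  if (!is.null(correct)) df <- df[df$correct == correct, ]
  if (!is.null(stay_switch)) df <- df[!is.na(df$stay_switch) &
                                        df$stay_switch %in% stay_switch, ]
  if (!is.null(stage)) df <- df[df$stage %in% stage, ]
  if (!is.null(rule)) df <- df[df$rule %in% rule, ]
  if (!is.null(session_in_rule)) df <- df[df$session_in_rule %in% session_in_rule, ]
  df$delta <- df[[col]]
  df$epoch <- epoch
  df %>%
    select("agent", "rule", "session", "session_in_rule", "trial",
           "condition", "stay_switch", "stage", "correct", "epoch", "delta") %>%
    as_tibble()
}
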