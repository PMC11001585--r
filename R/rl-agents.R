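#' Agent parameter set
#'
#' Bundles the parameters of a temporal-difference agent. Defaults are the
#' values used for all simulations: learning rate `alpha = 0.003` for
#' state-action learning (`0.015` for the state-value learner), discount
#' `gamma = 1`, softmax inverse temperature `beta = 6`, initial side bias
#' `beta_bias0 = 0.4` decaying across sessions with constant
#' `lambda_bias = 0.4`.
#'
#' The `state_value` algorithm learns a state-value table V(s) on episodes
#' generated by a SARSA state-action policy with the same settings; its
#' logged TD errors are the state-value prediction errors.
#'
#' @param algorithm `"sarsa"` (on-policy), `"qlearning"` (off-policy) or
#'   `"state_value"`.
#' @param alpha Learning rate; default 0.003, or 0.015 for `state_value`.
#' @param gamma Discount factor in `[0, 1]`.
#' @param beta Softmax inverse temperature (>= 0); 0 gives random choice.
#' @param beta_bias0 Initial magnitude of the action-selection side bias.
#' @param lambda_bias Exponential decay constant of the bias across
#'   sessions within a rule.
#' @param reset_mode Value reset applied at each rule switch: `"none"`,
#'   `"partial"` (cue-state action values retained, everything else
#'   zeroed) or `"complete"`.
#' @param bias_side `"left"`, `"right"` or `"random"` (drawn once per
#'   agent from its policy stream).
#' @param bias_decay `"exponential"` (default) or `"geometric"` decay of
#'   the bias across sessions.
#' @return An object of class `agent_params`.
#' @export
#' @examples
#' agent_params()
#' agent_params("qlearning", reset_mode = "none")
agent_params <- function(algorithm = c("sarsa", "qlearning", "state_value"),
                         alpha = NULL, gamma = 1, beta = 6,
                         beta_bias0 = 0.4, lambda_bias = 0.4,
                         reset_mode = c("partial", "none", "complete"),
                         bias_side = c("random", "left", "right"),
                         bias_decay = c("exponential", "geometric")) {
  algorithm <- match.arg(algorithm)
  reset_mode <- match.arg(reset_mode)
  bias_side <- match.arg(bias_side)
  bias_decay <- match.arg(bias_decay)
  if (is.null(alpha)) alpha <- if (algorithm == "state_value") 0.015 else 0.003
  stopifnot(alpha > 0, beta >= 0, gamma >= 0, gamma <= 1,
            beta_bias0 >= 0, lambda_bias >= 0)
  structure(
    list(algorithm = algorithm, alpha = alpha, gamma = gamma, beta = beta,
         beta_bias0 = beta_bias0, lambda_bias = lambda_bias,
         reset_mode = reset_mode, bias_side = bias_side,
         bias_decay = bias_decay,
         # state-action learning rate used for the policy when the logged
         # learner is the state-value observer
         alpha_policy = if (algorithm == "state_value") 0.003 else alpha),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "<agent_params> %s: alpha=%g gamma=%g beta=%g bias0=%g lambda=%g reset=%s side=%s\n",
    x$algorithm, x$alpha, x$gamma, x$beta, x$beta_bias0, x$lambda_bias,
    x$reset_mode, x$bias_side))
  invisible(x)
}

#' Fresh value table
#'
#' State-action values Q(s, a) and state values V(s) for the 22-state task
#' environment, all initialized to 0. The terminal end state stays at 0.
#'
#' @return An object of class `value_table`: list with matrix `Q`
#'   (22 x 2, columns left/right) and vector `V` (length 22).
#' @export
new_value_table <- function() {
  labels <- state_labels()
  Q <- matrix(0, nrow = length(labels), ncol = 2,
              dimnames = list(labels, c("left", "right")))
  V <- setNames(numeric(length(labels)), labels)
  structure(list(Q = Q, V = V), class = "value_table")
}

#' Reset learned values at a rule switch
#'
#' `"none"` leaves the table untouched, `"complete"` zeroes everything,
#' and `"partial"` zeroes everything except the cue-state action values
#' (Q_L and Q_R per condition) -- the choice-guiding information learned
#' under the previous rule. The state-value table keeps cue-state values
#' under partial reset, analogously.
#'
#' @param table A [new_value_table()] object.
#' @param mode `"none"`, `"partial"` or `"complete"`.
#' @return The reset `value_table`.
#' @export
apply_reset <- function(table, mode = c("partial", "none", "complete")) {
  stopifnot(inherits(table, "value_table"))
  if (length(mode) != 1L || !mode %in% c("none", "partial", "complete")) {
    abort("unknown reset mode", class = "ruleswitch_config_error")
  }
  if (mode == "none") return(table)
  keep_q <- if (mode == "partial") table$Q[2:5, , drop = FALSE] else NULL
  keep_v <- if (mode == "partial") table$V[2:5] else NULL
  out <- new_value_table()
  if (!is.null(keep_q)) {
    out$Q[2:5, ] <- keep_q
    out$V[2:5] <- keep_v
  }
  out
}

#' Softmax action selection with side bias
#'
#' Choice probability
#' `P(left) = exp(beta (Q_L + b_L)) / (exp(beta (Q_L + b_L)) + exp(beta (Q_R + b_R)))`,
#' computed via the logistic identity (overflow-safe). At `beta = 0` the
#' choice is random.
#'
#' @param q_left,q_right State-action values of the two actions.
#' @param beta Inverse temperature.
#' @param bias_left,bias_right Additive side-bias terms.
#' @param stream Optional [rng_stream()] used to sample the action;
#'   defaults to the global RNG.
#' @return List with `action` (`"left"`/`"right"`) and `p_left`.
#' @export
#' @examples
#' softmax_choice(1, 0, beta = 6)$p_left  # ~0.9975
softmax_choice <- function(q_left, q_right, beta, bias_left = 0,
                           bias_right = 0, stream = NULL) {
  stopifnot(is.finite(q_left), is.finite(q_right), is.finite(beta))
  p_left <- stats::plogis(beta * ((q_left + bias_left) - (q_right + bias_right)))
  u <- if (is.null(stream)) runif(1) else stream$runif(1)
  list(action = if (u < p_left) "left" else "right", p_left = p_left)
}

#' Session-decaying side bias magnitude
#'
#' The action-selection bias starts at `beta_bias0` and decays to 0 across
#' sessions within a rule: exponentially,
#' `beta_bias0 * exp(-lambda_bias * k)` with `k` the 0-based session index,
#' or geometrically, `beta_bias0 * (1 - lambda_bias)^k`. It applies to the
#' biased side only; the other side's bias is 0. When `active = FALSE`
#' (rules learned without a bias) the magnitude is 0.
#'
#' @param session_index 0-based session index within the current rule.
#' @param beta_bias0,lambda_bias Initial magnitude and decay constant.
#' @param active Logical; whether the bias is in effect for this rule.
#' @param form `"exponential"` or `"geometric"`.
#' @return Numeric bias magnitude.
#' @export
#' @examples
#' bias_magnitude(0, 0.4, 0.4)         # 0.4
#' bias_magnitude(1, 0.4, 0.4)         # 0.4 * exp(-0.4)
bias_magnitude <- function(session_index, beta_bias0 = 0.4, lambda_bias = 0.4,
                           active = TRUE, form = c("exponential", "geometric")) {
  form <- match.arg(form)
  if (any(session_index < 0)) {
    abort("session_index must be >= 0", class = "ruleswitch_argument_error")
  }
  if (!active) return(0 * session_index)
  if (form == "exponential") beta_bias0 * exp(-lambda_bias * session_index)
  else beta_bias0 * (1 - lambda_bias)^session_index
}

#' Temporal-difference errors
#'
#' The TD error on a transition is the reward prediction error of entering
#' the next state. For the on-policy SARSA agent it bootstraps from the
#' value of the action actually chosen in the next state,
#' `delta = r' + gamma Q(s', a') - Q(s, a)`; off-policy Q-learning uses the
#' maximum next-state action value; the state-value learner uses V(s').
#'
#' @param r_next Reward received on the transition.
#' @param q_next Value of the chosen next action (SARSA).
#' @param q_next_values Vector of next-state action values (Q-learning).
#' @param q_current Current state-action value.
#' @param v_next,v_current State values (state-value learner).
#' @param gamma Discount factor.
#' @return The TD error, a numeric scalar (vectorized over inputs).
#' @export
#' @examples
#' td_error_sarsa(1, 0, 0, 1)        # +1: unexpected first reward
#' td_error_qlearning(0, c(0.3, 0.9), 0, 1)  # 0.9
td_error_sarsa <- function(r_next, q_next, q_current, gamma) {
  r_next + gamma * q_next - q_current
}

#' @rdname td_error_sarsa
#' @export
td_error_qlearning <- function(r_next, q_next_values, q_current, gamma) {
  r_next + gamma * max(q_next_values) - q_current
}

#' @rdname td_error_sarsa
#' @export
td_error_state <- function(r_next, v_next, v_current, gamma) {
  r_next + gamma * v_next - v_current
}

#' Apply a TD update to a value table
#'
#' Increments the targeted entry by `alpha * delta`. In non-cue states a
#' dummy action is taken and both action slots are set to the same value
#' after the update; the terminal end state is never updated (attempts are
#' ignored with a warning).
#'
#' @param table A `value_table`.
#' @param state State index (1..22).
#' @param action `"left"`/`"right"` in a cue state, `NULL` (dummy)
#'   otherwise.
#' @param delta TD error.
#' @param alpha Learning rate.
#' @return The updated `value_table`.
#' @export
update_values <- function(table, state, action = NULL, delta, alpha) {
  stopifnot(inherits(table, "value_table"))
  if (state == nrow(table$Q)) {
    warn("update to terminal end state ignored")
    return(table)
  }
  is_cue <- state >= 2 && state <= 5
  if (is_cue) {
    if (is.null(action)) {
      abort("cue-state update requires the chosen action",
            class = "ruleswitch_contract_error")
    }
    j <- match(action, c("left", "right"))
    table$Q[state, j] <- table$Q[state, j] + alpha * delta
  } else {
    val <- table$Q[state, 1] + alpha * delta
    table$Q[state, ] <- val  # dummy action: keep both slots equal
  }
  table$V[state] <- table$V[state] + alpha * delta
  table
}

# Core per-trial simulation shared by run_trial() and run_session().
# Q: 22x2 matrix, V: length-22 vector, cond: integer 1..4,
# u_choice/u_flip: uniforms, forced: NULL or 1/2.
# Returns updated Q, V and the trial log scalars.
trial_step <- function(Q, V, env, params, bias_l, bias_r, cond,
                       u_choice, u_flip, forced = NULL) {
  g <- params$gamma
  a_pol <- params$alpha_policy
  a_v <- params$alpha
  cue <- cue_index(cond)
  p_left <- stats::plogis(params$beta *
    ((Q[cue, 1] + bias_l) - (Q[cue, 2] + bias_r)))
  a <- if (!is.null(forced)) forced else if (u_choice < p_left) 1L else 2L

  # entering the cue state (from initial)
  d_cue_sarsa <- g * Q[cue, a] - Q[1, 1]
  d_cue_q <- g * max(Q[cue, 1], Q[cue, 2]) - Q[1, 1]
  d_cue <- if (params$algorithm == "qlearning") d_cue_q else d_cue_sarsa
  v_cue <- g * V[cue] - V[1]
  Q[1, ] <- Q[1, 1] + a_pol * d_cue
  V[1] <- V[1] + a_v * v_cue

  # entering the action state
  act <- action_index(cond, a)
  d_action <- g * Q[act, 1] - Q[cue, a]
  v_action <- g * V[act] - V[cue]
  Q[cue, a] <- Q[cue, a] + a_pol * d_action
  V[cue] <- V[cue] + a_v * v_action

  # entering the outcome state
  correct <- a == env$correct[cond]
  out <- if (correct) 1L else 2L
  if (env$probabilistic && u_flip < env$p_flip) out <- 3L - out
  r <- if (out == 1L) env$reward[["reward"]] else env$reward[["noreward"]]
  ost <- outcome_index(cond, out)
  d_outcome <- r + g * Q[ost, 1] - Q[act, 1]
  v_outcome <- r + g * V[ost] - V[act]
  Q[act, ] <- Q[act, 1] + a_pol * d_outcome
  V[act] <- V[act] + a_v * v_outcome

  # entering the terminal end state (value fixed at 0)
  d_end <- -Q[ost, 1]
  v_end <- -V[ost]
  Q[ost, ] <- Q[ost, 1] + a_pol * d_end
  V[ost] <- V[ost] + a_v * v_end

  list(Q = Q, V = V, choice = a, correct = correct, rewarded = out == 1L,
       r = r, p_left = p_left,
       d_cue = d_cue, d_action = d_action, d_outcome = d_outcome,
       d_end = d_end,
       v_cue = v_cue, v_action = v_action, v_outcome = v_outcome,
       v_end = v_end)
}

#' Run a single trial episode
#'
#' One episode visits initial -> cue -> action -> outcome -> end. One TD
#' error is logged per state entry beyond the initial state (plus the
#' entry into the terminal end state), and values are updated online.
#' For SARSA the next action is selected before the cue-state entry is
#' evaluated.
#'
#' @param table A `value_table`.
#' @param env A `task_env`.
#' @param condition Condition label (e.g. `"left-low"`) or index 1..4.
#' @param params An [agent_params()] object.
#' @param bias Length-2 numeric `(bias_left, bias_right)`.
#' @param forced_action Optional `"left"`/`"right"` to bypass the softmax.
#' @param stream Optional policy [rng_stream()].
#' @param env_stream Optional environment [rng_stream()] (probabilistic
#'   outcome flips).
#' @return List with the updated `table` and a one-row tibble `log`
#'   containing the choice, outcome and the TD error at each state entry
#'   (`delta_cue`, `delta_action`, `delta_outcome`, `delta_end`). For the
#'   `state_value` algorithm the deltas are state-value TD errors.
#' @export
#' @examples
#' env <- make_environment("location")
#' run_trial(new_value_table(), env, "left-low", agent_params(),
#'           forced_action = "left")$log
run_trial <- function(table, env, condition, params = agent_params(),
                      bias = c(0, 0), forced_action = NULL, stream = NULL,
                      env_stream = NULL) {
  stopifnot(inherits(table, "value_table"), inherits(env, "task_env"))
  cond <- if (is.character(condition)) {
    match(condition, task_conditions()$condition)
  } else as.integer(condition)
  if (is.na(cond) || cond < 1 || cond > 4) {
    abort("unknown condition", class = "ruleswitch_argument_error")
  }
  forced <- if (!is.null(forced_action)) match(forced_action, c("left", "right"))
  u_choice <- if (is.null(stream)) runif(1) else stream$runif(1)
  u_flip <- if (is.null(env_stream)) runif(1) else env_stream$runif(1)
  st <- trial_step(table$Q, table$V, env, params, bias[1], bias[2], cond,
                   u_choice, u_flip, forced)
  table$Q <- st$Q
  table$V <- st$V
  sv <- params$algorithm == "state_value"
  log <- tibble::new_tibble(list(
    condition = task_conditions()$condition[cond],
    choice = c("left", "right")[st$choice],
    correct = st$correct, rewarded = st$rewarded, r = st$r,
    p_left = st$p_left,
    delta_cue = if (sv) st$v_cue else st$d_cue,
    delta_action = if (sv) st$v_action else st$d_action,
    delta_outcome = if (sv) st$v_outcome else st$d_outcome,
    delta_end = if (sv) st$v_end else st$d_end
  ), nrow = 1L)
  list(table = table, log = log)
}
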