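#' Predictor sets for the session-based choice model
#'
#' The final model uses the current trial's cue location and cue
#' frequency (coded -1 left/low, +1 right/high) and the reward-rate
#' difference between spouts. `choice_predictor_names()` lists every
#' predictor [build_regressors()] can construct.
#'
#' @return Character vector of predictor names.
#' @export
choice_predictors_full <- function() {
  c("cue_location", "cue_frequency", "delta_reward_rate")
}

#' @rdname choice_predictors_full
#' @export
choice_predictor_names <- function() {
  c("cue_location", "cue_frequency", "delta_reward_rate",
    "reward_rate_left", "reward_rate_right",
    paste0("choice_history_", 1:3),
    "win_stay", "lose_switch", "prev_choice", "prev_outcome",
    paste0("choice_outcome_", 1:3),
    "cue_interaction",
    paste0("cue_location_history_", 1:3),
    paste0("cue_frequency_history_", 1:3))
}

# exponentially weighted reward rate per spout, up to and including the
# previous trial; smoothing factor 2 / (memory + 1), state starts at 0.
ewma_prev <- function(x, memory) {
  lambda <- 2 / (memory + 1)
  n <- length(x)
  s <- numeric(n + 1)
  for (t in seq_len(n)) s[t + 1] <- lambda * x[t] + (1 - lambda) * s[t]
  s[seq_len(n)]  # value entering trial t uses trials 1..t-1
}

#' Reward-rate difference between spouts
#'
#' Ten-trial exponentially weighted average of rewards obtained on each
#' spout (reward indicator 1 when that spout was chosen and rewarded,
#' else 0), computed up to and including the previous trial; the
#' difference left minus right ranges between -1 and +1 and is 0 on the
#' first trial.
#'
#' @param trials Trial tibble with `choice` and `rewarded` (or `correct`)
#'   columns.
#' @param memory Memory in trials for the exponential weighting
#'   (smoothing factor `2 / (memory + 1)`); default 10.
#' @return Numeric vector, one value per trial.
#' @export
delta_reward_rate <- function(trials, memory = 10) {
  rew <- reward_indicator(trials)
  left <- ewma_prev(as.numeric(rew & trials$choice == "left"), memory)
  right <- ewma_prev(as.numeric(rew & trials$choice == "right"), memory)
  left - right
}

reward_indicator <- function(trials) {
  if ("rewarded" %in% names(trials)) trials$rewarded else trials$correct
}

lag0 <- function(x, k) c(rep(0, k), head(x, -k))

#' Build the design matrix for the choice model
#'
#' Codes the requested predictors per trial, each in `[-1, +1]`:
#' cue location/frequency (-1 left/low, +1 right/high), reward-rate
#' terms, choice history at lags 1-3, win-stay and lose-switch (signed
#' previous choice gated on previous-trial outcome), previous choice and
#' outcome and their interactions up to lag 3, the cue interaction, and
#' cue history at lags 1-3. History terms are 0 where the lag extends
#' before the first trial. Predictors are not standardized. The response
#' `y` is 0 for a left and 1 for a right choice.
#'
#' @param trials Trial tibble with `cue_location`, `cue_frequency`,
#'   `choice`, and `rewarded` (or `correct`) columns.
#' @param predictors Character vector of predictor names (see
#'   [choice_predictor_names()]).
#' @return Tibble with column `y` followed by one column per predictor.
#' @export
#' @examples
#' trials <- simulate_behavior_parametric(n_trials = 20, seed = 1)
#' build_regressors(trials, c("cue_location", "delta_reward_rate"))
build_regressors <- function(trials, predictors = choice_predictors_full()) {
  unknown <- setdiff(predictors, choice_predictor_names())
  if (length(unknown) > 0) {
    abort(paste("unknown predictor(s):", paste(unknown, collapse = ", ")),
          class = "ruleswitch_config_error")
  }
  loc <- ifelse(trials$cue_location == "right", 1, -1)
  freq <- ifelse(trials$cue_frequency == "high", 1, -1)
  ch <- ifelse(trials$choice == "right", 1, -1)
  rew <- reward_indicator(trials)
  outc <- ifelse(rew, 1, -1)
  memory <- 10
  make <- function(p) {
    switch(p,
      cue_location = loc,
      cue_frequency = freq,
      delta_reward_rate = delta_reward_rate(trials, memory),
      reward_rate_left = ewma_prev(as.numeric(rew & trials$choice == "left"),
                                   memory),
      reward_rate_right = ewma_prev(as.numeric(rew & trials$choice == "right"),
                                    memory),
      choice_history_1 = lag0(ch, 1),
      choice_history_2 = lag0(ch, 2),
      choice_history_3 = lag0(ch, 3),
      win_stay = lag0(ifelse(rew, ch, 0), 1),
      lose_switch = lag0(ifelse(rew, 0, ch), 1),
      prev_choice = lag0(ch, 1),
      prev_outcome = lag0(outc, 1),
      choice_outcome_1 = lag0(ch * outc, 1),
      choice_outcome_2 = lag0(ch * outc, 2),
      choice_outcome_3 = lag0(ch * outc, 3),
      cue_interaction = loc * freq,
      cue_location_history_1 = lag0(loc, 1),
      cue_location_history_2 = lag0(loc, 2),
      cue_location_history_3 = lag0(loc, 3),
      cue_frequency_history_1 = lag0(freq, 1),
      cue_frequency_history_2 = lag0(freq, 2),
      cue_frequency_history_3 = lag0(freq, 3)
    )
  }
  out <- tibble(y = as.integer(trials$choice == "right"))
  for (p in predictors) out[[p]] <- make(p)
  out
}

#' Fit the logistic choice model by gradient descent
#'
#' Models the per-trial choice probability as
#' `y_hat = 1 / (1 + exp(-z))` with `z = sum_p beta_p x_p + beta_0`, and
#' minimizes the negative log-likelihood
#' `J = -(1/m) sum_i [y_i log y_hat_i + (1 - y_i) log(1 - y_hat_i)]`
#' by batch gradient descent with a backtracking step size (halved on a
#' loss increase). No regularization is applied. Optimization stops when
#' the loss falls below `tol_loss`, when the gradient infinity-norm falls
#' below `tol_grad`, or at `max_iter` (non-converged; occurs under
#' perfect separation, where the likelihood has no finite optimum).
#'
#' @param design Design tibble from [build_regressors()] (`y` plus
#'   predictor columns).
#' @param tol_loss Loss stopping threshold (default `1e-4`).
#' @param tol_grad Gradient infinity-norm stopping threshold.
#' @param max_iter Iteration cap (default 50000).
#' @param step0 Initial step size.
#' @param keep_path Record the loss after every accepted iteration
#'   (element `loss_path`).
#' @return An object of class `choice_fit` with elements `coefficients`
#'   (intercept first), `loss`, `iterations`, `converged`, `degenerate`
#'   (single response class), `predictors`, `n`.
#' @export
#' @examples
#' trials <- simulate_behavior_parametric(n_trials = 300, seed = 2)
#' fit <- fit_logistic(build_regressors(trials))
#' tidy(fit)
fit_logistic <- function(design, tol_loss = 1e-4, tol_grad = 1e-7,
                         max_iter = 50000, step0 = 1, keep_path = FALSE) {
  stopifnot("y" %in% names(design))  # zero predictors = bias-only model
  y <- design$y
  X <- cbind(`(Intercept)` = 1, as.matrix(design[setdiff(names(design), "y")]))
  m <- length(y)
  degenerate <- length(unique(y)) < 2
  if (degenerate) warn("single response class: intercept-driven degenerate fit")
  beta <- numeric(ncol(X))
  eps <- 1e-12
  loss_fn <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  }
  J <- loss_fn(beta)
  step <- step0
  iter <- 0L
  converged <- FALSE
  path <- if (keep_path) J
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- stats::plogis(drop(X %*% beta))
    grad <- drop(crossprod(X, p - y)) / m
    if (J < tol_loss || max(abs(grad)) < tol_grad) {
      converged <- TRUE
      break
    }
    repeat {
      cand <- beta - step * grad
      Jc <- loss_fn(cand)
      if (Jc <= J || step < 1e-12) break
      step <- step / 2
    }
    beta <- cand
    J <- Jc
    if (keep_path) path <- c(path, J)
    step <- min(step * 1.1, 1e3)
  }
  structure(
    list(coefficients = setNames(beta, colnames(X)), loss = J,
         iterations = iter, converged = converged && !degenerate,
         degenerate = degenerate,
         loss_path = if (keep_path) path,
         predictors = setdiff(names(design), "y"), n = m),
    class = "choice_fit"
  )
}

#' @export
print.choice_fit <- function(x, ...) {
  cat(sprintf("<choice_fit> %d trials, J = %.4g, %d iterations%s\n",
              x$n, x$loss, x$iterations,
              if (x$converged) "" else " (not converged)"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @describeIn fit_logistic Coefficients as a tibble (`term`, `estimate`).
#' @param x,object A `choice_fit`.
#' @param ... Unused.
#' @method tidy choice_fit
#' @export
tidy.choice_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @describeIn fit_logistic One-row fit summary.
#' @method glance choice_fit
#' @export
glance.choice_fit <- function(x, ...) {
  tibble(loss = x$loss, iterations = x$iterations, converged = x$converged,
         degenerate = x$degenerate, n = x$n)
}

#' @describeIn fit_logistic Predicted choice probabilities or classes for
#'   new data. Probabilities exactly at 0.5 round to class 1.
#' @param newdata Design tibble (a `y` column, if present, is ignored).
#' @param type `"response"` (probability of a right choice) or `"class"`.
#' @export
predict.choice_fit <- function(object, newdata, type = c("response", "class"),
                               ...) {
  type <- match.arg(type)
  X <- cbind(1, as.matrix(newdata[object$predictors]))
  p <- stats::plogis(drop(X %*% object$coefficients))
  if (type == "response") p else as.integer(p >= 0.5)
}

#' Cross-validated prediction accuracy
#'
#' Ten-fold cross-validation of the logistic choice model: trials are
#' randomly partitioned into folds (stratified by response class so both
#' classes appear in every training set), each fold is predicted from a
#' model fit on the others, and every trial appears in the test set
#' exactly once. Accuracy is computed over the pooled test predictions.
#'
#' @param design Design tibble from [build_regressors()].
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment (same seed, same
#'   folds).
#' @param ... Passed to [fit_logistic()].
#' @return Accuracy in `[0, 1]`, with the per-trial fold assignment and
#'   pooled predictions attached as attributes `folds` and `predictions`.
#' @export
crossval_accuracy <- function(design, folds = 10, seed = 1, ...) {
  y <- design$y
  stream <- rng_stream(derive_seed(seed, 97L))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- stream$permute(rep_len(seq_len(folds), length(idx)))
  }
  pred <- integer(length(y))
  for (f in sort(unique(fold))) {
    test <- fold == f
    fit <- fit_logistic(design[!test, , drop = FALSE], ...)
    pred[test] <- predict(fit, design[test, , drop = FALSE], type = "class")
  }
  acc <- mean(pred == y)
  attr(acc, "folds") <- fold
  attr(acc, "predictions") <- tibble(y = y, predicted = pred, fold = fold)
  acc
}

#' Compare the full choice model to reduced and alternative models
#'
#' Computes the cross-validated accuracy of a base predictor set and of
#' each variant on the same trials with matched fold assignments, and the
#' accuracy difference base minus variant. Positive differences indicate
#' the variant predicts worse than the base model.
#'
#' @param trials Trial tibble (see [build_regressors()]).
#' @param base Base predictor set (default [choice_predictors_full()]).
#' @param variants Named list of predictor sets; default
#'   [choice_model_variants()].
#' @param folds,seed Cross-validation settings shared by all models.
#' @param ... Passed to [fit_logistic()].
#' @return Tibble with `model`, `accuracy`, `delta_accuracy`
#'   (base minus variant; 0 for the base row).
#' @export
compare_models <- function(trials, base = choice_predictors_full(),
                           variants = choice_model_variants(),
                           folds = 10, seed = 1, ...) {
  acc_base <- as.numeric(crossval_accuracy(build_regressors(trials, base),
                                           folds = folds, seed = seed, ...))
  rows <- purrr::imap(variants, function(preds, name) {
    acc <- as.numeric(crossval_accuracy(build_regressors(trials, preds),
                                        folds = folds, seed = seed, ...))
    tibble(model = name, accuracy = acc, delta_accuracy = acc_base - acc)
  })
  bind_rows(tibble(model = "base", accuracy = acc_base, delta_accuracy = 0),
            bind_rows(rows))
}

#' @rdname compare_models
#' @export
choice_model_variants <- function(base = choice_predictors_full()) {
  hist_free <- setdiff(base, "delta_reward_rate")
  c(
    lapply(setNames(base, paste0("remove_", base)), function(p) setdiff(base, p)),
    list(
      reward_rate_lr_instead = c(hist_free, "reward_rate_left", "reward_rate_right"),
      choice_history_instead = c(hist_free, paste0("choice_history_", 1:3)),
      win_stay_lose_switch_instead = c(hist_free, "win_stay", "lose_switch"),
      prev_choice_instead = c(hist_free, "prev_choice"),
      add_choice_outcome = c(base, "prev_choice", "prev_outcome",
                             "choice_outcome_1"),
      add_win_stay_lose_switch = c(base, "win_stay", "lose_switch"),
      add_cue_interaction = c(base, "cue_interaction"),
      add_cue_history = c(base, paste0("cue_location_history_", 1:3),
                          paste0("cue_frequency_history_", 1:3))
    )
  )
}
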