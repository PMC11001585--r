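# Hand-built six-trial session used for regressor coding checks.
hand_trials <- tibble::tibble(
  cue_location  = c("left", "right", "right", "left", "right", "left"),
  cue_frequency = c("low", "high", "low", "low", "high", "high"),
  choice        = c("left", "right", "left", "left", "right", "right"),
  correct       = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
  rewarded      = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
)

test_that("regressor coding matches the hand-computed table", {
  X <- build_regressors(hand_trials, choice_predictor_names())
  expect_equal(X$y, c(0L, 1L, 0L, 0L, 1L, 1L))
  expect_equal(X$cue_location, c(-1, 1, 1, -1, 1, -1))
  expect_equal(X$cue_frequency, c(-1, 1, -1, -1, 1, 1))
  expect_equal(X$cue_interaction, c(1, 1, -1, 1, 1, -1))
  expect_equal(X$choice_history_1, c(0, -1, 1, -1, -1, 1))
  expect_equal(X$choice_history_2, c(0, 0, -1, 1, -1, -1))
  expect_equal(X$choice_history_3, c(0, 0, 0, -1, 1, -1))
  expect_equal(X$prev_choice, X$choice_history_1)
  expect_equal(X$prev_outcome, c(0, 1, 1, -1, 1, 1))
  # win-stay: signed previous choice after a correct trial, else 0
  expect_equal(X$win_stay, c(0, -1, 1, 0, -1, 1))
  expect_equal(X$lose_switch, c(0, 0, 0, -1, 0, 0))
  expect_equal(X$choice_outcome_1, c(0, -1, 1, 1, -1, 1))
  expect_equal(X$cue_location_history_1, c(0, -1, 1, 1, -1, 1))
  expect_equal(X$cue_frequency_history_1, c(0, -1, 1, -1, -1, 1))
  expect_error(build_regressors(hand_trials, "moon_phase"),
               class = "ruleswitch_config_error")
})

test_that("reward-rate difference follows the hand-unrolled recursion", {
  lam <- 2 / 11
  # left rewarded on trials 1 and 4, right on trials 2 and 5
  el <- c(0, lam, (1 - lam) * lam, (1 - lam)^2 * lam,
          (1 - lam)^3 * lam + lam, (1 - lam)^4 * lam + (1 - lam) * lam)
  er <- c(0, 0, lam, (1 - lam) * lam, (1 - lam)^2 * lam,
          (1 - lam)^3 * lam + lam)
  expect_equal(delta_reward_rate(hand_trials), el - er)
  # no rewards anywhere: flat zero
  none <- hand_trials
  none$rewarded <- FALSE
  expect_equal(delta_reward_rate(none), rep(0, 6))
  # left-only rewards saturate towards +1
  lefty <- tibble::tibble(choice = rep("left", 200), rewarded = TRUE)
  expect_gt(delta_reward_rate(lefty)[200], 0.999)
  expect_true(all(abs(delta_reward_rate(lefty)) <= 1))
})

test_that("gradient descent matches the maximum-likelihood oracle", {
  for (s in 1:3) {
    tr <- simulate_behavior_parametric(
      n_trials = 300, w_cue_location = 1.2, w_bias = 0.4, w_history = 0.3,
      lapse = 0.05, seed = s)
    X <- build_regressors(tr, c("cue_location", "cue_frequency",
                                "delta_reward_rate", "prev_choice"))
    fit <- fit_logistic(X)
    expect_true(fit$converged)
    oracle <- stats::glm(y ~ ., data = X, family = stats::binomial)
    expect_lt(max(abs(fit$coefficients - coef(oracle)[names(fit$coefficients)])),
              1e-3)
    acc_gd <- mean(predict(fit, X, type = "class") == X$y)
    acc_ml <- mean((stats::predict(oracle, type = "response") >= 0.5) == X$y)
    expect_lt(abs(acc_gd - acc_ml), 0.01)
  }
})

test_that("the loss is non-increasing across accepted iterations", {
  tr <- simulate_behavior_parametric(n_trials = 400, seed = 4)
  fit <- fit_logistic(build_regressors(tr), keep_path = TRUE)
  expect_true(all(diff(fit$loss_path) <= 0))
})

test_that("a separable predictor yields perfect training accuracy", {
  y <- rep(c(0L, 1L), 20)
  X <- tibble::tibble(y = y, cue_location = ifelse(y == 1, 1, -1))
  fit <- fit_logistic(X, max_iter = 2000)
  expect_equal(mean(predict(fit, X, type = "class") == y), 1)
  # no finite optimum: the fit either runs into the loss stopping rule
  # (loss below 1e-4 as the weights grow) or is cut off at max_iter
  expect_true(fit$loss < 1e-4 || !fit$converged)
})

test_that("single-class sessions are flagged degenerate", {
  X <- tibble::tibble(y = rep(1L, 30), cue_location = rep(c(-1, 1), 15))
  expect_warning(fit <- fit_logistic(X, max_iter = 200))
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_gt(fit$coefficients[["(Intercept)"]], 0)
})

test_that("predictions follow the fitted logistic and the half rule", {
  fit <- structure(
    list(coefficients = c(`(Intercept)` = 0.5, cue_location = 1),
         predictors = "cue_location"),
    class = "choice_fit")
  nd <- tibble::tibble(cue_location = c(-1, 0, 1))
  expect_equal(predict(fit, nd), stats::plogis(c(-0.5, 0.5, 1.5)))
  zero <- structure(
    list(coefficients = c(`(Intercept)` = 0, cue_location = 0),
         predictors = "cue_location"),
    class = "choice_fit")
  expect_equal(predict(zero, nd), rep(0.5, 3))
  expect_equal(predict(zero, nd, type = "class"), rep(1L, 3))  # 0.5 -> 1
})

test_that("cross-validation tests every sample once and is reproducible", {
  tr <- simulate_behavior_parametric(n_trials = 200, seed = 5)
  X <- build_regressors(tr)
  a1 <- crossval_accuracy(X, seed = 3)
  a2 <- crossval_accuracy(X, seed = 3)
  expect_equal(as.numeric(a1), as.numeric(a2))
  expect_identical(attr(a1, "folds"), attr(a2, "folds"))
  expect_equal(nrow(attr(a1, "predictions")), 200)
  expect_setequal(unique(attr(a1, "folds")), 1:10)
  # stratification: both classes in every training fold
  folds <- attr(a1, "folds")
  for (f in 1:10) expect_gt(length(unique(X$y[folds != f])), 1)
})

test_that("cross-validated accuracy separates signal from chance", {
  # strongly cue-driven session: near-perfect prediction
  driven <- simulate_behavior_parametric(n_trials = 400, w_cue_location = 6,
                                         lapse = 0, seed = 6)
  acc <- crossval_accuracy(build_regressors(driven), seed = 1)
  expect_gt(as.numeric(acc), 0.95)
  # label-shuffled session: chance within the binomial 99% CI
  Xs <- build_regressors(driven)
  Xs$y <- Xs$y[rng_stream(2)$permute(seq_len(nrow(Xs)))]
  acc_sh <- crossval_accuracy(Xs, seed = 1)
  expect_lt(abs(as.numeric(acc_sh) - 0.5), qnorm(0.995) * sqrt(0.25 / 400) + 0.02)
})

test_that("the bias-only model predicts biased but not unbiased behavior", {
  biased <- simulate_behavior_parametric(n_trials = 400, w_cue_location = 0,
                                         w_bias = 1.5, lapse = 0, seed = 7)
  X0 <- build_regressors(biased, character(0))
  expect_gt(as.numeric(crossval_accuracy(X0, seed = 1)), 0.6)
  unbiased <- simulate_behavior_parametric(n_trials = 400, w_cue_location = 0,
                                           w_bias = 0, lapse = 0, seed = 8)
  acc <- as.numeric(crossval_accuracy(build_regressors(unbiased, character(0)),
                                      seed = 1))
  expect_lt(abs(acc - 0.5), qnorm(0.995) * sqrt(0.25 / 400) + 0.03)
})

test_that("model comparison ranks reduced and augmented variants sensibly", {
  tr <- simulate_behavior_parametric(n_trials = 600, w_cue_location = 2.5,
                                     lapse = 0.02, seed = 9)
  cmp <- compare_models(
    tr, variants = list(
      self = choice_predictors_full(),
      drop_generative = setdiff(choice_predictors_full(), "cue_location"),
      add_irrelevant = c(choice_predictors_full(), "cue_interaction")),
    seed = 2)
  expect_equal(cmp$delta_accuracy[cmp$model == "base"], 0)
  expect_equal(cmp$delta_accuracy[cmp$model == "self"], 0)
  expect_gt(cmp$delta_accuracy[cmp$model == "drop_generative"], 0.2)
  expect_lt(abs(cmp$delta_accuracy[cmp$model == "add_irrelevant"]), 0.05)
})

test_that("choice-fit tidiers expose terms and fit quality", {
  tr <- simulate_behavior_parametric(n_trials = 200, seed = 10)
  fit <- fit_logistic(build_regressors(tr))
  td <- tidy(fit)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 4)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, 200)
})
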