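#' Fraction of correct trials
#'
#' @param trials Trial tibble with a logical `correct` column (and, when
#'   filtering, the columns referenced by the filter).
#' @param ... Optional filter expressions evaluated in the data (as in
#'   [dplyr::filter()]), applied before counting.
#' @return Fraction correct among selected trials; `NA_real_` when the
#'   selection is empty (never silently zero).
#' @export
#' @examples
#' trials <- tibble::tibble(correct = c(TRUE, TRUE, TRUE, FALSE))
#' fraction_correct(trials)  # 0.75
fraction_correct <- function(trials, ...) {
  sel <- dplyr::filter(trials, ...)
  if (nrow(sel) == 0) return(NA_real_)
  mean(sel$correct)
}

#' Response bias index
#'
#' Quantifies a side preference from per-side accuracy. With
#' `fcl`/`fcr` the fraction of correct trials among left-cued and
#' right-cued trials, the primary index is `fcl / (fcl + fcr)`: 0.5 for
#' unbiased behavior, 0 or 1 for a one-sided responder. The absolute
#' response bias `|bias - 0.5|` then ranges from 0 (unbiased) to 0.5
#' (maximally one-sided). `method = "printed"` gives the alternative form
#' `(fcl - fcr) / fcl`, retained for reference; its absolute transform
#' does not respect the `[0, 0.5]` range.
#'
#' @param trials Trial tibble with `cue_location` and `correct` columns;
#'   must contain at least one trial per cued side.
#' @param method `"ratio"` (primary) or `"printed"`.
#' @return `response_bias()`: the bias index (`NA_real_` on a zero
#'   denominator). `abs_response_bias()`: `|bias - 0.5|`.
#' @export
#' @examples
#' trials <- tibble::tibble(
#'   cue_location = rep(c("left", "right"), each = 10),
#'   correct = rep(c(TRUE, FALSE), c(19, 1))
#' )
#' response_bias(trials)
#' abs_response_bias(trials)
response_bias <- function(trials, method = c("ratio", "printed")) {
  method <- match.arg(method)
  fcl <- fraction_correct(trials, .data$cue_location == "left")
  fcr <- fraction_correct(trials, .data$cue_location == "right")
  if (is.na(fcl) || is.na(fcr)) {
    abort("at least one trial per cued side is required",
          class = "ruleswitch_argument_error")
  }
  if (method == "ratio") {
    if (fcl + fcr == 0) return(NA_real_)
    fcl / (fcl + fcr)
  } else {
    if (fcl == 0) return(NA_real_)
    (fcl - fcr) / fcl
  }
}

#' @rdname response_bias
#' @export
abs_response_bias <- function(trials, method = c("ratio", "printed")) {
  abs(response_bias(trials, method) - 0.5)
}

#' Performance staging and acquisition criterion
#'
#' Sessions are staged by accuracy: *novice* below 60% correct,
#' *intermediate* between 60% and 80% (including sessions above 80%
#' overall that fail the per-condition clause), *expert* at or above 80%
#' overall with every condition at or above 60%. The acquisition criterion
#' coincides with the expert stage: at least 80% correct overall and at
#' least 60% correct in each of the four conditions.
#'
#' @param overall Overall fraction correct.
#' @param min_condition Minimum per-condition fraction correct.
#' @return `stage_session()`: `"novice"`, `"intermediate"` or `"expert"`;
#'   `meets_criterion()`: logical.
#' @export
#' @examples
#' stage_session(0.85, 0.7)   # expert
#' stage_session(0.85, 0.5)   # intermediate (condition clause fails)
#' stage_session(0.59, 0.5)   # novice
stage_session <- function(overall, min_condition) {
  if (is.na(overall)) return(NA_character_)
  if (overall < 0.6) return("novice")
  if (meets_criterion(overall, min_condition)) return("expert")
  "intermediate"
}

#' @rdname stage_session
#' @export
meets_criterion <- function(overall, min_condition) {
  !is.na(overall) && !is.na(min_condition) &&
    overall >= 0.8 && min_condition >= 0.6
}

#' Summarise one session of trials
#'
#' @param trials Trial tibble for a single session with `condition`,
#'   `cue_location` and `correct` columns.
#' @return One-row tibble: `n_trials`, `fraction_correct`,
#'   `min_condition_correct`, `response_bias`, `abs_response_bias`,
#'   `stage`, `criterion`.
#' @export
session_summary <- function(trials) {
  n <- nrow(trials)
  fc <- if (n > 0) mean(trials$correct) else NA_real_
  by_cond <- tapply(trials$correct, factor(trials$condition,
                                           levels = task_conditions()$condition),
                    mean)
  minc <- if (anyNA(by_cond)) NA_real_ else min(by_cond)
  has_sides <- all(c("left", "right") %in% trials$cue_location)
  rb <- if (has_sides) response_bias(trials) else NA_real_
  tibble(
    n_trials = n, fraction_correct = fc, min_condition_correct = minc,
    response_bias = rb,
    abs_response_bias = if (is.na(rb)) NA_real_ else abs(rb - 0.5),
    stage = stage_session(fc, minc),
    criterion = meets_criterion(fc, minc)
  )
}

#' Learning rate from a performance curve
#'
#' The learning rate is the least-squares slope of a linear fit to the
#' per-session accuracy curve, from the first session to the first
#' criterion session. For the location rule (initial acquisition, where a
#' strong response bias produces an apparent slope increase) two fits are
#' used: first session to last novice session, and first intermediate
#' session to first criterion session.
#'
#' @param sessions Per-session tibble for one rule, in order, with
#'   columns `fraction_correct`, `stage` and `criterion` (as produced by
#'   `tidy()` on an [run_protocol()] result).
#' @param rule Rule the curve belongs to; selects the one- or two-segment
#'   fit.
#' @return Tibble with `segment`, `slope` (fraction correct per session;
#'   `NA` when a segment has fewer than two sessions), `from`, `to`.
#' @export
learning_rate <- function(sessions, rule) {
  assert_rule(rule)
  acc <- sessions$fraction_correct
  first_crit <- which(sessions$criterion)[1]
  end <- if (is.na(first_crit)) length(acc) else first_crit
  fit_slope <- function(from, to) {
    if (is.na(from) || is.na(to) || to - from < 1) return(NA_real_)
    idx <- from:to
    unname(coef(lm(acc[idx] ~ idx))[2])
  }
  if (rule == "location") {
    last_novice <- rev(which(sessions$stage == "novice"))[1]
    first_inter <- which(sessions$stage == "intermediate")[1]
    tibble(
      segment = c("novice", "acquisition"),
      slope = c(fit_slope(1L, last_novice), fit_slope(first_inter, end)),
      from = c(1L, first_inter), to = c(last_novice, end)
    )
  } else {
    tibble(segment = "acquisition", slope = fit_slope(1L, end),
           from = 1L, to = end)
  }
}

#' Truncate a session at satiety
#'
#' Sessions are truncated at the first miss trial occurring after 90% of
#' the trials, and further truncated if running performance drops during
#' the trailing 15% of trials. Running performance is the fraction correct
#' in `window`-trial rolling windows; a trailing window is dropped when it
#' falls below the session mean minus 1.5 standard deviations of the
#' windowed performance. The slump cut never removes more than the final
#' 15% of (post-miss-cut) trials.
#'
#' @param trials Trial tibble with `correct` and (optionally) a logical
#'   `miss` column.
#' @param window Rolling-window length in trials (default 20).
#' @return The truncated trial tibble (miss trials removed).
#' @export
truncate_session <- function(trials, window = 20) {
  n <- nrow(trials)
  if (n == 0) return(trials)
  miss <- if ("miss" %in% names(trials)) trials$miss else rep(FALSE, n)
  late_miss <- which(miss & seq_len(n) > 0.9 * n)
  if (length(late_miss) > 0) {
    trials <- trials[seq_len(late_miss[1] - 1L), ]
    miss <- miss[seq_len(late_miss[1] - 1L)]
  }
  n2 <- nrow(trials)
  if (n2 >= window) {
    cs <- c(0, cumsum(as.numeric(trials$correct)))
    idx <- window:n2
    roll <- (cs[idx + 1] - cs[idx + 1 - window]) / window
    thr <- mean(roll) - 1.5 * stats::sd(roll)
    tail_start <- floor(0.85 * n2) + 1L
    in_tail <- idx > 0.85 * n2
    bad <- idx[in_tail & roll < thr]
    if (length(bad) > 0 && !is.na(thr)) {
      cut_at <- max(bad[1] - window + 1L, tail_start)
      trials <- trials[seq_len(cut_at - 1L), ]
      miss <- miss[seq_len(cut_at - 1L)]
    }
  }
  trials[!miss, ]
}

#' Stay/switch performance around a rule switch
#'
#' Splits the first `first_n` trials of each supplied session by whether
#' the condition's correct response is the same (*stay*) or different
#' (*switch*) under the new rule relative to the previous one, and
#' computes the fraction of correct trials per class. Typically applied
#' to the last session of the previous rule and the first session of the
#' new rule.
#'
#' @param trials Trial tibble with `session`, `trial`, `cue_location`,
#'   `cue_frequency` and `correct` columns (one or more sessions).
#' @param prev_rule,new_rule The rules before and after the switch.
#' @param first_n Number of trials used from the start of each session
#'   (default 100).
#' @return Tibble with `session`, `stay_switch`, `fraction_correct`,
#'   `n_trials`.
#' @export
stay_switch_performance <- function(trials, prev_rule, new_rule, first_n = 100) {
  trials %>%
    group_by(.data$session) %>%
    arrange(.data$trial, .by_group = TRUE) %>%
    slice(seq_len(min(first_n, dplyr::n()))) %>%
    ungroup() %>%
    mutate(stay_switch = classify_stay_switch(
      prev_rule, new_rule, .data$cue_location, .data$cue_frequency)) %>%
    group_by(.data$session, .data$stay_switch) %>%
    summarise(fraction_correct = mean(.data$correct),
              n_trials = dplyr::n(), .groups = "drop")
}
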