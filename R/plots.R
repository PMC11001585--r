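#' Plot learning curves of a simulated protocol
#'
#' Per-agent fraction correct across sessions (gray) with the across-agent
#' mean (color), split by task rule, with the criterion and chance levels
#' marked.
#'
#' @param object An `rl_protocol`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rl_protocol
#' @export
autoplot.rl_protocol <- function(object, ...) {
  sess <- object$sessions %>%
    mutate(rule = factor(.data$rule, levels = object$rules))
  avg <- sess %>%
    group_by(.data$rule, .data$session_in_rule) %>%
    summarise(fraction_correct = mean(.data$fraction_correct), .groups = "drop")
  ggplot2::ggplot(sess, ggplot2::aes(x = .data$session_in_rule,
                                     y = .data$fraction_correct)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$agent), color = "grey70") +
    ggplot2::geom_line(data = avg, color = "#2166ac", linewidth = 1) +
    ggplot2::geom_hline(yintercept = c(0.5, 0.8), linetype = "dashed",
                        color = "grey40") +
    ggplot2::facet_wrap(~rule, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = "Session within rule", y = "Fraction correct",
                  title = sprintf("%s agents, %s reset",
                                  object$params$algorithm,
                                  object$params$reset_mode)) +
    ggplot2::theme_minimal()
}

#' Plot fitted choice-model weights
#'
#' @param object A `choice_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot choice_fit
#' @export
autoplot.choice_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "Regression weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-trial epoch amplitudes of a photometry session
#'
#' @param object A `photometry_session` from [process_photometry()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot photometry_session
#' @export
autoplot.photometry_session <- function(object, ...) {
  df <- object$amplitudes %>%
    mutate(epoch = factor(.data$epoch, levels = c("cue", "spouts", "outcome")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$amplitude)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~epoch, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Trial", y = "Amplitude (robust z)",
                  title = paste(object$region, "epoch amplitudes")) +
    ggplot2::theme_minimal()
}

#' Plot cue- and outcome-epoch RPEs around a rule switch
#'
#' Mean TD error on correct trials in the cue and outcome epochs, split
#' by stay and switch conditions, for the first sessions after a rule
#' switch -- the uncoupling signature of on-policy learning with a
#' partial value reset.
#'
#' @param protocol An `rl_protocol` that includes a rule switch.
#' @param rule Post-switch rule to display (default `"frequency"`).
#' @param sessions Session-within-rule indices to display.
#' @return A ggplot object.
#' @export
plot_rpe_stay_switch <- function(protocol, rule = "frequency", sessions = 1:5) {
  df <- bind_rows(
    extract_rpes(protocol, "cue", correct = TRUE, rule = rule,
                 session_in_rule = sessions),
    extract_rpes(protocol, "outcome", correct = TRUE, rule = rule,
                 session_in_rule = sessions)
  ) %>%
    filter(!is.na(.data$stay_switch)) %>%
    group_by(.data$epoch, .data$session_in_rule, .data$stay_switch) %>%
    summarise(delta = mean(.data$delta), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$session_in_rule, y = .data$delta,
                                   color = .data$stay_switch)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~epoch, scales = "free_y") +
    ggplot2::labs(x = "Session after switch", y = "Mean TD error (correct trials)",
                  color = NULL) +
    ggplot2::theme_minimal()
}
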