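# Small hand-buildable fixtures used across test files.

# A toy trial log with explicit correctness per (side, correct) counts.
toy_trials <- function(n_left_correct, n_left_error, n_right_correct,
                       n_right_error) {
  tibble::tibble(
    trial = seq_len(n_left_correct + n_left_error + n_right_correct +
                      n_right_error),
    cue_location = rep(c("left", "right"),
                       c(n_left_correct + n_left_error,
                         n_right_correct + n_right_error)),
    cue_frequency = "low",
    condition = rep(c("left-low", "right-low"),
                    c(n_left_correct + n_left_error,
                      n_right_correct + n_right_error)),
    correct = c(rep(c(TRUE, FALSE), c(n_left_correct, n_left_error)),
                rep(c(TRUE, FALSE), c(n_right_correct, n_right_error)))
  )
}

# A session tibble in the shape of tidy(rl_protocol) for learning_rate().
toy_sessions <- function(acc) {
  tibble::tibble(
    fraction_correct = acc,
    min_condition_correct = acc,
    stage = vapply(acc, function(a) stage_session(a, a), character(1)),
    criterion = vapply(acc, function(a) meets_criterion(a, a), logical(1))
  )
}

# Independent brute-force oracle for prominence-based extremum selection.
# Scans outward from each interior local extremum to the nearest strictly
# higher (lower) sample or the segment edge.
oracle_detect_peak <- function(x) {
  n <- length(x)
  interior_max <- function(v, i) v[i] > min(v[i - 1], v[i + 1]) &&
    v[i] >= max(v[i - 1], v[i + 1])
  best <- function(v) {
    out <- NULL
    i <- 2L
    while (i <= n - 1L) {
      # skip plateau: require a strict rise before and a strict fall after
      j <- i
      while (j < n && v[j + 1] == v[j]) j <- j + 1
      if (j <= n - 1 && v[i] > v[i - 1] && v[j] > v[j + 1]) {
        left <- i - 1
        while (left >= 1 && v[left] <= v[j]) left <- left - 1
        right <- j + 1
        while (right <= n && v[right] <= v[j]) right <- right + 1
        lmin <- min(v[max(left, 1):j])
        rmin <- min(v[j:min(right, n)])
        prom <- v[j] - max(lmin, rmin)
        if (is.null(out) || prom > out$prominence) {
          out <- list(index = j, prominence = prom)
        }
      }
      i <- j + 1
    }
    out
  }
  pk <- best(x)
  vl <- best(-x)
  if (is.null(pk) && is.null(vl)) {
    return(list(kind = if (x[1] >= x[n]) "peak" else "valley",
                amplitude = x[1]))
  }
  if (!is.null(pk) && (is.null(vl) || pk$prominence >= vl$prominence)) {
    list(kind = "peak", amplitude = x[pk$index])
  } else {
    list(kind = "valley", amplitude = x[vl$index])
  }
}
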