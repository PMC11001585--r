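test_that("smoothing and downsampling preserve level and length", {
  n <- 1000
  const <- tibble::tibble(time = (0:(n - 1)) / 1000, value = 2.5)
  out <- smooth_downsample(const)
  expect_equal(out$value, rep(2.5, 50))
  expect_equal(nrow(out), ceiling(n / 20))
  # a unit impulse becomes a 1/50 plateau of 50 samples pre-decimation
  imp <- tibble::tibble(time = (0:999) / 1000, value = 0)
  imp$value[500] <- 1
  sm <- smooth_downsample(imp, factor = 1)
  expect_equal(sum(sm$value > 1e-12), 50)
  expect_equal(max(sm$value), 1 / 50)
  # edges use shrinking windows, so a constant stays exact at both ends
  expect_equal(smooth_downsample(const, factor = 1)$value[c(1, n)], c(2.5, 2.5))
  # odd lengths round the output length up
  odd <- tibble::tibble(time = (0:40) / 1000, value = 1)
  expect_equal(nrow(smooth_downsample(odd)), ceiling(41 / 20))
})

test_that("dF/F is baseline-relative per trial and flags bad baselines", {
  tm <- (0:999) / 50  # 20 s at 50 Hz
  ev <- tibble::tibble(trial = 1:2, trial_start = c(1, 10),
                       cue_onset = c(2, 11), cue_offset = c(3, 12),
                       lick = c(3.6, 12.6))
  # F == B everywhere: dF/F identically 0
  flat <- tibble::tibble(time = tm, value = 2)
  d0 <- compute_dff(flat, ev)
  expect_true(all(d0$dff == 0))
  # B = 2, F = 3 in the segment: dF/F = 0.5
  stepped <- tibble::tibble(time = tm, value = ifelse(tm >= 1 & tm <= 5, 3, 2))
  d1 <- compute_dff(stepped, ev)
  expect_equal(unique(d1$dff[d1$trial == 1]), 0.5)
  # non-positive baseline invalidates the trial
  bad <- tibble::tibble(time = tm, value = ifelse(tm < 1, -1, 2))
  expect_warning(d2 <- compute_dff(bad, ev))
  expect_equal(attr(d2, "invalid_trials"), 1)
  expect_setequal(unique(d2$trial), 2)
})

test_that("robust z subtracts the median and divides by the MAD", {
  x <- c(1, 2, 3, 4, 100)
  z <- robust_z(x)
  expect_equal(as.numeric(z), (x - 3) / 1)  # median 3, MAD 1
  expect_equal(attr(z, "center"), 3)
  expect_equal(attr(z, "scale"), 1)
  # already-normalized input is unchanged
  y <- c(-2, -1, 0, 1, 2)
  expect_equal(as.numeric(robust_z(y)), y)
  # constant input: degenerate session
  expect_warning(zc <- robust_z(rep(1, 10)), class = "ruleswitch_degenerate")
  expect_true(all(is.na(zc)))
  # invertible given stored center/scale
  expect_equal(as.numeric(z) * attr(z, "scale") + attr(z, "center"), x)
})

test_that("detect_peak picks the more prominent signed extremum", {
  bump <- c(0, 0.2, 0.6, 1, 0.6, 0.2, 0)
  expect_equal(detect_peak(bump)$amplitude, 1)
  expect_equal(detect_peak(bump)$kind, "peak")
  dip <- -0.4 * bump
  pk <- detect_peak(dip)
  expect_equal(pk$kind, "valley")
  expect_equal(pk$amplitude, -0.4)
  # bump (height 1) beats dip (depth 0.4) in the same window
  both <- c(0, 0.5, 1, 0.5, 0, -0.2, -0.4, -0.2, 0)
  expect_equal(detect_peak(both)$amplitude, 1)
  # monotone falling flank: tail of a peak anchored at the first sample
  falling <- c(1, 0.8, 0.6, 0.45, 0.33)
  expect_equal(detect_peak(falling)$amplitude, 1)
  expect_equal(detect_peak(falling)$kind, "peak")
  rising <- -falling
  expect_equal(detect_peak(rising)$amplitude, -1)
  expect_equal(detect_peak(rising)$kind, "valley")
})

test_that("detect_peak agrees with a brute-force extremum oracle", {
  s <- rng_stream(23)
  for (i in 1:200) {
    x <- cumsum(s$rnorm(30))  # random-walk segments with rich structure
    got <- detect_peak(x)
    want <- oracle_detect_peak(x)
    expect_equal(got$kind, want$kind, info = paste("case", i))
    expect_equal(got$amplitude, want$amplitude, info = paste("case", i))
  }
})

test_that("epoch windows encode the region-specific table", {
  vs <- epoch_windows("VS")
  expect_equal(vs$end_ms - vs$start_ms, c(1000, 340, 840))
  expect_equal(vs$start_ms[vs$epoch == "outcome"], 160)
  dms <- epoch_windows("DMS")
  expect_equal(dms$end_ms[dms$epoch == "outcome"] -
                 dms$start_ms[dms$epoch == "outcome"], 740)
  dls <- epoch_windows("DLS")
  expect_equal(dls$start_ms[dls$epoch == "outcome"], 140)
  expect_equal(dls$end_ms[dls$epoch == "outcome"], 520)
  expect_true(all(vs$start_ms >= 0))
})

test_that("epoch amplitudes recover injected transients within tolerance", {
  logs <- tibble::tibble(
    delta_cue = c(0.9, -0.5, 0.4, 0.7, -0.8, 0.3, 0.6, -0.4, 0.5, 0.8),
    delta_action = c(0.2, -0.3, 0.1, 0.3, -0.2, 0.15, 0.25, -0.1, 0.2, 0.3),
    delta_outcome = c(1, -1.5, 0.8, -0.9, 1.2, 0.5, -0.6, 1.1, 0.9, -1.2))
  for (rg in c("VS", "DMS", "DLS")) {
    sim <- simulate_photometry(logs, region = rg, noise_sd = 0.01, seed = 5)
    ds <- smooth_downsample(sim$trace)
    dff <- compute_dff(ds, sim$events)
    amps <- epoch_amplitudes(dplyr::rename(dff, value = dff), sim$events,
                             region = rg)
    j <- dplyr::inner_join(amps, sim$truth, by = c("trial", "epoch"))
    j <- j[j$epoch %in% c("cue", "outcome") & abs(j$expected_dff) >= 0.2, ]
    expect_gt(nrow(j), 15)
    expect_true(all(abs(j$amplitude - j$expected_dff) /
                      abs(j$expected_dff) < 0.1), info = rg)
    expect_true(all(abs(j$latency_ms - j$expected_latency_ms) < 40), info = rg)
  }
})

test_that("different regions cut different outcome segments from one trace", {
  logs <- tibble::tibble(delta_cue = 0.5, delta_action = 0.2,
                         delta_outcome = 1)
  sim <- simulate_photometry(logs, region = "VS", noise_sd = 0, seed = 1)
  ds <- smooth_downsample(sim$trace)
  dff <- dplyr::rename(compute_dff(ds, sim$events), value = dff)
  a_vs <- epoch_amplitudes(dff, sim$events, "VS")
  a_dls <- epoch_amplitudes(dff, sim$events, "DLS")
  n_vs <- a_vs$n_samples[a_vs$epoch == "outcome"]
  n_dls <- a_dls$n_samples[a_dls$epoch == "outcome"]
  expect_gt(n_vs, n_dls)
})

test_that("window means are available as the cross-check variant", {
  logs <- tibble::tibble(delta_cue = 1, delta_action = 0, delta_outcome = 0.5)
  sim <- simulate_photometry(logs, noise_sd = 0, drift_amplitude = 0,
                             region = "VS", seed = 2)
  ps <- process_photometry(sim$trace, sim$events, "VS", method = "mean")
  amp <- ps$amplitudes
  expect_true(all(is.na(amp$latency_ms)))
  # the mean understates the peak but keeps its sign
  expect_gt(amp$amplitude[amp$epoch == "cue"], 0)
})

test_that("the pipeline is invariant to positive rescaling of the trace", {
  logs <- tibble::tibble(delta_cue = c(0.5, -0.6), delta_action = c(0.1, 0.2),
                         delta_outcome = c(1, -0.8))
  sim <- simulate_photometry(logs, region = "DMS", seed = 3)
  p1 <- process_photometry(sim$trace, sim$events, "DMS")
  scaled <- sim$trace
  scaled$value <- scaled$value * 3.7
  p2 <- process_photometry(scaled, sim$events, "DMS")
  expect_equal(p1$amplitudes$amplitude, p2$amplitudes$amplitude,
               tolerance = 1e-10)
})

test_that("recovered amplitudes track injected amplitudes across trials", {
  s <- rng_stream(29)
  logs <- tibble::tibble(
    delta_cue = round(s$runif(30) * 2 - 1, 2),
    delta_action = 0,
    delta_outcome = round(s$runif(30) * 2 - 1, 2))
  sim <- simulate_photometry(logs, region = "VS", noise_sd = 0.05,
                             pavlovian = 0, seed = 6)
  ps <- process_photometry(sim$trace, sim$events, "VS")
  j <- dplyr::inner_join(ps$amplitudes, sim$truth, by = c("trial", "epoch"))
  for (ep in c("cue", "outcome")) {
    je <- j[j$epoch == ep, ]
    expect_gt(cor(je$amplitude, je$injected, method = "spearman"), 0.9)
  }
})
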