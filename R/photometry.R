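#' Smooth and downsample a raw fluorescence trace
#'
#' Applies a centered running average (50 ms at the native 1 kHz sampling
#' rate) and decimates by a fixed factor of 20, giving 50 samples per
#' second. Edge samples use shrinking windows (the average over the part
#' of the window inside the trace).
#'
#' @param trace Tibble with `time` (seconds, strictly increasing) and
#'   `value`, sampled at `fs_in`.
#' @param smooth_ms Running-average width in ms (default 50).
#' @param fs_in Input sampling rate in Hz (default 1000).
#' @param factor Decimation factor (default 20).
#' @return Tibble with `time` and `value` at `fs_in / factor` Hz; length
#'   `ceiling(n / factor)`.
#' @export
smooth_downsample <- function(trace, smooth_ms = 50, fs_in = 1000, factor = 20) {
  x <- trace$value
  n <- length(x)
  w <- round(smooth_ms * fs_in / 1000)
  half_lo <- ceiling(w / 2) - 1L  # centered: w samples around i
  half_hi <- w - half_lo - 1L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  keep <- seq(1L, n, by = factor)
  tibble(time = trace$time[keep], value = sm[keep])
}

#' Per-trial relative fluorescence (dF/F)
#'
#' For each trial, the baseline B is the mean fluorescence in a 500-ms
#' window before the trial start; each sample in the trial segment is
#' transformed to `(F - B) / B`. Trials whose baseline is non-positive
#' are flagged invalid and dropped with a warning.
#'
#' @param trace Processed tibble (`time`, `value`), e.g. from
#'   [smooth_downsample()].
#' @param events Per-trial event tibble with columns `trial`,
#'   `trial_start`, and the event times needed downstream (`cue_onset`,
#'   `cue_offset`, `lick`), all in seconds on the trace clock.
#' @param baseline_ms Baseline window length before trial start
#'   (default 500).
#' @param post_s Segment end, seconds after the `lick` event
#'   (default 1.2, covering the longest outcome window).
#' @return Tibble with `trial`, `time` and `dff`; invalid trial ids in
#'   attribute `invalid_trials`.
#' @export
compute_dff <- function(trace, events, baseline_ms = 500, post_s = 1.2) {
  segs <- vector("list", nrow(events))
  invalid <- integer(0)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    base_idx <- trace$time >= ev$trial_start - baseline_ms / 1000 &
      trace$time < ev$trial_start
    b <- mean(trace$value[base_idx])
    seg_idx <- trace$time >= ev$trial_start & trace$time <= ev$lick + post_s
    if (!is.finite(b) || b <= 0) {
      invalid <- c(invalid, ev$trial)
      next
    }
    segs[[i]] <- tibble(trial = ev$trial, time = trace$time[seg_idx],
                        dff = (trace$value[seg_idx] - b) / b)
  }
  if (length(invalid) > 0) {
    warn(paste("dropping", length(invalid), "trial(s) with non-positive baseline"))
  }
  out <- bind_rows(segs)
  attr(out, "invalid_trials") <- invalid
  out
}

#' Robust z-score
#'
#' Subtracts the median and divides by the median absolute deviation
#' (MAD, unscaled) of the reference values -- by default the values
#' themselves, typically the concatenated analyzed trial segments of a
#' session. A zero MAD flags the session as degenerate: a warning is
#' raised and `NA` returned.
#'
#' @param x Numeric values to normalize.
#' @param reference Values from which median and MAD are computed
#'   (default `x`).
#' @return Normalized values, with attributes `center` (median) and
#'   `scale` (MAD) so the transform is invertible.
#' @export
#' @examples
#' robust_z(c(1, 2, 3, 4, 100))
robust_z <- function(x, reference = x) {
  ctr <- median(reference)
  scl <- mad(reference, constant = 1)
  if (scl == 0) {
    warn("zero median absolute deviation: degenerate session",
         class = "ruleswitch_degenerate")
    z <- rep(NA_real_, length(x))
  } else {
    z <- (x - ctr) / scl
  }
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- sign(diff(x))
  # carry the last nonzero slope across plateaus
  for (i in seq_along(d)) if (d[i] == 0 && i > 1) d[i] <- d[i - 1]
  which(d[-length(d)] == 1 & d[-1] == -1) + 1L
}

prominence_at <- function(x, i) {
  higher_l <- which(x[seq_len(i - 1)] > x[i])
  lo <- if (length(higher_l) > 0) max(higher_l) else 1L
  higher_r <- which(x[seq(i + 1, length(x))] > x[i]) + i
  hi <- if (length(higher_r) > 0) min(higher_r) else length(x)
  left_min <- if (lo < i) min(x[lo:(i - 1)]) else x[i]
  right_min <- if (hi > i) min(x[(i + 1):hi]) else x[i]
  x[i] - max(left_min, right_min)
}

best_extremum <- function(x) {
  peaks <- local_maxima(x)
  if (length(peaks) == 0) return(NULL)
  proms <- vapply(peaks, function(i) prominence_at(x, i), numeric(1))
  j <- which.max(proms)
  list(index = peaks[j], prominence = proms[j])
}

#' Signed dominant peak of a signal segment
#'
#' Finds the local peak with the largest prominence and the local valley
#' with the largest prominence (valleys via sign inversion) and returns
#' whichever is more prominent; ties go to the peak. The amplitude is the
#' signal value at the selected extremum (negative for a dominant
#' valley). A segment with no interior local extremum at all (a monotone
#' flank, as when an analysis window opens past the transient maximum) is
#' treated as the tail of a peak (falling flank) or of a valley (rising
#' flank) anchored at the first sample, with prominence equal to the
#' segment range.
#'
#' @param values Numeric segment (e.g. robust-z dF/F within one epoch
#'   window).
#' @return One-row tibble: `kind` (`"peak"`/`"valley"`), `amplitude`,
#'   `index` (sample index within the segment), `prominence`.
#' @export
#' @examples
#' seg <- c(0, 0.2, 1, 0.3, 0, -0.4, -0.1)
#' detect_peak(seg)
detect_peak <- function(values) {
  stopifnot(length(values) >= 1)
  pk <- best_extremum(values)
  vl <- best_extremum(-values)
  if (is.null(pk) && is.null(vl)) {
    n <- length(values)
    falling <- values[1] >= values[n]
    return(tibble(kind = if (falling) "peak" else "valley",
                  amplitude = values[1], index = 1L,
                  prominence = max(values) - min(values)))
  }
  if (!is.null(pk) && (is.null(vl) || pk$prominence >= vl$prominence)) {
    tibble(kind = "peak", amplitude = values[pk$index], index = pk$index,
           prominence = pk$prominence)
  } else {
    tibble(kind = "valley", amplitude = values[vl$index], index = vl$index,
           prominence = vl$prominence)
  }
}

#' Region-specific epoch analysis windows
#'
#' Windows for dominant-peak extraction per trial epoch. The cue window
#' spans 1,000 ms after cue onset for all striatal subregions; the spouts
#' window spans 340 ms after cue offset; the outcome window starts with a
#' region-specific latency after the instrumental lick (160 ms for the VS
#' and DMS, 140 ms for the DLS, reflecting reward-delivery latency and
#' sensor kinetics) and lasts 840 ms (VS), 740 ms (DMS) or 380 ms (DLS).
#'
#' @param region `"VS"`, `"DMS"` or `"DLS"`.
#' @return Tibble with `epoch`, `anchor` (event column name), `start_ms`,
#'   `end_ms` (offsets from the anchor).
#' @export
#' @examples
#' epoch_windows("DLS")
epoch_windows <- function(region = c("VS", "DMS", "DLS")) {
  region <- match.arg(region)
  out_len <- c(VS = 840, DMS = 740, DLS = 380)[[region]]
  out_lat <- c(VS = 160, DMS = 160, DLS = 140)[[region]]
  tibble(
    epoch = c("cue", "spouts", "outcome"),
    anchor = c("cue_onset", "cue_offset", "lick"),
    start_ms = c(0, 0, out_lat),
    end_ms = c(1000, 340, out_lat + out_len)
  )
}

#' Per-trial epoch amplitudes
#'
#' Applies the region's epoch windows to every trial of a processed
#' session and extracts the signed dominant peak (or, as a cross-check
#' variant, the plain window mean) in each window.
#'
#' @param processed Tibble with `trial`, `time` and `value` (normalized
#'   dF/F) -- e.g. [compute_dff()] output with `dff` renamed or passed
#'   through [robust_z()].
#' @param events Per-trial event tibble (see [compute_dff()]).
#' @param region Striatal subregion, see [epoch_windows()].
#' @param method `"peak"` (prominence-based, default) or `"mean"`.
#' @return Tibble with `trial`, `epoch`, `amplitude`, `latency_ms` (time
#'   of the extremum relative to the epoch's anchor event; `NA` for
#'   `method = "mean"`) and `n_samples`.
#' @export
epoch_amplitudes <- function(processed, events, region = c("VS", "DMS", "DLS"),
                             method = c("peak", "mean")) {
  region <- match.arg(region)
  method <- match.arg(method)
  win <- epoch_windows(region)
  rows <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    seg <- processed[processed$trial == ev$trial, ]
    if (nrow(seg) == 0) next
    for (j in seq_len(nrow(win))) {
      anchor <- ev[[win$anchor[j]]]
      ws <- anchor + win$start_ms[j] / 1000
      we <- anchor + win$end_ms[j] / 1000
      idx <- seg$time >= ws & seg$time <= we
      vals <- seg$value[idx]
      if (length(vals) == 0) next
      if (method == "peak") {
        pk <- detect_peak(vals)
        lat <- (seg$time[idx][pk$index] - anchor) * 1000
        amp <- pk$amplitude
      } else {
        lat <- NA_real_
        amp <- mean(vals)
      }
      rows[[length(rows) + 1L]] <- tibble(
        trial = ev$trial, epoch = win$epoch[j], amplitude = amp,
        latency_ms = lat, n_samples = length(vals)
      )
    }
  }
  bind_rows(rows)
}

#' Full photometry processing chain
#'
#' Convenience pipeline: smooth and downsample the raw 1-kHz trace,
#' compute per-trial dF/F against the 500-ms pre-trial baseline,
#' robust-z normalize using the concatenated trial segments of the
#' session, and extract per-trial epoch amplitudes for the given region.
#'
#' @param trace Raw tibble (`time`, `value`) at 1 kHz.
#' @param events Per-trial event tibble (see [compute_dff()]).
#' @param region Striatal subregion.
#' @param method Amplitude extraction method, see [epoch_amplitudes()].
#' @return List of class `photometry_session`: `amplitudes` (per-trial
#'   epoch table), `processed` (normalized 50-Hz per-trial samples),
#'   `region`, `method`.
#' @export
process_photometry <- function(trace, events, region = c("VS", "DMS", "DLS"),
                               method = c("peak", "mean")) {
  region <- match.arg(region)
  method <- match.arg(method)
  ds <- smooth_downsample(trace)
  dff <- compute_dff(ds, events)
  z <- robust_z(dff$dff)
  processed <- tibble(trial = dff$trial, time = dff$time, value = as.numeric(z))
  amps <- epoch_amplitudes(processed, events, region, method)
  structure(
    list(amplitudes = amps, processed = processed, region = region,
         method = method, center = attr(z, "center"), scale = attr(z, "scale")),
    class = "photometry_session"
  )
}

#' @export
print.photometry_session <- function(x, ...) {
  cat(sprintf("<photometry_session> %s, %s amplitudes for %d trials\n",
              x$region, x$method, length(unique(x$amplitudes$trial))))
  invisible(x)
}

#' @describeIn process_photometry Per-trial epoch amplitudes as a tibble.
#' @param x A `photometry_session`.
#' @param ... Unused.
#' @method tidy photometry_session
#' @export
tidy.photometry_session <- function(x, ...) x$amplitudes
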