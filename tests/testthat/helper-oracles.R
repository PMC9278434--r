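# Independent oracles and shared fixtures for the test suite.

# Brute-force Hazen percentile: sort, plotting positions (i - 0.5)/n, linear
# interpolation by hand. Kept deliberately independent of stats::quantile.
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- p * n + 0.5
  if (h <= 1) return(x[1])
  if (h >= n) return(x[n])
  lo <- floor(h)
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Windowed minute-ventilation oracle on a raw airflow trace: per-window
# breath count and mean peak-trough amplitude from simple cycle extrema
# between zero crossings of the mean-centred signal. Independent of
# detect_breaths.
oracle_windowed_ve <- function(trace, t0, t1, ml_per_unit, body_mass_kg) {
  x <- trace$value
  idx <- trace$time_s >= t0 & trace$time_s < t1
  x <- x[idx]
  rate <- trace_rate(trace)
  xc <- x - mean(x)
  up <- which(xc[-1] > 0 & xc[-length(xc)] <= 0)
  if (length(up) < 3) return(0)
  amps <- vapply(seq_len(length(up) - 1), function(i) {
    seg <- x[up[i]:up[i + 1]]
    max(seg) - min(seg)
  }, 1.0)
  n_breaths <- length(amps)
  dur_min <- (up[length(up)] - up[1]) / rate / 60
  vt <- mean(amps) * ml_per_unit / body_mass_kg
  vt * (n_breaths / dur_min)
}

# Cache of simulated recordings shared across test blocks (keyed by preset,
# seed, duration and overrides), so expensive 3 h simulations run once.
.rec_cache <- new.env(parent = emptyenv())

cached_recording <- function(preset, seed, duration_s, ...) {
  key <- paste(preset, seed, duration_s,
               paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.rec_cache[[key]])) {
    pr <- protocol_preset(preset, duration_s = duration_s, seed = seed, ...)
    .rec_cache[[key]] <- simulate_recording(pr)
  }
  .rec_cache[[key]]
}

cached_analysis <- function(preset, seed, duration_s, ...) {
  key <- paste("an", preset, seed, duration_s,
               paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.rec_cache[[key]])) {
    rec <- cached_recording(preset, seed, duration_s, ...)
    pr <- rec$truth$protocol
    .rec_cache[[key]] <- analyze_recording(
      rec$airflow, rec$eeg, rec$emg,
      calibration_info(pr$ml_per_unit, pr$body_mass_kg))
  }
  .rec_cache[[key]]
}

# A constructed ventilation series: constant breathing at `f_bpm` with dips
# of given (depth, duration) at given onset times. Returns the vent tibble
# (class vent_series) with exact per-breath values.
constructed_vent <- function(duration_s, f_bpm = 100, vt = 2.5,
                             dips = NULL) {
  ibi <- 60 / f_bpm
  t <- seq(ibi / 2, duration_s, by = ibi)
  v <- rep(vt, length(t))
  if (!is.null(dips)) {
    for (i in seq_len(nrow(dips))) {
      in_dip <- t >= dips$start_s[i] & t < dips$start_s[i] + dips$duration_s[i]
      v[in_dip] <- vt * (1 - dips$depth[i])
    }
  }
  out <- tibble::tibble(
    t_peak_s = t, vt_ml_per_kg = v,
    ibi_s = c(diff(t), ibi),
    ve_ml_per_kg_min = v * 60 / c(diff(t), ibi),
    is_sigh = FALSE
  )
  class(out) <- c("vent_series", class(out))
  out
}

# An all-one-state hypnogram with plausible feature columns.
constructed_hypnogram <- function(labels, epoch_s = 5, emg = NULL) {
  n <- length(labels)
  emg <- emg %||% ifelse(labels == "WAKE", 30,
                         ifelse(labels == "NREM", 8, 1.5))
  out <- tibble::tibble(
    epoch = seq_len(n) - 1L,
    start_s = (seq_len(n) - 1L) * epoch_s,
    delta_power = ifelse(labels == "NREM", 900, 100),
    theta_power = ifelse(labels == "REM", 900, 100),
    td_ratio = ifelse(labels == "REM", 9, 0.3),
    emg_rms = emg,
    label = labels
  )
  attr(out, "epoch_s") <- epoch_s
  class(out) <- c("hypnogram", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
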