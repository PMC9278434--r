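#' Segment an airflow trace into breaths
#'
#' Low-pass filters the airflow (zero-phase, default 20 Hz cut-off), locates
#' inspiration peaks no closer than `min_ibi_s`, and pairs each peak with the
#' end-expiration trough that follows it. Breath amplitude is peak minus
#' trough in signal units. Small deflections are rejected relative to a
#' rolling median amplitude: breaths with amplitude below
#' `min_amplitude_fraction` x the local median are dropped, so detection is
#' invariant to rescaling of the trace.
#'
#' @param airflow a [signal_trace()]; at least 2 s long, rate >= 20 Hz.
#' @param min_amplitude_fraction reject breaths smaller than this fraction of
#'   the rolling median amplitude (default 0.3). Lower it to resolve breaths
#'   inside deep apnoeas on clean traces.
#' @param min_ibi_s minimum inter-breath interval, seconds.
#' @param lowpass_hz pre-filter cut-off for peak localisation; `NULL`
#'   disables filtering.
#' @param amplitude_lowpass_hz cut-off of the heavier breath-band smoothing
#'   used only to read peak/trough values (amplitude). Rodent breathing sits
#'   below ~2.5 Hz, so an 8 Hz measurement bandwidth preserves the waveform
#'   while suppressing the noise-extremum bias that otherwise inflates small
#'   breaths. `NULL` reads amplitudes off the detection-filtered trace.
#' @return A tibble with one row per breath: `t_peak_s`, `t_trough_s`,
#'   `amplitude_units`, `ibi_s` (peak-to-peak to the next breath; `NA` for
#'   the last breath), `is_sigh` (filled by [detect_sighs()]). A flat trace
#'   yields zero rows.
#' @examples
#' tr <- signal_trace(sin(2 * pi * 1.75 * seq(0, 60, by = 0.01)), 100)
#' nrow(detect_breaths(tr))
#' @export
detect_breaths <- function(airflow, min_amplitude_fraction = 0.3,
                           min_ibi_s = 0.25, lowpass_hz = 20,
                           amplitude_lowpass_hz = 8) {
  rate <- trace_rate(airflow)
  abort_if(trace_duration(airflow) < 2, "airflow trace must be >= 2 s")
  abort_if(rate < 20, "airflow sample rate must be >= 20 Hz")
  x <- airflow$value
  if (!is.null(lowpass_hz) && lowpass_hz < rate / 2) {
    x <- butter_filtfilt(x, rate, high = lowpass_hz)
  }
  # peaks and amplitudes are taken on the breath-band copy: on the wider
  # detection band, noise can raise secondary maxima on breath flanks whose
  # "troughs" are the genuine end-expiration minima, inflating the count.
  # Noise in the breath band cannot out-climb the flank slope.
  xa <- if (!is.null(amplitude_lowpass_hz) && amplitude_lowpass_hz < rate / 2) {
    butter_filtfilt(airflow$value, rate, high = amplitude_lowpass_hz)
  } else {
    x
  }
  empty <- tibble::tibble(t_peak_s = numeric(0), t_trough_s = numeric(0),
                          amplitude_units = numeric(0), ibi_s = numeric(0),
                          is_sigh = logical(0))
  if (diff(range(xa)) == 0) return(empty)
  pk <- local_maxima(xa, min_dist = max(1L, as.integer(min_ibi_s * rate)))
  if (length(pk) == 0L) return(empty)
  n <- length(xa)
  # end-expiration trough: minimum between this peak and the next
  tr_idx <- integer(length(pk))
  for (i in seq_along(pk)) {
    to <- if (i < length(pk)) pk[i + 1L] else n
    seg <- pk[i]:to
    tr_idx[i] <- seg[which.min(xa[seg])]
  }
  amp <- xa[pk] - xa[tr_idx]
  keep <- amp > 0
  pk <- pk[keep]; tr_idx <- tr_idx[keep]; amp <- amp[keep]
  if (length(pk) == 0L) return(empty)
  # two-stage amplitude gate. First against the recording-wide median, so
  # bursts of noise-born secondary peaks cannot drag a local median down to
  # their own level; then against a ~10 s rolling median of the survivors
  # for local adaptivity. Both references scale with the trace, keeping
  # detection invariant to amplitude rescaling.
  keep <- amp >= min_amplitude_fraction * stats::median(amp)
  pk <- pk[keep]; tr_idx <- tr_idx[keep]; amp <- amp[keep]
  if (length(pk) == 0L) return(empty)
  med_k <- max(5L, 2L * as.integer(10 / (stats::median(diff(pk)) / rate) / 2) + 1L)
  local_med <- rolling_median_k(amp, med_k)
  keep <- amp >= min_amplitude_fraction * local_med
  pk <- pk[keep]; tr_idx <- tr_idx[keep]; amp <- amp[keep]
  if (length(pk) == 0L) return(empty)
  # refine amplitudes on the surviving breaths: peak value is the maximum of
  # the smooth copy over the breath's own peak region (previous trough to
  # this trough), trough value the minimum between this peak and the next.
  # Reading point values at noise-jittered indices loses the peak curvature
  # and biases small breaths; regional extremes of the smooth copy do not.
  nb <- length(pk)
  for (i in seq_len(nb)) {
    seg <- pk[i]:(if (i < nb) pk[i + 1L] else n)
    tr_idx[i] <- seg[which.min(xa[seg])]
  }
  for (i in seq_len(nb)) {
    lo <- if (i > 1L) tr_idx[i - 1L] else 1L
    amp[i] <- max(xa[lo:tr_idx[i]]) - xa[tr_idx[i]]
  }
  t <- airflow$time_s
  tibble::tibble(
    t_peak_s = t[pk],
    t_trough_s = t[tr_idx],
    amplitude_units = amp,
    ibi_s = c(diff(t[pk]), NA_real_),
    is_sigh = FALSE
  )
}

#' Convert breath amplitudes to mass-specific tidal volume
#'
#' V_T per breath is the peak-minus-trough amplitude converted to mL via the
#' volumetric calibration and standardised to body mass:
#' `vt = amplitude_units * ml_per_unit / body_mass_kg` (mL/kg).
#'
#' @param breaths a [detect_breaths()] tibble.
#' @param calibration a [calibration_info()].
#' @return `breaths` with a `vt_ml_per_kg` column.
#' @export
compute_vt <- function(breaths, calibration) {
  abort_if(!inherits(calibration, "calibration_info"),
           "`calibration` must be a calibration_info object")
  dplyr::mutate(breaths,
    vt_ml_per_kg = .data$amplitude_units * calibration$ml_per_unit /
      calibration$body_mass_kg)
}

#' Respiratory frequency in 1-minute windows
#'
#' f per window is the mean of instantaneous rates `60 / ibi_s` over breaths
#' whose inspiration peak lies in the window (peak-of-inspiration to
#' peak-of-inspiration, averaged over 1 min). Windows holding fewer than two
#' breaths are reported as missing.
#'
#' @param breaths a [detect_breaths()] tibble with >= 2 breaths.
#' @param window_s window length, seconds.
#' @return A tibble with `window_start_s`, `f_bpm`, `n_breaths`.
#' @export
compute_frequency <- function(breaths, window_s = 60) {
  abort_if(nrow(breaths) < 2, "need at least 2 breaths")
  b <- breaths[!is.na(breaths$ibi_s), ]
  win <- floor(b$t_peak_s / window_s)
  all_win <- seq(0, floor(max(breaths$t_peak_s) / window_s))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(win = win, rate = 60 / b$ibi_s), .data$win),
    f_bpm = mean(.data$rate), n_breaths = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(win = all_win), out, by = "win")
  out$f_bpm[is.na(out$n_breaths) | out$n_breaths < 2] <- NA_real_
  out$n_breaths[is.na(out$n_breaths)] <- 0L
  tibble::tibble(window_start_s = out$win * window_s, f_bpm = out$f_bpm,
                 n_breaths = as.integer(out$n_breaths))
}

#' Per-breath minute ventilation
#'
#' V_E at each breath is `vt_ml_per_kg * 60 / ibi_s` (mL kg^-1 min^-1); the
#' identity V_E = V_T x f holds exactly at every breath. A 60 s windowed
#' aggregate (window mean V_T x window f) is attached as an attribute.
#'
#' @param breaths a breath tibble with `vt_ml_per_kg` populated
#'   (see [compute_vt()]).
#' @return A tibble of class `vent_series` with `t_peak_s`, `vt_ml_per_kg`,
#'   `ibi_s`, `ve_ml_per_kg_min`, `is_sigh`; attribute `windowed` holds the
#'   per-minute aggregate `window_start_s`, `f_bpm`, `vt_mean`, `ve_window`.
#' @export
minute_ventilation <- function(breaths) {
  abort_if(!"vt_ml_per_kg" %in% names(breaths),
           "vt_ml_per_kg missing: run compute_vt() first")
  out <- tibble::tibble(
    t_peak_s = breaths$t_peak_s,
    vt_ml_per_kg = breaths$vt_ml_per_kg,
    ibi_s = breaths$ibi_s,
    ve_ml_per_kg_min = breaths$vt_ml_per_kg * 60 / breaths$ibi_s,
    is_sigh = breaths$is_sigh
  )
  if (nrow(breaths) >= 2) {
    f <- compute_frequency(breaths)
    b <- breaths[!is.na(breaths$ibi_s), ]
    vt_win <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(win = floor(b$t_peak_s / 60),
                                     vt = b$vt_ml_per_kg), .data$win),
      vt_mean = mean(.data$vt), .groups = "drop")
    w <- dplyr::left_join(
      dplyr::mutate(f, win = .data$window_start_s / 60), vt_win, by = "win")
    w$ve_window <- w$vt_mean * w$f_bpm
    attr(out, "windowed") <- w[, c("window_start_s", "f_bpm", "vt_mean",
                                   "ve_window")]
  }
  class(out) <- c("vent_series", class(out))
  out
}

#' Flag sighs and compute the sigh rate
#'
#' A sigh is an augmented breath: `vt > k_sigh` x the rolling median tidal
#' volume (window of 60 breaths, centred). The rate denominator is hours of
#' sleep plus quiet wakefulness when a hypnogram is supplied, following the
#' convention that sigh counts are expressed per hour of sleep + quiet
#' wakefulness.
#'
#' @param breaths a breath tibble with `vt_ml_per_kg` (>= 20 breaths).
#' @param k_sigh multiplier on the rolling median V_T (default 2).
#' @param hypnogram optional [classify_epochs()] hypnogram for the rate
#'   denominator; without it the rate is per hour of recording.
#' @return `breaths` with `is_sigh` updated; attributes `sigh_rate_per_h` and
#'   `sigh_denominator_h`.
#' @export
detect_sighs <- function(breaths, k_sigh = 2, hypnogram = NULL) {
  abort_if(nrow(breaths) < 20, "need >= 20 breaths for a stable sigh baseline")
  med <- rolling_median_k(breaths$vt_ml_per_kg, 61L)
  breaths$is_sigh <- breaths$vt_ml_per_kg > k_sigh * med
  if (is.null(hypnogram)) {
    denom_h <- diff(range(breaths$t_peak_s)) / 3600
    n_sigh <- sum(breaths$is_sigh)
  } else {
    iv <- sigh_denominator_epochs(hypnogram)
    denom_h <- nrow(iv$epochs) * attr(hypnogram, "epoch_s") / 3600
    ep <- floor(breaths$t_peak_s / attr(hypnogram, "epoch_s"))
    n_sigh <- sum(breaths$is_sigh & ep %in% iv$epochs$epoch)
  }
  attr(breaths, "sigh_rate_per_h") <- n_sigh / denom_h
  attr(breaths, "sigh_denominator_h") <- denom_h
  breaths
}

sigh_denominator_epochs <- function(hypnogram) {
  # sleep + quiet wakefulness: scored sleep, DOUBT (at bout boundaries these
  # are overwhelmingly sleep) and WAKE epochs with below-median muscle tone;
  # only active wakefulness is excluded
  wake <- hypnogram[hypnogram$label == "WAKE", ]
  quiet_cut <- stats::median(wake$emg_rms)
  keep <- hypnogram$label != "WAKE" |
    hypnogram$emg_rms < quiet_cut
  list(epochs = hypnogram[keep, ], quiet_cut = quiet_cut)
}

#' Select the quiet-wakefulness interval for resting measurements
#'
#' Resting respiratory parameters are read during calm wakefulness at the
#' start of the recording. Operationally: the earliest run of at least
#' `window_s` of contiguous WAKE epochs whose EMG RMS is below the WAKE
#' median.
#'
#' @param hypnogram a [classify_epochs()] hypnogram (with `emg_rms`).
#' @param window_s minimum interval length, seconds.
#' @return A list `list(start_s, end_s)`, or `NULL` when no interval
#'   qualifies.
#' @export
select_quiet_wake <- function(hypnogram, window_s = 60) {
  abort_if(!any(hypnogram$label == "WAKE"), "hypnogram contains no WAKE epochs")
  epoch_s <- attr(hypnogram, "epoch_s") %||% 5
  wake_med <- stats::median(hypnogram$emg_rms[hypnogram$label == "WAKE"])
  # low-tone non-sleep epochs: sporadic DOUBT epochs inside a calm-wake
  # stretch do not break the resting interval, scored sleep does
  quiet <- !hypnogram$label %in% c("NREM", "REM") &
    hypnogram$emg_rms < wake_med
  need <- ceiling(window_s / epoch_s)
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (length(hit) == 0L) return(NULL)
  i <- hit[1L]
  list(start_s = (starts[i] - 1L) * epoch_s, end_s = ends[i] * epoch_s)
}

#' Resting respiratory parameters over an interval
#'
#' Mean f (from instantaneous rates), mean V_T and their product V_E over
#' breaths whose peak lies in `[start_s, end_s)`.
#'
#' @param vent a [minute_ventilation()] series.
#' @param interval a `list(start_s, end_s)` as from [select_quiet_wake()].
#' @return A one-row tibble: `f_bpm`, `vt_ml_per_kg`, `ve_ml_per_kg_min`.
#' @export
resting_parameters <- function(vent, interval) {
  b <- vent[vent$t_peak_s >= interval$start_s &
              vent$t_peak_s < interval$end_s & !is.na(vent$ibi_s) &
              !vent$is_sigh, ]
  abort_if(nrow(b) < 2, "fewer than 2 breaths in the resting interval")
  # breaths per minute by counting peaks over the spanned time: robust to
  # the reciprocal-mean inflation a single short interval would cause
  f <- 60 * (nrow(b) - 1) / diff(range(b$t_peak_s))
  vt <- mean(b$vt_ml_per_kg)
  tibble::tibble(f_bpm = f, vt_ml_per_kg = vt, ve_ml_per_kg_min = vt * f)
}
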