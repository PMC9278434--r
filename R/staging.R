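#' Per-epoch EEG band power and EMG tone
#'
#' EEG is zero-phase band-pass filtered into the delta (default 0.5-4 Hz) and
#' theta (6-10 Hz) bands; the instantaneous band power (squared filtered
#' signal) is smoothed by a first-order exponential smoother with a 5 s time
#' constant and sampled at each 5 s epoch midpoint. EMG tone is the same
#' smoother applied to the squared EMG, square-rooted (an RMS with a 5 s time
#' constant). The trailing partial epoch is dropped.
#'
#' @param eeg,emg [signal_trace()] objects, >= 10 s, EEG rate >= 40 Hz.
#' @param config a config list (see [default_config()]).
#' @return A tibble with `epoch` (0-based), `start_s`, `delta_power`,
#'   `theta_power`, `td_ratio`, `emg_rms`.
#' @export
extract_features <- function(eeg, emg, config = default_config()) {
  abort_if(trace_duration(eeg) < 10 || trace_duration(emg) < 10,
           "EEG and EMG traces must be >= 10 s")
  abort_if(trace_rate(eeg) < 2 * config$theta_band_hz[2],
           "EEG rate below twice the upper theta edge")
  epoch_s <- config$epoch_s
  tau <- config$smooth_tau_s
  r_eeg <- trace_rate(eeg)
  r_emg <- trace_rate(emg)
  delta <- exp_smooth(
    butter_filtfilt(eeg$value, r_eeg, config$delta_band_hz[1],
                    config$delta_band_hz[2])^2, r_eeg, tau)
  theta <- exp_smooth(
    butter_filtfilt(eeg$value, r_eeg, config$theta_band_hz[1],
                    config$theta_band_hz[2])^2, r_eeg, tau)
  emg_sq <- exp_smooth(emg$value^2, r_emg, tau)
  n_ep <- floor(min(trace_duration(eeg), trace_duration(emg)) / epoch_s)
  mid <- (seq_len(n_ep) - 0.5) * epoch_s
  i_eeg <- pmin(length(delta), round(mid * r_eeg) + 1L)
  i_emg <- pmin(length(emg_sq), round(mid * r_emg) + 1L)
  d <- delta[i_eeg]
  th <- theta[i_eeg]
  tibble::tibble(
    epoch = seq_len(n_ep) - 1L,
    start_s = (seq_len(n_ep) - 1L) * epoch_s,
    delta_power = d,
    theta_power = th,
    td_ratio = ifelse(d > 0, th / d, NA_real_),
    emg_rms = sqrt(pmax(emg_sq[i_emg], 0))
  )
}

#' Fit adaptive staging thresholds
#'
#' Per-recording percentile thresholds: `delta_hi` at the 60th percentile of
#' delta power, `emg_hi` at the 50th percentile of EMG RMS, `td_hi` at the
#' 75th percentile of the theta:delta ratio (quantile probabilities are
#' configurable). Because the thresholds are quantiles of the recording's own
#' features, downstream staging is invariant to channel gain.
#'
#' @param features an [extract_features()] tibble with >= 60 epochs.
#' @param config a config list.
#' @return A named list `delta_hi`, `emg_hi`, `td_hi`,
#'   `emg_low` (bottom-decile EMG cut used by the REM rule).
#' @export
fit_thresholds <- function(features, config = default_config()) {
  abort_if(nrow(features) < 60, "need >= 60 epochs to fit staging thresholds")
  degenerate <- function(x) diff(range(x, na.rm = TRUE)) == 0
  abort_if(degenerate(features$delta_power) || degenerate(features$emg_rms),
           "degenerate (constant) features: cannot fit thresholds")
  list(
    delta_hi = quantile_hazen(features$delta_power, config$delta_hi_quantile),
    emg_hi   = quantile_hazen(features$emg_rms, config$emg_hi_quantile),
    td_hi    = quantile_hazen(features$td_ratio[is.finite(features$td_ratio)],
                              config$td_hi_quantile),
    emg_low  = quantile_hazen(features$emg_rms, 0.10)
  )
}

#' Classify epochs into WAKE / NREM / REM / DOUBT
#'
#' Rules applied in order per epoch: WAKE iff EMG RMS exceeds `emg_hi`
#' (wakefulness is muscular, whatever the EEG); otherwise NREM iff delta
#' power exceeds `delta_hi` (high-amplitude slow waves, low tone); otherwise
#' REM iff the theta:delta ratio exceeds `td_hi` and EMG RMS is in the bottom
#' decile (theta-dominated EEG with atonia); otherwise DOUBT.
#'
#' @param features an [extract_features()] tibble.
#' @param thresholds a [fit_thresholds()] list.
#' @param epoch_s epoch length, seconds.
#' @return A tibble of class `hypnogram`: features plus `label`.
#' @export
classify_epochs <- function(features, thresholds, epoch_s = 5) {
  lab <- ifelse(features$emg_rms > thresholds$emg_hi, "WAKE",
         ifelse(features$delta_power > thresholds$delta_hi, "NREM",
         ifelse(is.finite(features$td_ratio) &
                  features$td_ratio > thresholds$td_hi &
                  features$emg_rms <= thresholds$emg_low, "REM", "DOUBT")))
  out <- dplyr::mutate(features, label = lab)
  attr(out, "epoch_s") <- epoch_s
  attr(out, "thresholds") <- thresholds
  class(out) <- c("hypnogram", class(out))
  out
}

#' Stage a recording in one call
#'
#' [extract_features()] + [fit_thresholds()] + [classify_epochs()].
#'
#' @inheritParams extract_features
#' @return A `hypnogram` tibble.
#' @export
stage_sleep <- function(eeg, emg, config = default_config()) {
  fx <- extract_features(eeg, emg, config)
  classify_epochs(fx, fit_thresholds(fx, config), config$epoch_s)
}

#' Summarise a hypnogram
#'
#' State fractions are computed over scored (non-DOUBT) epochs; total sleep
#' is NREM + REM only. Bout statistics count maximal label runs.
#'
#' @param hypnogram a `hypnogram` tibble (or any tibble with `label`).
#' @param epoch_s epoch length, seconds (taken from the hypnogram attribute
#'   when present).
#' @return A list: `fractions` (named, over scored epochs), `sleep_hours`,
#'   `doubt_fraction`, `bouts` (tibble of per-state bout count and mean
#'   length), `n_epochs`.
#' @export
summarize_hypnogram <- function(hypnogram, epoch_s = NULL) {
  abort_if(nrow(hypnogram) == 0, "empty hypnogram")
  epoch_s <- epoch_s %||% attr(hypnogram, "epoch_s") %||% 5
  lab <- hypnogram$label
  scored <- lab[lab != "DOUBT"]
  abort_if(length(scored) == 0, "all epochs are DOUBT; nothing to summarise")
  frac <- table(factor(scored, levels = c("WAKE", "NREM", "REM")))
  frac <- as.numeric(frac) / length(scored)
  names(frac) <- c("WAKE", "NREM", "REM")
  r <- rle(lab)
  bouts <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(state = r$values, len = r$lengths),
                    .data$state),
    n_bouts = dplyr::n(),
    mean_bout_s = mean(.data$len) * epoch_s, .groups = "drop")
  list(
    fractions = frac,
    sleep_hours = sum(lab %in% c("NREM", "REM")) * epoch_s / 3600,
    doubt_fraction = mean(lab == "DOUBT"),
    bouts = bouts,
    n_epochs = length(lab)
  )
}

#' Epoch-wise staging accuracy against a reference
#'
#' Fraction of epochs whose predicted label matches the reference. With
#' `exclude_transitions = TRUE` the epoch on each side of every reference
#' state transition is excluded, since the 5 s feature smoother necessarily
#' blurs epochs at bout edges.
#'
#' @param truth,predicted label vectors (equal length).
#' @param exclude_transitions drop transition-adjacent epochs.
#' @return A scalar accuracy in `[0, 1]`.
#' @export
staging_accuracy <- function(truth, predicted,
                             exclude_transitions = TRUE) {
  n <- min(length(truth), length(predicted))
  truth <- truth[seq_len(n)]; predicted <- predicted[seq_len(n)]
  keep <- rep(TRUE, n)
  if (exclude_transitions && n > 2) {
    tr <- which(truth[-1] != truth[-n])  # transition between tr and tr+1
    keep[unique(c(tr, tr + 1L))] <- FALSE
  }
  mean(predicted[keep] == truth[keep])
}
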