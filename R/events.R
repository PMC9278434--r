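#' Baseline minute ventilation at each breath
#'
#' A rolling median of per-breath V_E over the preceding `window_s`,
#' computed in two passes: a provisional pass marks candidate events (breaths
#' below the hypopnoea threshold of the provisional baseline), then the
#' baseline is recomputed with those breaths masked out, so the events
#' themselves do not drag the reference down. Breaths with less than
#' `window_s` of history use the median of the first window.
#'
#' @param vent a [minute_ventilation()] series.
#' @param window_s trailing window, seconds.
#' @param hypopnoea_frac masking threshold for the provisional pass.
#' @return Numeric vector of baseline V_E, one per breath.
#' @export
baseline_ventilation <- function(vent, window_s = 60, hypopnoea_frac = 0.5) {
  ve <- vent$ve_ml_per_kg_min
  t <- vent$t_peak_s
  ok <- !is.na(ve) & !vent$is_sigh
  ve0 <- ifelse(ok, ve, NA_real_)
  use1 <- ok
  base1 <- rolling_median_time(t, ifelse(is.na(ve0), 0, ve0), window_s, use1)
  mask <- ok & ve < (1 - hypopnoea_frac) * base1
  use2 <- ok & !mask
  if (!any(use2)) use2 <- ok
  rolling_median_time(t, ifelse(is.na(ve0), 0, ve0), window_s, use2)
}

#' Detect apnoeas and hypopnoeas on a ventilation series
#'
#' A respiratory disturbance is a maximal run of breaths whose V_E falls
#' below `(1 - hypopnoea_frac)` x baseline, lasting at least
#' `min_duration_s`, occurring during sleep. Runs separated by less than one
#' typical breath are merged before the duration test. An event is an apnoea
#' when V_E stays below `(1 - apnoea_frac)` x baseline for at least
#' `min_duration_s` within it, otherwise a hypopnoea. Depth is the maximal
#' fractional reduction `1 - min(ve / baseline)`. Each event belongs to the
#' state of its onset epoch; events whose onset epoch is WAKE or DOUBT are
#' discarded.
#'
#' @param vent a [minute_ventilation()] series.
#' @param baseline per-breath baseline from [baseline_ventilation()].
#' @param hypnogram a `hypnogram` tibble.
#' @param hypopnoea_frac,apnoea_frac fractional V_E reduction thresholds
#'   (0 < hypopnoea < apnoea <= 1).
#' @param min_duration_s minimum event duration, seconds.
#' @return A tibble of class `resp_events`: `start_s`, `end_s`,
#'   `duration_s`, `kind`, `depth`, `state`, plus arousal columns filled by
#'   [associate_arousals()]. Events are sorted and non-overlapping.
#' @export
detect_events <- function(vent, baseline, hypnogram,
                          hypopnoea_frac = 0.5, apnoea_frac = 0.9,
                          min_duration_s = 1.8) {
  abort_if(!(hypopnoea_frac > 0 && hypopnoea_frac < apnoea_frac &&
               apnoea_frac <= 1),
           "need 0 < hypopnoea_frac < apnoea_frac <= 1")
  epoch_s <- attr(hypnogram, "epoch_s") %||% 5
  ve <- vent$ve_ml_per_kg_min
  t <- vent$t_peak_s
  n <- length(ve)
  empty <- tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          duration_s = numeric(0), kind = character(0),
                          depth = numeric(0), state = character(0),
                          followed_by_arousal = logical(0),
                          arousal_latency_s = numeric(0),
                          arousal_type = character(0))
  class(empty) <- c("resp_events", class(empty))
  if (n < 3) return(empty)
  low <- !is.na(ve) & ve < (1 - hypopnoea_frac) * baseline
  low[is.na(low)] <- FALSE
  r <- rle(low)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) == 0) return(empty)
  # merge runs separated by less than one typical breath interval
  med_ibi <- stats::median(vent$ibi_s, na.rm = TRUE)
  if (nrow(runs) > 1) {
    merged <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      prev <- merged[[length(merged)]]
      gap_t <- t[runs[i, 1]] - t[prev[2]]
      gap_breaths <- runs[i, 1] - prev[2] - 1L
      if (gap_breaths <= 1L && gap_t < 3 * med_ibi) {
        merged[[length(merged)]] <- c(prev[1], runs[i, 2])
      } else {
        merged[[length(merged) + 1]] <- runs[i, ]
      }
    }
    runs <- do.call(rbind, merged)
  }

  span <- function(i1, i2) {
    # event interval: a breath's V_E covers its own inter-breath interval
    # (peak to next peak), so the run starts half a typical breath before
    # the first low peak and ends just short of the first recovered peak
    s <- if (i1 > 1) max((t[i1] + t[i1 - 1]) / 2, t[i1] - med_ibi) else
      t[i1] - med_ibi / 2
    e <- if (i2 < n) t[i2 + 1] - med_ibi / 2 else t[i2] + med_ibi / 2
    c(s, e)
  }
  out <- list()
  for (k in seq_len(nrow(runs))) {
    i1 <- runs[k, 1]; i2 <- runs[k, 2]
    se <- span(i1, i2)
    if (se[2] - se[1] < min_duration_s) next
    # state of the onset epoch; a DOUBT onset defers to the first scored
    # sleep epoch the event touches, a WAKE onset discards the interval
    ep <- floor(se[1] / epoch_s)
    st <- hypnogram$label[match(ep, hypnogram$epoch)]
    if (is.na(st) || st == "WAKE") next
    if (st == "DOUBT") {
      # DOUBT is excluded from scoring denominators, so an event landing in
      # a DOUBT pocket takes the nearest scored sleep label (the covered
      # epochs first, then the immediate neighbours); WAKE neighbours drop it
      covered <- floor(se[1] / epoch_s):floor(se[2] / epoch_s)
      labs <- hypnogram$label[match(covered, hypnogram$epoch)]
      st <- labs[which(labs %in% c("NREM", "REM"))[1]]
      if (is.na(st)) {
        nb <- hypnogram$label[match(c(covered[1] - 1L,
                                      covered[length(covered)] + 1L),
                                    hypnogram$epoch)]
        st <- nb[which(nb %in% c("NREM", "REM"))[1]]
      }
      if (is.na(st)) next
    }
    idx <- i1:i2
    ratio <- ve[idx] / baseline[idx]
    depth <- 1 - min(ratio, na.rm = TRUE)
    # apnoea: a sub-run below the apnoea threshold sustained >= min duration
    deep <- ratio < (1 - apnoea_frac)
    kind <- "hypopnoea"
    if (any(deep, na.rm = TRUE)) {
      rr <- rle(ifelse(is.na(deep), FALSE, deep))
      ee <- cumsum(rr$lengths); ss <- ee - rr$lengths + 1L
      for (j in which(rr$values)) {
        sub <- span(idx[ss[j]], idx[ee[j]])
        if (sub[2] - sub[1] >= min_duration_s) { kind <- "apnoea"; break }
      }
    }
    out[[length(out) + 1]] <- tibble::tibble(
      start_s = se[1], end_s = se[2], duration_s = se[2] - se[1],
      kind = kind, depth = depth, state = st,
      followed_by_arousal = FALSE, arousal_latency_s = NA_real_,
      arousal_type = NA_character_)
  }
  if (length(out) == 0) return(empty)
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$start_s)
  class(res) <- c("resp_events", class(res))
  res
}

#' Link respiratory events to arousals
#'
#' An arousal is a sleep-to-WAKE label transition in the hypnogram. An event
#' is flagged when an arousal occurs within `arousal_window_s` after its
#' end; the arousal is classed `"hyperpnoea"` when mean V_E in the 5 s
#' before the arousal exceeds 1.2 x baseline (the post-event recovery
#' breaths), or `"coincident"` when the arousal epoch contains the event
#' end.
#'
#' @param events a [detect_events()] tibble.
#' @param hypnogram a `hypnogram` tibble.
#' @param vent the [minute_ventilation()] series.
#' @param baseline per-breath baseline.
#' @param arousal_window_s look-ahead window after event end, seconds.
#' @return `events` with `followed_by_arousal`, `arousal_latency_s`,
#'   `arousal_type` filled.
#' @export
associate_arousals <- function(events, hypnogram, vent, baseline,
                               arousal_window_s = 15) {
  if (nrow(events) == 0) return(events)
  epoch_s <- attr(hypnogram, "epoch_s") %||% 5
  lab <- hypnogram$label
  n <- length(lab)
  # awakening: first WAKE epoch after any non-WAKE epoch (DOUBT epochs at
  # the transition belong to the awakening, not to wake maintenance)
  is_arousal <- c(FALSE, lab[-1] == "WAKE" & lab[-n] != "WAKE")
  arousal_t <- hypnogram$start_s[is_arousal]
  for (i in seq_len(nrow(events))) {
    after <- arousal_t[arousal_t >= events$end_s[i] - epoch_s &
                         arousal_t <= events$end_s[i] + arousal_window_s]
    if (length(after) == 0) next
    a <- after[1]
    events$followed_by_arousal[i] <- TRUE
    events$arousal_latency_s[i] <- max(0, a - events$end_s[i])
    pre <- vent$t_peak_s >= a - 5 & vent$t_peak_s < a &
      !is.na(vent$ve_ml_per_kg_min)
    hyper <- sum(pre) > 0 &&
      mean(vent$ve_ml_per_kg_min[pre] / baseline[pre]) > 1.2
    contains_end <- floor(events$end_s[i] / epoch_s) == floor(a / epoch_s)
    events$arousal_type[i] <- if (hyper) "hyperpnoea"
      else if (contains_end) "coincident" else "other"
  }
  events
}

#' Per-recording summary: AHI, dyspnoea time, state breakdown
#'
#' AHI is events per hour of total sleep; per-state counts and per-state
#' event seconds are each normalised by TOTAL sleep hours (the convention
#' that per-state rates share the whole-sleep denominator, so per-state
#' values sum exactly to the totals). Total sleep is NREM + REM scored
#' epochs; DOUBT is excluded.
#'
#' @param events a [detect_events()] tibble.
#' @param hypnogram a `hypnogram` tibble with >= 1 sleep epoch.
#' @param vent optional [minute_ventilation()] series (for resting
#'   parameters).
#' @param breaths optional sigh-flagged breath tibble from [detect_sighs()]
#'   (for the sigh rate).
#' @param resting optional resting-parameter row from [resting_parameters()].
#' @return A one-row tibble of class `recording_summary`: `sleep_hours`,
#'   `ahi_total`, `ahi_nrem`, `ahi_rem`, `dyspnoea_s_total`,
#'   `dyspnoea_s_nrem`, `dyspnoea_s_rem` (seconds per hour of sleep),
#'   `mean_event_duration_nrem_s`, `mean_event_duration_rem_s`,
#'   `frac_wake`, `frac_nrem`, `frac_rem`, and when available
#'   `resting_f_bpm`, `resting_vt_ml_per_kg`, `resting_ve_ml_per_kg_min`,
#'   `sigh_rate_per_h`.
#' @export
compute_summary <- function(events, hypnogram, vent = NULL, breaths = NULL,
                            resting = NULL) {
  hs <- summarize_hypnogram(hypnogram)
  abort_if(hs$sleep_hours <= 0, "zero sleep hours: cannot normalise AHI")
  per_state <- function(st) {
    ev <- events[events$state == st, ]
    c(n = nrow(ev) / hs$sleep_hours,
      secs = sum(ev$duration_s) / hs$sleep_hours,
      mdur = if (nrow(ev)) mean(ev$duration_s) else NA_real_)
  }
  nrem <- per_state("NREM"); rem <- per_state("REM")
  out <- tibble::tibble(
    sleep_hours = hs$sleep_hours,
    ahi_total = nrem[["n"]] + rem[["n"]],
    ahi_nrem = nrem[["n"]], ahi_rem = rem[["n"]],
    dyspnoea_s_total = nrem[["secs"]] + rem[["secs"]],
    dyspnoea_s_nrem = nrem[["secs"]], dyspnoea_s_rem = rem[["secs"]],
    mean_event_duration_nrem_s = nrem[["mdur"]],
    mean_event_duration_rem_s = rem[["mdur"]],
    frac_wake = hs$fractions[["WAKE"]],
    frac_nrem = hs$fractions[["NREM"]],
    frac_rem = hs$fractions[["REM"]]
  )
  if (!is.null(resting)) {
    out$resting_f_bpm <- resting$f_bpm
    out$resting_vt_ml_per_kg <- resting$vt_ml_per_kg
    out$resting_ve_ml_per_kg_min <- resting$ve_ml_per_kg_min
  }
  if (!is.null(breaths) && !is.null(attr(breaths, "sigh_rate_per_h"))) {
    out$sigh_rate_per_h <- attr(breaths, "sigh_rate_per_h")
  }
  stopifnot(isTRUE(all.equal(out$ahi_total, out$ahi_nrem + out$ahi_rem)),
            isTRUE(all.equal(out$dyspnoea_s_total,
                             out$dyspnoea_s_nrem + out$dyspnoea_s_rem)))
  class(out) <- c("recording_summary", class(out))
  out
}

#' Calibrate the minimum event duration from a desaturation line
#'
#' Fits a least-squares line SpO2 = a + b x duration through calibration
#' points (apnoea duration, SpO2) and returns the duration at which the line
#' crosses `resting_spo2 - desat_criterion` — the apnoea length expected to
#' produce the criterion desaturation. The slope must be negative; a warning
#' is raised when the intercept disagrees with the stated resting SpO2 by
#' more than 1 percentage point.
#'
#' @param points a data frame with columns `duration_s` and `spo2_percent`
#'   (>= 2 distinct durations).
#' @param resting_spo2_percent resting saturation, percent.
#' @param desat_criterion_percent desaturation criterion, percentage points.
#' @return Minimum event duration, seconds.
#' @examples
#' pts <- data.frame(duration_s = c(0, 10), spo2_percent = c(100, 90))
#' calibrate_min_event_duration(pts, 100, 4)  # 4 s
#' @export
calibrate_min_event_duration <- function(points, resting_spo2_percent = 99,
                                         desat_criterion_percent = 4) {
  abort_if(length(unique(points$duration_s)) < 2,
           "need >= 2 points with distinct durations")
  abort_if(any(points$spo2_percent <= 0 | points$spo2_percent > 100),
           "SpO2 must lie in (0, 100]")
  fit <- stats::lm(spo2_percent ~ duration_s, data = points)
  a <- stats::coef(fit)[[1]]; b <- stats::coef(fit)[[2]]
  abort_if(b >= 0, "calibration line must have negative slope")
  if (abs(a - resting_spo2_percent) > 1) {
    warning("calibration intercept differs from resting SpO2 by > 1%",
            call. = FALSE)
  }
  (resting_spo2_percent - desat_criterion_percent - a) / b
}

#' Match detected events to injected ground truth
#'
#' Greedy one-to-one matching by temporal overlap: a detected event matches
#' an injected one when their intervals overlap. Returns sensitivity
#' (matched / injected) and precision (matched / detected).
#'
#' @param detected,injected event tibbles with `start_s`, `end_s`.
#' @return A list: `n_detected`, `n_injected`, `n_matched`, `sensitivity`,
#'   `precision`.
#' @export
match_events <- function(detected, injected) {
  used <- rep(FALSE, nrow(detected))
  matched <- 0L
  for (i in seq_len(nrow(injected))) {
    hit <- which(!used & detected$start_s < injected$end_s[i] &
                   detected$end_s > injected$start_s[i])
    if (length(hit) > 0) {
      used[hit[1]] <- TRUE
      matched <- matched + 1L
    }
  }
  list(n_detected = nrow(detected), n_injected = nrow(injected),
       n_matched = matched,
       sensitivity = if (nrow(injected)) matched / nrow(injected) else NA_real_,
       precision = if (nrow(detected)) matched / nrow(detected) else NA_real_)
}

#' Run the full respiratory pipeline on one recording
#'
#' Breath detection, tidal volume, staging, sigh flagging, quiet-wake
#' selection, baseline, event detection, arousal linkage and the recording
#' summary, in one call.
#'
#' @param airflow,eeg,emg [signal_trace()] channels.
#' @param calibration a [calibration_info()].
#' @param config a config list (see [default_config()]).
#' @return A list: `breaths`, `vent`, `hypnogram`, `baseline`, `events`,
#'   `quiet_wake`, `resting`, `summary`.
#' @export
analyze_recording <- function(airflow, eeg, emg, calibration,
                              config = default_config()) {
  breaths <- compute_vt(detect_breaths(airflow), calibration)
  hyp <- stage_sleep(eeg, emg, config)
  breaths <- detect_sighs(breaths, config$k_sigh, hyp)
  vent <- minute_ventilation(breaths)
  base <- baseline_ventilation(vent, config$baseline_window_s,
                               config$hypopnoea_frac)
  events <- detect_events(vent, base, hyp, config$hypopnoea_frac,
                          config$apnoea_frac, config$min_duration_s)
  events <- associate_arousals(events, hyp, vent, base,
                               config$arousal_window_s)
  qw <- select_quiet_wake(hyp, config$quiet_wake_min_s)
  resting <- if (!is.null(qw)) resting_parameters(vent, qw) else NULL
  summary <- compute_summary(events, hyp, vent, breaths, resting)
  list(breaths = breaths, vent = vent, hypnogram = hyp, baseline = base,
       events = events, quiet_wake = qw, resting = resting, summary = summary)
}
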