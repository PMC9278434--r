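# Synthetic plethysmography + EEG/EMG recordings with known ground truth.
#
# Airflow is built breath-by-breath as a raised-cosine cycle (one inspiration
# peak, one expiration trough per breath; peak-minus-trough equals the breath
# amplitude). Injected respiratory events scale breath amplitude by
# (1 - depth), so instantaneous minute ventilation drops to exactly
# (1 - depth) x its local baseline for the scripted span. EEG is band-limited
# noise whose delta (0.5-4 Hz) power dominates in NREM and theta (6-10 Hz)
# power dominates in REM; EMG is scaled white noise, high in wakefulness, low
# in NREM and near-absent in REM.

# Band-power envelopes (uV RMS within band) per state. Chosen once to mimic
# rodent cortical EEG contrast (delta roughly trebles in NREM, theta trebles
# in REM) and trapezius tone (quiet/active wakefulness bimodal, REM atonia).
.EEG_DELTA_ENV <- c(WAKE = 10, NREM = 30, REM = 8)
.EEG_THETA_ENV <- c(WAKE = 12, NREM = 10, REM = 30)
.EMG_ENV <- c(WAKE_ACTIVE = 30, WAKE_QUIET = 20, NREM = 8, REM = 1.5)
.F_MULT <- c(WAKE = 1, NREM = 0.92, REM = 0.97)
.AMP_MULT <- c(WAKE = 1, NREM = 1.05, REM = 0.9)

place_events <- function(protocol, bouts) {
  sleep <- bouts[bouts$state %in% c("NREM", "REM"), ]
  sleep_hours <- sum(sleep$end_s - sleep$start_s) / 3600
  n_total <- round(protocol$event_rate_per_h_sleep * sleep_hours)
  empty <- tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          duration_s = numeric(0), depth = numeric(0),
                          kind = character(0), state = character(0),
                          scripted_arousal = logical(0))
  if (n_total == 0) return(empty)
  split <- protocol$event_state_split
  n_rem <- round(n_total * split[["REM"]] /
                   (split[["REM"]] + split[["NREM"]]))
  if (sum(bouts$state == "REM") == 0) n_rem <- 0
  n_nrem <- n_total - n_rem

  head_trim <- c(NREM = 10, REM = 8)
  gap <- 2
  draw_depth <- function(n) {
    ap <- stats::runif(n) < protocol$apnoea_fraction
    ifelse(ap, stats::runif(n, 0.91, 0.98), stats::runif(n, 0.55, 0.85))
  }
  placed <- list()
  occupied <- list()  # per bout row index: matrix of placed [start, end]

  add_event <- function(bout_i, s, e, depth, arousal) {
    st <- bouts$state[bout_i]
    placed[[length(placed) + 1]] <<- tibble::tibble(
      start_s = s, end_s = e, duration_s = e - s, depth = depth,
      kind = ifelse(depth > protocol$apnoea_frac %||% 0.9, "apnoea",
                    "hypopnoea"),
      state = st, scripted_arousal = arousal)
    key <- as.character(bout_i)
    occupied[[key]] <<- rbind(occupied[[key]], c(s - gap, e + gap))
  }

  rem_rows <- which(bouts$state == "REM")
  # scripted-arousal events sit near the end of distinct REM bouts
  n_arousal <- min(round(n_rem * protocol$arousal_fraction), length(rem_rows))
  dur_rng <- protocol$event_duration_s
  # eligible REM bouts are long enough and wake into an ACTIVE bout: an
  # apnoea-triggered awakening is a startle arousal with immediate muscle
  # tone, and the staging EMG rule needs that tone to time the arousal
  next_active <- rem_rows + 1L <= nrow(bouts) &
    !is.na(bouts$quiet[pmin(rem_rows + 1L, nrow(bouts))]) &
    !bouts$quiet[pmin(rem_rows + 1L, nrow(bouts))]
  eligible <- rem_rows[(bouts$end_s[rem_rows] - bouts$start_s[rem_rows]) >
                         head_trim[["REM"]] + dur_rng[2] + 8 & next_active]
  n_arousal <- min(n_arousal, length(eligible))
  if (n_arousal > 0) {
    pick <- eligible[sample.int(length(eligible), n_arousal)]
    for (b in pick) {
      d <- stats::runif(1, dur_rng[1], dur_rng[2])
      e <- bouts$end_s[b] - 6
      add_event(b, e - d, e, draw_depth(1), TRUE)
    }
  }

  place_in_state <- function(state, n) {
    if (n == 0) return(0L)
    rows <- which(bouts$state == state)
    lens <- pmax(0, (bouts$end_s[rows] - gap) -
                      (bouts$start_s[rows] + head_trim[[state]]))
    rows <- rows[lens > dur_rng[2] + 1]
    lens <- lens[lens > dur_rng[2] + 1]
    if (length(rows) == 0) return(0L)
    n_placed <- 0L
    for (i in seq_len(n)) {
      d <- stats::runif(1, dur_rng[1], dur_rng[2])
      for (try in seq_len(400)) {
        b <- rows[sample.int(length(rows), 1, prob = lens)]
        lo <- bouts$start_s[b] + head_trim[[state]]
        hi <- bouts$end_s[b] - gap - d
        if (hi <= lo) next
        s <- stats::runif(1, lo, hi)
        occ <- occupied[[as.character(b)]]
        if (!is.null(occ) && any(s < occ[, 2] & s + d > occ[, 1])) next
        add_event(b, s, s + d, draw_depth(1), FALSE)
        n_placed <- n_placed + 1L
        break
      }
    }
    n_placed
  }
  # REM events that cannot be placed (short or crowded REM bouts) spill into
  # NREM so the injected total stays at rate x sleep hours; only genuine
  # saturation of sleep aborts
  placed_rem <- place_in_state("REM", n_rem - n_arousal)
  spill <- (n_rem - n_arousal) - placed_rem
  placed_nrem <- place_in_state("NREM", n_nrem + spill)
  abort_if(placed_nrem < n_nrem + spill, paste0(
    "could not place injected events without overlap; ",
    "event_rate_per_h_sleep too high for the scripted architecture"))
  ev <- dplyr::arrange(dplyr::bind_rows(placed), .data$start_s)
  ev
}

place_sighs <- function(protocol, bouts, events) {
  ok <- bouts$state %in% c("NREM", "REM") |
    (bouts$state == "WAKE" & !is.na(bouts$quiet) & bouts$quiet)
  iv <- bouts[ok, c("start_s", "end_s")]
  hours <- sum(iv$end_s - iv$start_s) / 3600
  n <- stats::rpois(1, protocol$sigh_rate_per_h * hours)
  if (n == 0 || nrow(iv) == 0) return(numeric(0))
  lens <- iv$end_s - iv$start_s
  times <- numeric(0)
  guard <- 0
  while (length(times) < n && guard < 50 * n + 200) {
    guard <- guard + 1
    k <- sample.int(nrow(iv), 1, prob = lens)
    tt <- stats::runif(1, iv$start_s[k], iv$end_s[k])
    in_event <- nrow(events) > 0 &&
      any(tt > events$start_s - 1 & tt < events$end_s + 1)
    too_close <- length(times) > 0 && any(abs(times - tt) < 5)
    if (!in_event && !too_close) times <- c(times, tt)
  }
  sort(times)
}

synth_breaths <- function(protocol, bouts, events, sighs) {
  dur <- protocol$duration_s
  vt_units <- protocol$resting_vt_ml_per_kg * protocol$body_mass_kg /
    protocol$ml_per_unit
  n_guess <- ceiling(dur / (60 / protocol$resting_f_bpm) * 1.3) + 8L
  t0 <- Tb <- A <- numeric(n_guess)
  ev_id <- integer(n_guess)
  sigh_flag <- logical(n_guess)
  hyper <- events[events$scripted_arousal, , drop = FALSE]
  mod <- protocol$state_modulation
  sp <- 0L  # sigh pointer
  t <- 0; k <- 0L
  while (t < dur) {
    k <- k + 1L
    st <- state_at(bouts, t + 1e-9)
    f <- protocol$resting_f_bpm * (if (mod) .F_MULT[[st]] else 1)
    Ti <- 60 / f * (if (mod) exp(stats::rnorm(1, 0, 0.04)) else 1)
    Ai <- vt_units * (if (mod) .AMP_MULT[[st]] * exp(stats::rnorm(1, 0, 0.05))
                      else 1)
    mid <- t + Ti / 2
    e <- 0L
    if (nrow(events) > 0) {
      hit <- which(events$start_s <= mid & mid <= events$end_s)
      if (length(hit) > 0) {
        e <- hit[1]
        Ai <- Ai * (1 - events$depth[e])
      }
    }
    if (e == 0L && nrow(hyper) > 0 &&
        any(mid > hyper$end_s & mid <= hyper$end_s + 12)) {
      # post-event hyperpnoea persisting into the scripted awakening
      Ai <- Ai * 1.5
    }
    if (e == 0L && sp < length(sighs) && sighs[sp + 1L] < t + Ti) {
      Ai <- Ai * 3
      sigh_flag[k] <- TRUE
      while (sp < length(sighs) && sighs[sp + 1L] < t + Ti) sp <- sp + 1L
    }
    t0[k] <- t; Tb[k] <- Ti; A[k] <- Ai; ev_id[k] <- e
    t <- t + Ti
  }
  tibble::tibble(t0 = t0[1:k], dur = Tb[1:k], amplitude = A[1:k],
                 t_peak_s = t0[1:k] + Tb[1:k] / 2,
                 event_id = ev_id[1:k], is_sigh = sigh_flag[1:k])
}

breaths_to_airflow <- function(breaths, protocol) {
  rate <- protocol$sample_rate_hz
  n_s <- round(protocol$duration_s * rate)
  t <- (seq_len(n_s) - 1) / rate
  k <- findInterval(t, breaths$t0)
  phase <- pmin((t - breaths$t0[k]) / breaths$dur[k], 1)
  x <- breaths$amplitude[k] / 2 * (1 - cos(2 * pi * phase))
  if (protocol$noise_sd > 0) {
    vt_units <- protocol$resting_vt_ml_per_kg * protocol$body_mass_kg /
      protocol$ml_per_unit
    x <- x + stats::rnorm(n_s, 0, protocol$noise_sd * vt_units)
  }
  signal_trace(x, rate_hz = rate, label = "airflow", units = "a.u.")
}

synth_eeg_emg <- function(protocol, bouts) {
  rate <- protocol$sample_rate_hz
  n_s <- round(protocol$duration_s * rate)
  t <- (seq_len(n_s) - 1) / rate
  st <- state_at(bouts, t)
  unit_rms <- function(x) x / sqrt(mean(x^2))
  dn <- unit_rms(butter_filtfilt(stats::rnorm(n_s), rate, 0.5, 4))
  tn <- unit_rms(butter_filtfilt(stats::rnorm(n_s), rate, 6, 10))
  eeg <- dn * .EEG_DELTA_ENV[st] + tn * .EEG_THETA_ENV[st] +
    stats::rnorm(n_s, 0, 2)
  emg_env <- numeric(n_s)
  bi <- findInterval(t, bouts$start_s)
  bi[bi < 1L] <- 1L
  emg_env <- ifelse(bouts$state[bi] == "WAKE",
                    ifelse(!is.na(bouts$quiet[bi]) & bouts$quiet[bi],
                           .EMG_ENV[["WAKE_QUIET"]], .EMG_ENV[["WAKE_ACTIVE"]]),
                    .EMG_ENV[bouts$state[bi]])
  emg <- stats::rnorm(n_s) * emg_env + stats::rnorm(n_s, 0, 0.5)
  list(eeg = signal_trace(eeg, rate, label = "EEG", units = "uV"),
       emg = signal_trace(emg, rate, label = "EMG", units = "uV"))
}

#' Simulate a full synthetic recording with ground truth
#'
#' Generates airflow, EEG and EMG channels following the protocol's scripted
#' sleep architecture, with respiratory events (ventilation reductions of
#' known depth and duration) injected only into sleep bouts, sighs injected
#' into sleep plus quiet wakefulness, and a ground-truth record of everything
#' injected. Identical protocol and seed give bit-identical output.
#'
#' @param protocol a [simulation_protocol()] or [protocol_preset()].
#' @return A list of class `synthetic_recording` with elements `airflow`,
#'   `eeg`, `emg` (each a [signal_trace()]) and `truth` (protocol, bout table,
#'   epoch hypnogram, injected events/sighs, per-breath table, scripted
#'   quiet-wake interval and scripted sleep hours).
#' @examples
#' rec <- simulate_recording(protocol_preset("dta", duration_s = 300))
#' nrow(rec$truth$events)
#' @export
simulate_recording <- function(protocol) {
  validate_protocol(protocol)
  bouts <- script_bouts(protocol)
  events <- with_local_seed(protocol$seed + 1L, place_events(protocol, bouts))
  sighs <- with_local_seed(protocol$seed + 2L,
                           place_sighs(protocol, bouts, events))
  breaths <- with_local_seed(protocol$seed + 3L,
                             synth_breaths(protocol, bouts, events, sighs))
  # realized event spans: first to last breath actually attenuated
  if (nrow(events) > 0) {
    for (e in seq_len(nrow(events))) {
      hit <- which(breaths$event_id == e)
      if (length(hit) > 0) {
        events$start_s[e] <- breaths$t0[hit[1]]
        events$end_s[e] <- breaths$t0[hit[length(hit)]] +
          breaths$dur[hit[length(hit)]]
        events$duration_s[e] <- events$end_s[e] - events$start_s[e]
      }
    }
  }
  airflow <- with_local_seed(protocol$seed + 4L,
                             breaths_to_airflow(breaths, protocol))
  ee <- with_local_seed(protocol$seed + 5L, synth_eeg_emg(protocol, bouts))
  truth <- list(
    protocol = protocol,
    bouts = bouts,
    hypnogram = bouts_to_epochs(bouts, protocol$duration_s),
    events = events,
    sighs = sighs,
    breaths = breaths,
    quiet_wake = c(0, if (protocol$state_fractions[["WAKE"]] > 0)
      protocol$quiet_onset_s else 0),
    sleep_hours = sum(with(bouts, end_s - start_s)[bouts$state %in%
                                                     c("NREM", "REM")]) / 3600
  )
  structure(list(airflow = airflow, eeg = ee$eeg, emg = ee$emg, truth = truth),
            class = "synthetic_recording")
}

#' Write a synthetic recording to disk
#'
#' Airflow goes to `airflow.csv` (`time_s,flow`), EEG and EMG to
#' `eegemg.edf` (channels `EEG`, `EMG`, physical units uV), and the ground
#' truth (hypnogram, injected events and sighs, sleep hours) to `truth.json`.
#'
#' @param rec a [simulate_recording()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_timeseries_csv(rec$airflow, file.path(dir, "airflow.csv"))
  write_edf(list(EEG = rec$eeg, EMG = rec$emg), file.path(dir, "eegemg.edf"))
  tr <- rec$truth
  jsonlite::write_json(
    list(hypnogram = tr$hypnogram, events = tr$events, sighs = tr$sighs,
         quiet_wake = tr$quiet_wake, sleep_hours = tr$sleep_hours),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
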