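test_that("baseline equals the signal on constant ventilation and masks events", {
  v <- constructed_vent(600)
  base <- baseline_ventilation(v)
  expect_equal(base, rep(v$ve_ml_per_kg_min[1], nrow(v)), tolerance = 1e-9)

  dips <- data.frame(start_s = 300, duration_s = 3, depth = 0.9)
  v2 <- constructed_vent(600, dips = dips)
  base2 <- baseline_ventilation(v2)
  expect_lt(max(abs(base2 - v$ve_ml_per_kg_min[1])) /
              v$ve_ml_per_kg_min[1], 0.01)
})

test_that("baseline tracks a slow drift with bounded lag", {
  v <- constructed_vent(600)
  drift <- 1 + 0.5 * v$t_peak_s / 600
  v$ve_ml_per_kg_min <- v$ve_ml_per_kg_min * drift
  base <- baseline_ventilation(v, window_s = 60)
  late <- v$t_peak_s > 120
  # rolling median over the trailing 60 s lags by at most the window
  lag_frac <- (v$ve_ml_per_kg_min[late] - base[late]) /
    v$ve_ml_per_kg_min[late]
  expect_true(all(lag_frac >= 0))
  expect_lt(max(lag_frac), 0.5 * 60 / 600 + 0.01)
})

test_that("threshold and duration semantics classify constructed dips exactly", {
  dips <- data.frame(
    start_s   = c(100, 200, 300, 400),
    duration_s = c(3, 3, 1.5, 10),
    depth     = c(0.95, 0.6, 0.95, 0.3)
  )
  v <- constructed_vent(600, dips = dips)
  hyp <- constructed_hypnogram(rep("NREM", 120))
  base <- baseline_ventilation(v)
  ev <- detect_events(v, base, hyp)
  # the 1.5 s dip fails the >= 1.8 s rule; the 0.3 dip fails the > 50% rule
  expect_equal(nrow(ev), 2)
  expect_equal(ev$kind, c("apnoea", "hypopnoea"))
  expect_equal(ev$state, c("NREM", "NREM"))
  expect_lt(abs(ev$start_s[1] - 100), 1)
  expect_lt(abs(ev$duration_s[1] - 3), 1)
})

test_that("no events are reported on constant ventilation or during WAKE", {
  v <- constructed_vent(600)
  hyp <- constructed_hypnogram(rep("NREM", 120))
  expect_equal(nrow(detect_events(v, baseline_ventilation(v), hyp)), 0)

  dips <- data.frame(start_s = 300, duration_s = 3, depth = 0.95)
  v2 <- constructed_vent(600, dips = dips)
  wake <- constructed_hypnogram(rep("WAKE", 120))
  expect_equal(nrow(detect_events(v2, baseline_ventilation(v2), wake)), 0)
})

test_that("event counts are monotone in the thresholds", {
  set.seed(31)
  dips <- data.frame(start_s = seq(60, 540, by = 60),
                     duration_s = runif(9, 1, 6),
                     depth = runif(9, 0.4, 0.98))
  v <- constructed_vent(600, dips = dips)
  hyp <- constructed_hypnogram(rep("NREM", 120))
  base <- baseline_ventilation(v)
  n <- function(hf, md) nrow(detect_events(v, base, hyp,
                                           hypopnoea_frac = hf,
                                           min_duration_s = md))
  expect_gte(n(0.3, 1.8), n(0.5, 1.8))  # more permissive depth
  expect_gte(n(0.5, 1.8), n(0.5, 4))    # stricter duration
  expect_error(detect_events(v, base, hyp, hypopnoea_frac = 0.95,
                             apnoea_frac = 0.9), "hypopnoea_frac")
})

test_that("detected events partition into apnoeas and hypopnoeas by the 90% rule", {
  res <- cached_analysis("dta", 1, 1800)
  ev <- res$events
  expect_true(all(ev$kind %in% c("apnoea", "hypopnoea")))
  expect_true(all(ev$depth > 0.5))
  expect_true(all(diff(ev$start_s) > 0))
  expect_true(all(ev$end_s[-nrow(ev)] <= ev$start_s[-1]))
  expect_true(all(ev$duration_s >= 1.8))
  expect_true(all(ev$state %in% c("NREM", "REM")))
})

test_that("the recording summary reproduces the per-state arithmetic", {
  # 1 h of sleep holding 21 NREM events (47 s total) and 9 REM events
  # (27 s total): AHI 30, dyspnoea 74 s/h, NREM share 70%
  hyp <- constructed_hypnogram(c(rep("NREM", 600), rep("REM", 120),
                                 rep("WAKE", 100)))
  ev <- tibble::tibble(
    start_s = seq(10, by = 12, length.out = 30),
    duration_s = c(rep(47 / 21, 21), rep(27 / 9, 9)),
    end_s = start_s + duration_s,
    kind = "hypopnoea", depth = 0.6,
    state = c(rep("NREM", 21), rep("REM", 9)),
    followed_by_arousal = FALSE, arousal_latency_s = NA_real_,
    arousal_type = NA_character_
  )
  s <- compute_summary(ev, hyp)
  expect_equal(s$sleep_hours, 1)
  expect_equal(s$ahi_total, 30)
  expect_equal(s$ahi_nrem, 21)
  expect_equal(s$ahi_rem, 9)
  expect_equal(s$dyspnoea_s_total, 74)
  expect_equal(s$ahi_nrem / s$ahi_total, 0.7)

  expect_error(compute_summary(ev, constructed_hypnogram(rep("WAKE", 100))),
               "zero sleep")
})

test_that("per-state counts and durations always sum to the totals", {
  for (s in 1:3) {
    res <- cached_analysis("dta", s, 1800)
    expect_equal(res$summary$ahi_total,
                 res$summary$ahi_nrem + res$summary$ahi_rem)
    expect_equal(res$summary$dyspnoea_s_total,
                 res$summary$dyspnoea_s_nrem + res$summary$dyspnoea_s_rem)
  }
})

test_that("arousal linkage flags events followed by an awakening", {
  v <- constructed_vent(600)
  hyp_no_wake <- constructed_hypnogram(rep("NREM", 120))
  ev <- tibble::tibble(start_s = 100, end_s = 103, duration_s = 3,
                       kind = "apnoea", depth = 0.95, state = "NREM",
                       followed_by_arousal = FALSE,
                       arousal_latency_s = NA_real_,
                       arousal_type = NA_character_)
  out <- associate_arousals(ev, hyp_no_wake, v, baseline_ventilation(v))
  expect_false(out$followed_by_arousal)

  # scripted awakening 3 s after event end (event ends 102, WAKE at 105)
  labs <- rep("NREM", 120); labs[22:120] <- "WAKE"
  hyp <- constructed_hypnogram(labs)
  ev2 <- dplyr::mutate(ev, start_s = 99, end_s = 102, duration_s = 3)
  out2 <- associate_arousals(ev2, hyp, v, baseline_ventilation(v))
  expect_true(out2$followed_by_arousal)
  expect_equal(out2$arousal_latency_s, 3)
})

test_that("scripted post-event hyperpnoea arousals are classified as such", {
  n_hyper <- n_tot <- 0
  for (s in 1:6) {
    rec <- cached_recording("dta", s, 1800)
    res <- cached_analysis("dta", s, 1800)
    ta <- rec$truth$events[rec$truth$events$scripted_arousal, ]
    for (i in seq_len(nrow(ta))) {
      hit <- which(res$events$start_s < ta$end_s[i] &
                     res$events$end_s > ta$start_s[i])
      if (length(hit)) {
        n_tot <- n_tot + 1
        if (isTRUE(res$events$arousal_type[hit[1]] == "hyperpnoea")) {
          n_hyper <- n_hyper + 1
        }
      }
    }
  }
  expect_gt(n_tot, 0)
  expect_gte(n_hyper / n_tot, 0.9)
})

test_that("desaturation calibration matches its closed form", {
  pts <- data.frame(duration_s = c(0, 10), spo2_percent = c(100, 90))
  expect_equal(calibrate_min_event_duration(pts, 100, 4), 4.0)

  # arbitrary negative-slope lines through (10, 99 - 10 b), (15, 99 - 15 b)
  for (b in c(0.2, 0.5, 1.3, 2.7)) {
    pts <- data.frame(duration_s = c(10, 15),
                      spo2_percent = c(99 - 10 * b, 99 - 15 * b))
    expect_equal(calibrate_min_event_duration(pts, 99, 4), 4 / b,
                 tolerance = 1e-9)
  }

  flat <- data.frame(duration_s = c(10, 15), spo2_percent = c(90, 90))
  expect_error(calibrate_min_event_duration(flat, 99, 4), "negative slope")
  expect_error(
    calibrate_min_event_duration(
      data.frame(duration_s = c(10, 10), spo2_percent = c(90, 95)), 99, 4),
    "distinct")
})
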