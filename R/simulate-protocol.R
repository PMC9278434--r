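#' Define a simulation protocol for a synthetic recording
#'
#' The protocol fixes everything the generator needs: recording length and
#' sample rate, the resting respiratory operating point (rate and mass-specific
#' tidal volume), the scripted sleep architecture (target time-in-state
#' fractions plus mean NREM/REM bout lengths; the WAKE dwell mean and the
#' NREM-to-REM branching probability are derived from the fraction
#' constraint), the injected respiratory-event load, sighs, and noise.
#'
#' @param duration_s recording length, seconds.
#' @param sample_rate_hz per-channel sample rate (>= 40 Hz so the 6-10 Hz
#'   theta band is well inside Nyquist).
#' @param resting_f_bpm resting breathing rate, breaths per minute.
#' @param resting_vt_ml_per_kg resting tidal volume, mL per kg body mass.
#' @param body_mass_kg animal mass, kg.
#' @param ml_per_unit volumetric calibration of the airflow channel, mL per
#'   signal unit.
#' @param state_fractions named numeric `c(WAKE=, NREM=, REM=)`, summing to 1.
#' @param nrem_dwell_s,rem_dwell_s mean bout lengths, seconds.
#' @param event_rate_per_h_sleep injected apnoea/hypopnoea rate per hour of
#'   scripted sleep.
#' @param apnoea_fraction fraction of injected events with depth > 0.9.
#' @param event_duration_s length-2 range (min, max) of event durations, s.
#' @param event_state_split named `c(NREM=, REM=)` fractions of injected
#'   events per sleep state.
#' @param arousal_fraction fraction of REM events scripted to terminate in an
#'   arousal preceded by hyperpnoea.
#' @param sigh_rate_per_h injected sigh rate per hour of sleep plus quiet
#'   wakefulness.
#' @param noise_sd additive Gaussian airflow noise, relative to the median
#'   breath amplitude.
#' @param state_modulation logical; modulate breath rate/amplitude by sleep
#'   state (and jitter breath timing). Turn off for exact-rate traces.
#' @param quiet_onset_s length of the scripted calm-wakefulness bout that
#'   opens every recording (resting parameters are read there), seconds.
#' @param seed integer seed; every random choice in the generator derives
#'   from it.
#' @return A list of class `simulation_protocol`.
#' @export
simulation_protocol <- function(duration_s = 3 * 3600,
                                sample_rate_hz = 100,
                                resting_f_bpm = 105,
                                resting_vt_ml_per_kg = 2.3,
                                body_mass_kg = 0.4,
                                ml_per_unit = 0.5,
                                state_fractions = c(WAKE = 0.50, NREM = 0.46,
                                                    REM = 0.04),
                                nrem_dwell_s = 65,
                                rem_dwell_s = 30,
                                event_rate_per_h_sleep = 30,
                                apnoea_fraction = 0.3,
                                event_duration_s = c(2, 4),
                                event_state_split = c(NREM = 0.7, REM = 0.3),
                                arousal_fraction = 0.6,
                                sigh_rate_per_h = 14,
                                noise_sd = 0.1,
                                state_modulation = TRUE,
                                quiet_onset_s = 120,
                                seed = 1L) {
  p <- as.list(environment())
  validate_protocol(p)
  structure(p, class = "simulation_protocol")
}

validate_protocol <- function(p) {
  sf <- p$state_fractions
  abort_if(!all(c("WAKE", "NREM", "REM") %in% names(sf)),
           "state_fractions must name WAKE, NREM and REM")
  abort_if(any(sf < 0), "state fractions must be >= 0")
  abort_if(abs(sum(sf) - 1) > 1e-9, "state fractions must sum to 1")
  abort_if(any(sf == 1) && any(sf[sf != 1] > 0),
           "invalid protocol: one state fraction is 1 with another > 0")
  abort_if(sf[["REM"]] > 0 && sf[["NREM"]] == 0,
           "invalid protocol: REM requires NREM (REM is entered from NREM)")
  abort_if(p$sample_rate_hz < 40,
           "sample_rate_hz must be >= 40 (4x the upper theta edge)")
  abort_if(p$duration_s <= 0, "duration_s must be > 0")
  abort_if(p$resting_f_bpm <= 0 || p$resting_vt_ml_per_kg <= 0 ||
             p$body_mass_kg <= 0 || p$ml_per_unit <= 0,
           "respiratory parameters must be > 0")
  abort_if(p$event_rate_per_h_sleep < 0 || p$sigh_rate_per_h < 0 ||
             p$noise_sd < 0, "rates and noise must be >= 0")
  abort_if(length(p$event_duration_s) != 2 ||
             p$event_duration_s[1] > p$event_duration_s[2] ||
             p$event_duration_s[1] <= 0,
           "event_duration_s must be an increasing positive pair")
  abort_if(p$apnoea_fraction < 0 || p$apnoea_fraction > 1,
           "apnoea_fraction must be in [0, 1]")
  invisible(p)
}

#' Protocol presets for the two study arms
#'
#' `"sham"` encodes the control phenotype (f 95 bpm, V_T 3.6 mL/kg, AHI 9/h,
#' sigh rate 13/h, WAKE/NREM/REM 46/48/6%); `"dta"` the lesioned sleep-apnoea
#' phenotype (f 105 bpm, V_T 2.3 mL/kg, AHI 30/h, sigh rate 14/h,
#' WAKE/NREM/REM 52/46/4%).
#'
#' @param preset `"sham"` or `"dta"`.
#' @param ... overrides passed to [simulation_protocol()].
#' @return A `simulation_protocol`.
#' @export
protocol_preset <- function(preset = c("sham", "dta"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    sham = list(resting_f_bpm = 95, resting_vt_ml_per_kg = 3.6,
                state_fractions = c(WAKE = 0.46, NREM = 0.48, REM = 0.06),
                event_rate_per_h_sleep = 9, sigh_rate_per_h = 13),
    dta  = list(resting_f_bpm = 105, resting_vt_ml_per_kg = 2.3,
                # printed group means 52/46/4% sum to 102; normalised to 1
                state_fractions = c(WAKE = 0.52, NREM = 0.46, REM = 0.04) / 1.02,
                event_rate_per_h_sleep = 30, sigh_rate_per_h = 14)
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_protocol, args)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
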