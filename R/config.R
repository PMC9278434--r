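#' Default analysis configuration
#'
#' The thresholds and band definitions used throughout the pipeline:
#' hypopnoea = ventilation reduction > 50%, apnoea > 90%, minimum event
#' duration 1.8 s; delta band 0.5-4 Hz (the 0 Hz edge of the nominal 0-4 Hz
#' delta band is raised to 0.5 Hz so the band-pass filter is realisable),
#' theta band 6-10 Hz; 5 s epochs; 5 s smoothing time constant; staging
#' percentile thresholds; sigh criterion.
#'
#' @return A named list of defaults.
#' @export
default_config <- function() {
  list(
    hypopnoea_frac   = 0.5,
    apnoea_frac      = 0.9,
    min_duration_s   = 1.8,
    delta_band_hz    = c(0.5, 4),
    theta_band_hz    = c(6, 10),
    epoch_s          = 5,
    smooth_tau_s     = 5,
    baseline_window_s = 60,
    arousal_window_s = 15,
    k_sigh           = 2,
    # staging quantiles are calibrated so a control-architecture recording
    # (WAKE/NREM/REM 46/48/6%) reproduces its state fractions: the NREM rule
    # must pass the NREM share of epochs (1 - 0.46 - 0.06 = 0.52) and the
    # WAKE rule the WAKE share (1 - 0.46 = 0.54)
    delta_hi_quantile = 0.52,
    emg_hi_quantile   = 0.54,
    td_hi_quantile    = 0.75,
    quiet_wake_min_s  = 60
  )
}

#' Load and validate a run configuration
#'
#' Reads a JSON or YAML document, fills all defaults from [default_config()],
#' rejects unknown keys and validates ranges (in particular the apnoea
#' threshold must exceed the hypopnoea threshold).
#'
#' @param path path to a `.json`, `.yaml`/`.yml` file, or `NULL` for pure
#'   defaults.
#' @return A validated named list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    abort_if(!file.exists(path), paste0("config file not found: ", path))
    user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    abort_if(length(unknown) > 0,
             paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
    cfg[names(user)] <- user
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    abort_if(!(hypopnoea_frac > 0 && hypopnoea_frac < 1),
             "hypopnoea_frac must be in (0, 1)")
    abort_if(!(apnoea_frac > hypopnoea_frac && apnoea_frac <= 1),
             "apnoea_frac must satisfy hypopnoea_frac < apnoea_frac <= 1")
    abort_if(min_duration_s <= 0, "min_duration_s must be > 0")
    abort_if(length(delta_band_hz) != 2 || diff(delta_band_hz) <= 0,
             "delta_band_hz must be an increasing pair")
    abort_if(length(theta_band_hz) != 2 || diff(theta_band_hz) <= 0,
             "theta_band_hz must be an increasing pair")
    abort_if(delta_band_hz[2] > theta_band_hz[1],
             "delta and theta bands must not overlap")
    abort_if(epoch_s <= 0 || smooth_tau_s < 0, "epoch_s/smooth_tau_s invalid")
    abort_if(k_sigh <= 1, "k_sigh must exceed 1")
  })
  cfg
}

#' Calibration from plethysmograph signal units to tidal volume
#'
#' @param ml_per_unit millilitres per airflow signal unit (from volumetric
#'   calibration of the chamber); must be > 0.
#' @param body_mass_kg animal body mass in kg; must be > 0.
#' @return A list of class `calibration_info`.
#' @export
calibration_info <- function(ml_per_unit, body_mass_kg) {
  abort_if(!is.finite(ml_per_unit) || ml_per_unit <= 0,
           "ml_per_unit must be > 0")
  abort_if(!is.finite(body_mass_kg) || body_mass_kg <= 0,
           "body_mass_kg must be > 0")
  structure(list(ml_per_unit = ml_per_unit, body_mass_kg = body_mass_kg),
            class = "calibration_info")
}
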