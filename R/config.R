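#' Default run configuration
#'
#' The fully serializable configuration of a run: circuit, geometry,
#' oscillator, solver, growth/differentiation scenarios, noise and study
#' settings, with units in the key names.  A run's config snapshot (plus the
#' package version) reproduces it bit for bit.
#'
#' @return a nested named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    circuit = list(r_s_ohm = 500, r_ct_ohm = 1e6, c_dl_farad = 50e-9,
                   r_gap_ohm = 1000, r_s_ff_slope_ohm = 0),
    geometry = list(n_electrodes = 10, electrode_diameter_um = 250,
                    well_area_cm2 = 0.8),
    bandpass = list(f0_hz = 1e4, q = 5, k = 1),
    comparator = list(vsat_volt = 3.3, loop_sign = -1, gain = 1),
    bioimpedance = list(kz_a_per_volt = NA_real_, current_limit_a = 10e-6),
    growth = list(ff_max = 0.95, growth_rate_per_day = 1.3, seed_ff = 0.05),
    differentiation = list(plateau_mean_days = 0.8, plateau_sd_days = 0.1,
                           rise_slope_per_day = 0.1, final_coverage = 1.0),
    noise = list(multiplicative_sd = 0.01, additive_sd_volt = 0, seed = 1),
    study = list(duration_days = 10, sample_period_h = 1,
                 medium_change_ff = 0.70, confluence_ff = 0.95,
                 final_window_h = 24, alpha = 0.05)),
    class = "run_config")
}

#' Parse and validate a run configuration file
#'
#' JSON only (the environment provides no YAML parser).  Missing keys are
#' filled from [default_run_config()]; unknown sections or keys are
#' rejected with a message listing them; resistances, capacitance,
#' frequencies and rates must be positive.
#'
#' @param path JSON file.
#' @return validated `run_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop_domain("config file not found: %s", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(user)
}

#' @param config a (partial) configuration list.
#' @rdname parse_config
#' @export
validate_run_config <- function(config) {
  def <- default_run_config()
  if (!is.list(config)) stop_domain("configuration must be a JSON object")
  bad_sec <- setdiff(names(config), names(def))
  if (length(bad_sec))
    stop_domain("unknown config section(s): %s", paste(bad_sec, collapse = ", "))
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(bad))
      stop_domain("unknown key(s) in '%s': %s", sec, paste(bad, collapse = ", "))
  }
  cfg <- def
  for (sec in names(config)) {
    user_sec <- as.list(config[[sec]])
    user_sec <- user_sec[!vapply(user_sec, is.null, logical(1))]  # JSON null -> default
    cfg[[sec]] <- modifyList(def[[sec]], user_sec)
  }

  pos_keys <- list(
    circuit = c("r_s_ohm", "r_ct_ohm", "c_dl_farad", "r_gap_ohm"),
    geometry = c("n_electrodes", "electrode_diameter_um", "well_area_cm2"),
    bandpass = c("f0_hz", "q", "k"),
    comparator = c("vsat_volt", "gain"),
    bioimpedance = "current_limit_a",
    growth = c("ff_max", "growth_rate_per_day", "seed_ff"),
    differentiation = c("plateau_mean_days", "rise_slope_per_day",
                        "final_coverage"),
    study = c("duration_days", "sample_period_h"))
  for (sec in names(pos_keys)) for (key in pos_keys[[sec]]) {
    v <- cfg[[sec]][[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop_domain("config %s.%s must be a positive number (got %s)",
                  sec, key, paste(format(v), collapse = ","))
  }
  if (!cfg$comparator$loop_sign %in% c(-1, 1))
    stop_domain("config comparator.loop_sign must be +1 or -1")
  if (cfg$noise$multiplicative_sd < 0 || cfg$noise$additive_sd_volt < 0)
    stop_domain("config noise SDs must be >= 0")
  class(cfg) <- "run_config"
  cfg
}

#' @param config a `run_config`.
#' @rdname parse_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Build the oscillator objects from a run configuration
#'
#' @param config a `run_config` (see [parse_config()]).
#' @return an [obt_config()].
#' @export
as_obt_config <- function(config) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  kz <- config$bioimpedance$kz_a_per_volt
  obt_config(
    bandpass = bandpass_spec(config$bandpass$f0_hz, config$bandpass$q,
                             config$bandpass$k),
    comparator = comparator_spec(config$comparator$vsat_volt,
                                 config$comparator$loop_sign,
                                 config$comparator$gain),
    bioimpedance = bioimpedance_spec(
      kz = if (is.null(kz) || is.na(kz)) NULL else kz,
      current_limit = config$bioimpedance$current_limit_a),
    circuit = interface_params(config$circuit$r_s_ohm, config$circuit$r_ct_ohm,
                               config$circuit$c_dl_farad,
                               config$circuit$r_gap_ohm,
                               config$circuit$r_s_ff_slope_ohm),
    geometry = electrode_geometry(config$geometry$n_electrodes,
                                  config$geometry$electrode_diameter_um,
                                  config$geometry$well_area_cm2))
}

#' @rdname as_obt_config
#' @export
growth_from_config <- function(config)
  growth_scenario(config$growth$ff_max, config$growth$growth_rate_per_day,
                  config$growth$seed_ff)

#' @rdname as_obt_config
#' @export
differentiation_from_config <- function(config)
  differentiation_scenario(config$differentiation$plateau_mean_days,
                           config$differentiation$plateau_sd_days,
                           config$differentiation$rise_slope_per_day,
                           config$differentiation$final_coverage)

#' @rdname as_obt_config
#' @export
noise_from_config <- function(config)
  noise_spec(config$noise$multiplicative_sd, config$noise$additive_sd_volt,
             config$noise$seed)

#' Stable short hash of a configuration (for run logs)
#'
#' FNV-1a over the canonical JSON serialization; good enough to tell
#' configurations apart in logs, not cryptographic.
#'
#' @param config any serializable list.
#' @return 8-hex-digit character hash.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        na = "null")
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
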