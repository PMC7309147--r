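#' Logistic growth scenario
#'
#' Confluence growth of seeded myoblasts:
#' `ff(t) = ff_max / (1 + exp(-r (t - t0)))` (t in days).  The default
#' midpoint is derived from the seeding coverage (`seed_ff`, the fill factor
#' at t = 0), so the defaults — seed coverage 0.05 (1e4 cells of ~400 um^2
#' in a 0.8 cm^2 well), rate 1.3/day, ceiling 0.95 — reach confluence
#' (ff >= 0.9) in 4-5 days and cross the 70% medium-change threshold on
#' day ~3.
#'
#' @param ff_max asymptotic coverage (< 1).
#' @param growth_rate logistic rate, per day.
#' @param seed_ff coverage at t = 0.
#' @param t0 optional explicit midpoint, days (overrides `seed_ff`).
#' @return object of class `growth_scenario`.
#' @export
growth_scenario <- function(ff_max = 0.95, growth_rate = 1.3,
                            seed_ff = 0.05, t0 = NULL) {
  check_positive(ff_max, "ff_max"); check_positive(growth_rate, "growth_rate")
  check_positive(seed_ff, "seed_ff")
  if (ff_max > 1) stop_domain("'ff_max' must be <= 1")
  if (seed_ff >= ff_max) stop_domain("'seed_ff' must be below 'ff_max'")
  if (is.null(t0)) t0 <- log(ff_max / seed_ff - 1) / growth_rate
  structure(list(ff_max = ff_max, growth_rate = growth_rate,
                 seed_ff = seed_ff, t0 = t0),
            class = "growth_scenario")
}

logistic_ff <- function(scen, t_days)
  scen$ff_max / (1 + exp(-scen$growth_rate * (t_days - scen$t0)))

## continuous time (days) at which the logistic crosses a coverage level
logistic_crossing <- function(scen, level) {
  if (level >= scen$ff_max) return(Inf)
  scen$t0 + log(level / (scen$ff_max - level)) / scen$growth_rate
}

#' Differentiation scenario
#'
#' After the medium change the culture stops proliferating: coverage (and
#' hence amplitude) holds for a plateau whose duration is drawn from a
#' normal distribution truncated at 0 (defaults: mean 0.8 d, SD 0.1 d).
#' Elongation and fusion into myotubes then raise an effective-coverage
#' parameter linearly at `rise_slope` per day up to `final_coverage`
#' (default 1.0, above the undifferentiated ceiling, so differentiated
#' wells end at a higher amplitude).  This is trace morphology, not a
#' mechanistic myotube model.
#'
#' @param plateau_mean mean plateau duration, days.
#' @param plateau_sd SD of the plateau duration, days.
#' @param rise_slope effective-coverage increase per day.
#' @param final_coverage ceiling of the effective coverage (<= 1).
#' @return object of class `differentiation_scenario`.
#' @export
differentiation_scenario <- function(plateau_mean = 0.8, plateau_sd = 0.1,
                                     rise_slope = 0.1, final_coverage = 1.0) {
  check_positive(plateau_mean, "plateau_mean")
  if (plateau_sd < 0) stop_domain("'plateau_sd' must be >= 0")
  check_positive(rise_slope, "rise_slope")
  check_positive(final_coverage, "final_coverage")
  if (final_coverage > 1) stop_domain("'final_coverage' must be <= 1")
  structure(list(plateau_mean = plateau_mean, plateau_sd = plateau_sd,
                 rise_slope = rise_slope, final_coverage = final_coverage),
            class = "differentiation_scenario")
}

#' @param scen a `differentiation_scenario`.
#' @param n number of draws.
#' @return plateau durations in days (normal truncated at 0, by rejection).
#' @rdname differentiation_scenario
#' @export
draw_plateau <- function(scen, n = 1) {
  if (scen$plateau_sd == 0) return(rep(scen$plateau_mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    d <- rnorm(n, scen$plateau_mean, scen$plateau_sd)
    out <- c(out, d[d >= 0])
  }
  out[seq_len(n)]
}

#' Measurement noise specification
#'
#' Multiplicative Gaussian gain noise (default 1%) plus an optional
#' additive term, all drawn from one seeded generator at study level.
#'
#' @param multiplicative_sd relative SD of the gain noise.
#' @param additive_sd additive SD, volts.
#' @param seed integer RNG seed recorded in the ground truth.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(multiplicative_sd = 0.01, additive_sd = 0, seed = 1L) {
  if (multiplicative_sd < 0 || additive_sd < 0)
    stop_domain("noise SDs must be >= 0")
  structure(list(multiplicative_sd = multiplicative_sd,
                 additive_sd = additive_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Default 7-well study layout
#'
#' One column of the 8-well array as used in the experiments: wells 1 and 5
#' carry medium only, wells 2-4 undifferentiated cells, wells 6-7 cells for
#' differentiation; wells 4 and 7 are current-free controls and are never
#' monitored, so a default study emits 5 traces (wells 1, 2, 3, 5, 6).
#'
#' @return data.frame with columns `well`, `condition`, `monitored`.
#' @export
study_layout <- function() {
  data.frame(
    well = as.character(1:7),
    condition = c("medium_only", "undifferentiated", "undifferentiated",
                  "undifferentiated", "medium_only", "differentiated",
                  "differentiated"),
    monitored = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
}

#' Simulate one well's coverage trajectory with ground-truth events
#'
#' Undifferentiated wells follow the logistic to `ff_max`; differentiated
#' wells follow it until the 70% medium-change threshold, freeze for the
#' plateau duration, then rise linearly to `final_coverage`; medium-only
#' wells sit at coverage 0.  All event times are returned.
#'
#' @param times_h sampling times, hours, increasing.
#' @param condition well condition (see [amplitude_trace()]).
#' @param growth a [growth_scenario()].
#' @param diff a [differentiation_scenario()] (differentiated wells).
#' @param medium_change_ff threshold coverage triggering the medium change.
#' @param plateau_days plateau duration for this well, days; drawn via
#'   [draw_plateau()] when `NULL`.
#' @return list with `coverage` (vector along `times_h`) and `events`
#'   (list: `medium_change_h`, `plateau_duration_d`, `plateau_end_h`,
#'   `rise_end_h`; NA where not applicable).
#' @export
simulate_ff_trajectory <- function(times_h, condition,
                                   growth = growth_scenario(),
                                   diff = differentiation_scenario(),
                                   medium_change_ff = 0.70,
                                   plateau_days = NULL) {
  if (any(base::diff(times_h) <= 0)) stop_domain("'times_h' must be increasing")
  condition <- match.arg(condition, TRACE_CONDITIONS)
  t_d <- times_h / 24
  ev <- list(medium_change_h = NA_real_, plateau_duration_d = NA_real_,
             plateau_end_h = NA_real_, rise_end_h = NA_real_)
  if (condition == "medium_only")
    return(list(coverage = rep(0, length(times_h)), events = ev))
  if (condition != "differentiated")
    return(list(coverage = logistic_ff(growth, t_d), events = ev))

  t_mc <- logistic_crossing(growth, medium_change_ff)
  if (!is.finite(t_mc) || t_mc >= max(t_d))
    stop_domain("the %.0f%% medium-change threshold is not reached within the study",
                100 * medium_change_ff)
  D <- if (is.null(plateau_days)) draw_plateau(diff) else plateau_days
  t_rise_end <- t_mc + D +
    max(0, (diff$final_coverage - medium_change_ff) / diff$rise_slope)
  cov <- ifelse(t_d < t_mc, logistic_ff(growth, t_d),
         ifelse(t_d < t_mc + D, medium_change_ff,
                pmin(diff$final_coverage,
                     medium_change_ff + diff$rise_slope * (t_d - t_mc - D))))
  ev$medium_change_h <- t_mc * 24
  ev$plateau_duration_d <- D
  ev$plateau_end_h <- (t_mc + D) * 24
  ev$rise_end_h <- t_rise_end * 24
  list(coverage = cov, events = ev)
}

#' Simulate a full monitored study
#'
#' Generates every monitored well's coverage trajectory, maps it through
#' the oscillator forward model (`solve_oscillation` at each sample, or a
#' dense pre-tabulated calibration with monotone-spline interpolation when
#' `solver = "interpolate"` — numerically indistinguishable at the default
#' noise level and much faster for ensembles), applies measurement noise,
#' and returns traces plus full ground truth.  Unmonitored wells produce no
#' trace.  The same seed reproduces the study bit for bit.
#'
#' @param layout data.frame like [study_layout()].
#' @param growth a [growth_scenario()].
#' @param diff a [differentiation_scenario()].
#' @param noise a [noise_spec()].
#' @param config an [obt_config()].
#' @param duration_days study length, days.
#' @param sample_period_h sampling period, hours (60 min by default).
#' @param medium_change_ff threshold coverage for the medium change.
#' @param solver `"exact"` or `"interpolate"`.
#' @param seed RNG seed; defaults to the noise spec's.
#' @return object of class `obt_study`: list with `traces` (named list of
#'   [amplitude_trace()]), `truth` (per-well events, coverage, parameters),
#'   `layout`, `config`, `seed`.
#' @export
simulate_study <- function(layout = study_layout(),
                           growth = growth_scenario(),
                           diff = differentiation_scenario(),
                           noise = noise_spec(),
                           config = default_obt_config(),
                           duration_days = 10, sample_period_h = 1,
                           medium_change_ff = 0.70,
                           solver = c("exact", "interpolate"),
                           seed = noise$seed) {
  solver <- match.arg(solver)
  stopifnot(is.data.frame(layout),
            all(c("well", "condition", "monitored") %in% names(layout)))
  if (nrow(layout) == 0L) stop_domain("empty study layout")
  times_h <- seq(0, duration_days * 24, by = sample_period_h)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  amp_fun <- if (solver == "exact") {
    cache <- new.env(parent = emptyenv())
    function(ff) {
      key <- sprintf("%.12g", ff)
      if (!is.null(cache[[key]])) return(cache[[key]])
      s <- predict_oscillation(config, ff)
      if (!isTRUE(s$converged))
        stop_domain("oscillation solver failed at coverage %.4g: %s", ff, s$message)
      cache[[key]] <- s$a_osc
      s$a_osc
    }
  } else {
    cal <- build_calibration(config, ff = seq(0, 1, by = 0.005))
    fn <- splinefun(cal$ff, cal$a_osc_volt, method = "hyman")
    function(ff) fn(ff)
  }

  traces <- list(); truth <- list()
  for (i in seq_len(nrow(layout))) {
    well <- layout$well[i]; cond <- layout$condition[i]
    traj <- if (cond == "differentiated")
      simulate_ff_trajectory(times_h, cond, growth, diff,
                             medium_change_ff = medium_change_ff,
                             plateau_days = draw_plateau(diff))
    else simulate_ff_trajectory(times_h, cond, growth, diff,
                                medium_change_ff = medium_change_ff)
    truth[[well]] <- c(list(condition = cond,
                            monitored = layout$monitored[i],
                            coverage = traj$coverage), traj$events)
    if (!layout$monitored[i]) next
    a_clean <- vapply(traj$coverage, amp_fun, numeric(1))
    a <- a_clean * (1 + rnorm(length(a_clean), 0, noise$multiplicative_sd)) +
      rnorm(length(a_clean), 0, noise$additive_sd)
    traces[[well]] <- amplitude_trace(well, times_h, a, cond)
  }
  structure(list(traces = traces, truth = truth, layout = layout,
                 times_h = times_h, growth = unclass(growth),
                 diff = unclass(diff), noise = unclass(noise),
                 config = config, seed = as.integer(seed),
                 solver = solver),
            class = "obt_study")
}

#' @export
print.obt_study <- function(x, ...) {
  cat(sprintf("<obt_study> %d wells (%d monitored traces), %.0f h @ %g h, seed %d\n",
              nrow(x$layout), length(x$traces), max(x$times_h),
              median(diff(x$times_h)), x$seed))
  invisible(x)
}

#' Write / reload a simulated study as plain-text fixtures
#'
#' `traces.csv` (the [load_traces()] schema), `truth.json` (per-well ground
#' truth: condition, event times, plateau draw, coverage trajectory) and
#' `config.json` (scenario, noise and circuit snapshot).  Writing the same
#' study twice produces byte-identical files; `load_fixture()` reloads the
#' traces and ground truth.
#'
#' @param study an `obt_study`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(study, dir) {
  stopifnot(inherits(study, "obt_study"))
  if (length(study$traces) == 0L) stop_domain("study has no monitored traces")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_traces(study$traces, file.path(dir, "traces.csv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  snapshot <- list(growth = study$growth, differentiation = study$diff,
                   noise = study$noise, seed = study$seed,
                   solver = study$solver,
                   circuit = unclass(study$config$circuit),
                   bandpass = unclass(study$config$bandpass),
                   comparator = unclass(study$config$comparator),
                   bioimpedance = unclass(study$config$bioimpedance))
  jsonlite::write_json(snapshot, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' @rdname write_fixture
#' @export
load_fixture <- function(dir) {
  tr <- load_traces(file.path(dir, "traces.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  list(traces = tr, truth = truth, config = cfg)
}
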