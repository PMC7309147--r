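#' Fill factor from cell counts
#'
#' `ff = A_cell * N_cell / A_p` with the mean single-cell area in um^2 and
#' the well area in cm^2 (converted internally; all area arithmetic in the
#' package runs in um^2).  Values above 1 are returned as-is with an
#' `overflow` attribute set (and a warning) — they are never silently
#' clipped, since a supra-confluent count is a data problem the caller
#' should see.
#'
#' @param n_cell number of cells (>= 0; vectorized).
#' @param a_cell_um2 mean single-cell area, um^2.
#' @param a_p_cm2 well area, cm^2.
#' @return numeric fill factor(s) with logical attribute `overflow`.
#' @examples
#' fill_factor_from_counts(1e4, 400, 0.8)  # 0.05
#' @export
fill_factor_from_counts <- function(n_cell, a_cell_um2, a_p_cm2) {
  if (!is.numeric(a_p_cm2) || length(a_p_cm2) != 1L || is.na(a_p_cm2) ||
      a_p_cm2 <= 0)
    stop_domain("'a_p_cm2' must be a single positive well area")
  check_positive(a_cell_um2, "a_cell_um2")
  if (any(!is.finite(n_cell)) || any(n_cell < 0))
    stop_domain("'n_cell' must be finite and >= 0")
  ff <- a_cell_um2 * n_cell / cm2_to_um2(a_p_cm2)
  over <- ff > 1
  if (any(over))
    warning(sprintf("%d fill factor(s) exceed 1 (supra-confluent input)",
                    sum(over)), call. = FALSE)
  attr(ff, "overflow") <- over
  ff
}

#' Build an amplitude/frequency calibration curve over fill factor
#'
#' Tabulates the oscillation solution on a fill-factor grid.  The curve is
#' flagged `monotone` when the amplitude channel is strictly monotone — the
#' property that makes amplitude traces interpretable as coverage; the
#' solver configuration is attached so that inversion can refine against the
#' forward model.
#'
#' @param config an [obt_config()].
#' @param ff fill-factor grid in `[0, 1]`.
#' @return object of class `calibration_curve`: data.frame with columns
#'   `ff`, `a_osc_volt`, `f_osc_hz`; attributes `monotone` and `config`.
#' @export
build_calibration <- function(config, ff = seq(0, 1, by = 0.05)) {
  stopifnot(inherits(config, "obt_config"))
  if (any(ff < 0 | ff > 1)) stop_domain("'ff' grid must lie in [0, 1]")
  sols <- lapply(ff, function(f) {
    s <- predict_oscillation(config, f)
    if (!isTRUE(s$converged))
      stop_domain("oscillation solver did not converge at ff = %.4g: %s",
                  f, s$message)
    s
  })
  curve <- data.frame(ff = ff,
                      a_osc_volt = vapply(sols, `[[`, numeric(1), "a_osc"),
                      f_osc_hz = vapply(sols, `[[`, numeric(1), "f_osc"))
  d <- diff(curve$a_osc_volt)
  attr(curve, "monotone") <- length(d) == 0L || all(d > 0) || all(d < 0)
  attr(curve, "config") <- config
  class(curve) <- c("calibration_curve", "data.frame")
  curve
}

#' @param curve a `calibration_curve`.
#' @param path CSV path (`ff,a_osc_volt,f_osc_hz`).
#' @rdname build_calibration
#' @export
write_calibration <- function(curve, path) {
  stopifnot(all(c("ff", "a_osc_volt", "f_osc_hz") %in% names(curve)))
  write.csv(as.data.frame(curve)[c("ff", "a_osc_volt", "f_osc_hz")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname build_calibration
#' @export
read_calibration <- function(path, config = NULL) {
  df <- read.csv(path)
  need <- c("ff", "a_osc_volt", "f_osc_hz")
  if (!all(need %in% names(df)))
    stop_domain("calibration file misses columns: %s",
                paste(setdiff(need, names(df)), collapse = ", "))
  curve <- df[need]
  d <- diff(curve$a_osc_volt)
  attr(curve, "monotone") <- length(d) == 0L || all(d > 0) || all(d < 0)
  attr(curve, "config") <- config
  class(curve) <- c("calibration_curve", "data.frame")
  curve
}

#' Invert oscillation amplitude to fill factor
#'
#' Monotone (Hyman) spline interpolation of the calibration curve gives an
#' initial estimate; when the curve carries its solver configuration the
#' estimate is refined by root finding on the forward model
#' `a_osc(ff) = a`, so noiseless round trips are exact to ~1e-9.
#' Measurements outside the calibrated amplitude range are accepted within a
#' relative tolerance band (`tol_band`, default 2%) at either end and mapped
#' to the endpoint; beyond the band a range error is raised.  A
#' non-monotone curve is unusable for inversion and raises an error.
#'
#' @param a measured amplitude(s), volts.
#' @param curve a `calibration_curve` (monotone).
#' @param tol_band relative out-of-range tolerance at the curve ends.
#' @param refine refine with the forward solver when the configuration is
#'   available (default).
#' @param strict raise a range error for amplitudes beyond the tolerance
#'   band (default); `strict = FALSE` returns `NA` for those instead
#'   (useful when mapping whole noisy traces).
#' @return fill-factor estimate(s).
#' @export
amplitude_to_ff <- function(a, curve, tol_band = 0.02,
                            refine = !is.null(attr(curve, "config")),
                            strict = TRUE) {
  if (!isTRUE(attr(curve, "monotone")))
    stop_domain("calibration curve is not strictly monotone: unusable for inversion")
  ffg <- curve$ff; ag <- curve$a_osc_volt
  if (length(ffg) == 1L) return(rep(ffg, length(a)))
  if (ag[1] > ag[length(ag)]) { ffg <- rev(ffg); ag <- rev(ag) }
  config <- attr(curve, "config")
  inv <- if (length(ag) >= 4) splinefun(ag, ffg, method = "hyman")
         else function(x) approx(ag, ffg, xout = x, rule = 2)$y
  lo <- ag[1]; hi <- ag[length(ag)]

  vapply(a, function(ai) {
    if (!is.finite(ai)) {
      if (strict) stop_domain("non-finite amplitude")
      return(NA_real_)
    }
    if (ai < lo) {
      if (ai >= lo * (1 - tol_band)) return(ffg[1])
      if (strict)
        stop_domain("amplitude %.4g V below calibrated range [%.4g, %.4g]", ai, lo, hi)
      return(NA_real_)
    }
    if (ai > hi) {
      if (ai <= hi * (1 + tol_band)) return(ffg[length(ffg)])
      if (strict)
        stop_domain("amplitude %.4g V above calibrated range [%.4g, %.4g]", ai, lo, hi)
      return(NA_real_)
    }
    ff0 <- min(max(inv(ai), ffg[1]), ffg[length(ffg)])
    if (!refine || is.null(config)) return(ff0)
    j <- findInterval(ai, ag, rightmost.closed = TRUE)
    bracket <- c(ffg[max(1, j)], ffg[min(length(ffg), j + 1L)])
    g <- function(f) predict_oscillation(config, f)$a_osc - ai
    glo <- g(bracket[1]); ghi <- g(bracket[2])
    if (glo == 0) return(bracket[1])
    if (ghi == 0) return(bracket[2])
    if (sign(glo) == sign(ghi)) return(ff0)  # interp error outside cell; keep spline
    uniroot(g, bracket, f.lower = glo, f.upper = ghi,
            tol = .Machine$double.eps^0.75)$root
  }, numeric(1))
}

#' Fit interface parameters to oscillation observations
#'
#' Weighted least squares of log-residuals of the forward oscillation model
#' over observations `(ff, a_osc)` (and optionally `f_osc`): the relative
#' (log) loss lets volt-scale amplitudes and hertz-scale frequencies be
#' mixed.  Free parameters (any of `R_s`, `R_ct`, `C_dl`, `R_gap`) are
#' optimized on the log scale with positivity implied; standard errors come
#' from the Jacobian at the optimum.
#'
#' @param obs data.frame with columns `ff`, `a_osc_volt` and optionally
#'   `f_osc_hz`.
#' @param config an [obt_config()] providing the fixed parameters.
#' @param free character vector of free parameter names.
#' @param start optional named start values (defaults to the config values).
#' @param use_frequency also fit the frequency channel if present.
#' @param maxit maximum optimizer iterations.
#' @return object of class `interface_fit`: list with `params` (an
#'   [interface_params()] carrying the estimates), `values`, `se`,
#'   `residual_norm`, `converged`, `n_obs`.
#' @export
fit_interface_params <- function(obs, config, free = "R_gap", start = NULL,
                                 use_frequency = FALSE, maxit = 200) {
  stopifnot(inherits(config, "obt_config"), is.data.frame(obs))
  if (!all(c("ff", "a_osc_volt") %in% names(obs)))
    stop_domain("'obs' needs columns ff and a_osc_volt")
  ok <- c("R_s", "R_ct", "C_dl", "R_gap")
  if (!length(free) || !all(free %in% ok))
    stop_domain("'free' must be a subset of %s", paste(ok, collapse = ", "))
  use_frequency <- use_frequency && "f_osc_hz" %in% names(obs)
  n_resid <- nrow(obs) * (1L + use_frequency)
  if (nrow(obs) < length(free))
    stop_domain("need at least as many observations (%d) as free parameters (%d)",
                nrow(obs), length(free))

  base <- config$circuit
  make_params <- function(th) {
    vals <- unclass(base)
    vals[free] <- as.list(exp(th))
    do.call(interface_params, vals)
  }
  resids <- function(th) {
    p <- make_params(th)
    r <- unlist(lapply(seq_len(nrow(obs)), function(i) {
      m <- cell_electrode_model(p, obs$ff[i])
      s <- solve_oscillation(config$bandpass, config$bioimpedance,
                             config$comparator, m)
      if (!isTRUE(s$converged)) return(rep(1e3, 1L + use_frequency))
      out <- log(s$a_osc) - log(obs$a_osc_volt[i])
      if (use_frequency) out <- c(out, log(s$f_osc) - log(obs$f_osc_hz[i]))
      out
    }))
    r
  }
  obj <- function(th) sum(resids(th)^2)

  th0 <- log(unlist(if (is.null(start)) unclass(base)[free] else start[free]))
  opt <- if (length(th0) == 1L)
    optim(th0, obj, method = "Brent", lower = th0 - log(100),
          upper = th0 + log(100), control = list(maxit = maxit))
  else
    optim(th0, obj, method = "BFGS", control = list(maxit = maxit))
  th <- opt$par
  r <- resids(th)
  p_hat <- length(th)
  sigma2 <- sum(r^2) / max(1L, length(r) - p_hat)
  ## numerical Jacobian of the residual vector (forward differences)
  J <- vapply(seq_along(th), function(k) {
    d <- 1e-6 * max(1, abs(th[k]))
    thk <- th; thk[k] <- thk[k] + d
    (resids(thk) - r) / d
  }, numeric(length(r)))
  J <- matrix(J, nrow = length(r))
  se_log <- tryCatch(sqrt(diag(solve(crossprod(J))) * sigma2),
                     error = function(e) rep(NA_real_, p_hat))
  values <- setNames(exp(th), free)
  structure(list(params = make_params(th), values = values,
                 se = setNames(values * se_log, free),
                 residual_norm = sqrt(sum(r^2)),
                 converged = opt$convergence == 0,
                 n_obs = nrow(obs), free = free,
                 used_frequency = use_frequency),
            class = "interface_fit")
}

#' @export
print.interface_fit <- function(x, ...) {
  cat(sprintf("<interface_fit> %s (n=%d, residual %.3g%s)\n",
              paste(sprintf("%s=%.6g (se %.2g)", x$free, x$values, x$se),
                    collapse = ", "),
              x$n_obs, x$residual_norm,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Bulk resistance from the undifferentiated wells
#'
#' The bulk (electrode-to-tissue) resistance of a differentiated well is
#' taken as the arithmetic mean of the gap resistances fitted in the same
#' experiment's undifferentiated wells.
#'
#' @param rgap vector of per-well gap resistances, Ohm.
#' @return mean gap resistance, Ohm.
#' @examples
#' derive_rbulk(c(1017.6, 1009.2))  # 1013.4
#' @export
derive_rbulk <- function(rgap) {
  if (!is.numeric(rgap) || length(rgap) == 0L)
    stop_domain("'rgap' must be a non-empty numeric vector")
  if (any(!is.finite(rgap)) || any(rgap <= 0))
    stop_domain("gap resistances must be positive and finite")
  mean(rgap)
}

#' Tissue resistance from differentiated-well amplitudes
#'
#' One-dimensional least squares for `R_tissue` under the tissue forward
#' model with `R_bulk` held fixed: the model amplitude is strictly monotone
#' in `R_tissue`, so the log-loss minimizer satisfies
#' `log a_model(R_tissue) = mean(log a_obs)` and is found by root bracketing
#' on `interval`.  If the mean observed amplitude is unreachable inside the
#' interval the boundary value is returned flagged as not converged.
#'
#' @param amplitudes observed oscillation amplitudes in the differentiated
#'   (full-coverage) regime, volts.
#' @param config an [obt_config()]; `R_ct`, `C_dl` and `R_s` (applied at
#'   full coverage, including the fill-factor slope hook) are taken from its
#'   circuit.
#' @param R_bulk fixed bulk resistance, Ohm (from [derive_rbulk()]).
#' @param interval search interval for `R_tissue`, Ohm.
#' @return list with `R_tissue` (Ohm), `converged`, `residual_norm`.
#' @export
derive_rtissue <- function(amplitudes, config, R_bulk,
                           interval = c(1e-2, 1e5)) {
  stopifnot(inherits(config, "obt_config"))
  if (!is.numeric(amplitudes) || length(amplitudes) == 0L ||
      any(!is.finite(amplitudes)) || any(amplitudes <= 0))
    stop_domain("'amplitudes' must be positive finite values")
  check_positive(R_bulk, "R_bulk")
  p <- config$circuit
  fwd <- function(rt) {
    tm <- tissue_model(R_bulk, rt, R_ct = p$R_ct, C_dl = p$C_dl,
                       R_s = p$R_s + p$R_s_ff_slope, include_R_s = TRUE)
    s <- solve_oscillation(config$bandpass, config$bioimpedance,
                           config$comparator, tm)
    if (!isTRUE(s$converged)) NA_real_ else log(s$a_osc)
  }
  target <- mean(log(amplitudes))
  g <- function(rt) fwd(rt) - target
  glo <- g(interval[1]); ghi <- g(interval[2])
  if (!is.finite(glo) || !is.finite(ghi) || sign(glo) == sign(ghi)) {
    rt <- if (is.finite(glo) && abs(glo) < abs(ghi)) interval[1] else interval[2]
    r <- fwd(rt) - log(amplitudes)
    return(list(R_tissue = rt, converged = FALSE,
                residual_norm = sqrt(sum(r^2))))
  }
  rt <- uniroot(g, interval, f.lower = glo, f.upper = ghi,
                tol = 1e-7)$root
  r <- fwd(rt) - log(amplitudes)
  list(R_tissue = rt, converged = TRUE, residual_norm = sqrt(sum(r^2)))
}
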