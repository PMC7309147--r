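TRACE_CONDITIONS <- c("medium_only", "undifferentiated", "differentiated",
                      "unmonitored")

#' Per-well oscillation-amplitude trace
#'
#' One monitored well: oscillation amplitude sampled (nominally) every hour.
#'
#' @param well well identifier (coerced to character).
#' @param time_h sampling times, hours, strictly increasing.
#' @param amplitude_v oscillation amplitudes, volts.
#' @param condition one of `"medium_only"`, `"undifferentiated"`,
#'   `"differentiated"`, `"unmonitored"`.
#' @param freq_hz optional oscillation frequencies, Hz.
#' @return object of class `amplitude_trace`.
#' @export
amplitude_trace <- function(well, time_h, amplitude_v,
                            condition = "unmonitored", freq_hz = NULL) {
  condition <- match.arg(condition, TRACE_CONDITIONS)
  if (length(time_h) != length(amplitude_v))
    stop_domain("time and amplitude vectors must have equal length")
  if (!is.null(freq_hz) && length(freq_hz) != length(time_h))
    stop_domain("freq_hz must match the time vector length")
  if (any(!is.finite(time_h)) || any(diff(time_h) <= 0))
    stop_domain("'time_h' must be finite and strictly increasing")
  if (any(!is.finite(amplitude_v)))
    stop_domain("'amplitude_v' must be finite")
  structure(list(well = as.character(well), time_h = as.numeric(time_h),
                 amplitude_v = as.numeric(amplitude_v),
                 condition = condition,
                 freq_hz = if (is.null(freq_hz)) NULL else as.numeric(freq_hz)),
            class = "amplitude_trace")
}

#' @export
print.amplitude_trace <- function(x, ...) {
  cat(sprintf("<amplitude_trace> well %s (%s): %d samples, %.1f-%.1f h\n",
              x$well, x$condition, length(x$time_h), min(x$time_h),
              max(x$time_h)))
  invisible(x)
}

#' Read / write per-well amplitude traces
#'
#' CSV schema: `well,time_h,amplitude_v[,freq_hz][,condition]`, comma
#' separated, '.' decimal, header required.  Rows are grouped by well;
#' within each well times must be strictly increasing (a duplicated
#' timestamp is a format error naming the offending row).  A warning is
#' issued when the median sampling interval of a well deviates more than
#' 10% from the nominal 60 min.
#'
#' @param path CSV file.
#' @param conditions optional named character vector mapping well id to
#'   condition; overrides any `condition` column.
#' @return named list of [amplitude_trace()] objects.
#' @export
load_traces <- function(path, conditions = NULL) {
  if (!file.exists(path)) stop_domain("trace file not found: %s", path)
  df <- read.csv(path, colClasses = c(well = "character"))
  need <- c("well", "time_h", "amplitude_v")
  if (!all(need %in% names(df)))
    stop_domain("trace file misses columns: %s",
                paste(setdiff(need, names(df)), collapse = ", "))
  has_freq <- "freq_hz" %in% names(df)
  has_cond <- "condition" %in% names(df)
  traces <- lapply(split(seq_len(nrow(df)), df$well), function(idx) {
    sub <- df[idx, ]
    dt <- diff(sub$time_h)
    if (any(dt <= 0)) {
      bad <- idx[which(dt <= 0)[1] + 1L]
      stop_domain("non-increasing or duplicated timestamp at row %d (well %s)",
                  bad, sub$well[1])
    }
    if (length(dt) > 0 && abs(median(dt) - 1) > 0.1)
      warning(sprintf("well %s: median sampling interval %.2f h deviates >10%% from 60 min",
                      sub$well[1], median(dt)), call. = FALSE)
    cond <- if (!is.null(conditions) && sub$well[1] %in% names(conditions))
      conditions[[sub$well[1]]]
    else if (has_cond) sub$condition[1] else "unmonitored"
    amplitude_trace(sub$well[1], sub$time_h, sub$amplitude_v, cond,
                    freq_hz = if (has_freq) sub$freq_hz else NULL)
  })
  traces[order(names(traces))]
}

#' @param traces list of `amplitude_trace` objects.
#' @rdname load_traces
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "amplitude_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    out <- data.frame(well = tr$well, time_h = tr$time_h,
                      amplitude_v = tr$amplitude_v,
                      condition = tr$condition)
    if (!is.null(tr$freq_hz)) out$freq_hz <- tr$freq_hz
    out
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' First time the estimated coverage crosses a confluence threshold
#'
#' The calibration curve maps the threshold fill factor (70% by default,
#' the point at which the medium is switched to differentiation medium) to
#' an amplitude threshold; the lightly median-filtered trace is scanned for
#' its first crossing, linearly interpolated between samples.
#'
#' @param trace an [amplitude_trace()].
#' @param calibration a monotone `calibration_curve`.
#' @param threshold_ff coverage threshold, default 0.70.
#' @return crossing time in hours; `NA_real_` if never crossed; the first
#'   timestamp if the trace starts above threshold.
#' @export
detect_confluence_threshold <- function(trace, calibration,
                                        threshold_ff = 0.70) {
  stopifnot(inherits(trace, "amplitude_trace"))
  if (!isTRUE(attr(calibration, "monotone")))
    stop_domain("calibration curve must be monotone")
  a_thr <- if (length(calibration$ff) >= 4)
    splinefun(calibration$ff, calibration$a_osc_volt, method = "hyman")(threshold_ff)
  else approx(calibration$ff, calibration$a_osc_volt, xout = threshold_ff,
              rule = 2)$y
  increasing <- calibration$a_osc_volt[nrow(calibration)] >=
    calibration$a_osc_volt[1]
  a <- smooth_amplitude(trace$amplitude_v)
  above <- if (increasing) a >= a_thr else a <= a_thr
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1L) return(trace$time_h[1])
  t0 <- trace$time_h[i - 1L]; t1 <- trace$time_h[i]
  a0 <- a[i - 1L]; a1 <- a[i]
  if (a1 == a0) return(t1)
  t0 + (a_thr - a0) / (a1 - a0) * (t1 - t0)
}

## centered median filter, 5-sample window (edge-preserving denoising)
smooth_amplitude <- function(a, k = 5) {
  if (length(a) < k) return(a)
  as.numeric(runmed(a, k, endrule = "median"))
}

## exact least-squares summaries on index ranges via cumulative sums
segment_sums <- function(t, y) {
  list(t = c(0, cumsum(t)), y = c(0, cumsum(y)),
       tt = c(0, cumsum(t * t)), ty = c(0, cumsum(t * y)),
       yy = c(0, cumsum(y * y)))
}
sse_const <- function(S, a, b) {
  n <- b - a + 1
  sy <- S$y[b + 1] - S$y[a]; syy <- S$yy[b + 1] - S$yy[a]
  max(0, syy - sy^2 / n)
}
sse_lin <- function(S, a, b) {
  n <- b - a + 1
  if (n < 3) return(0)
  st <- S$t[b + 1] - S$t[a]; sy <- S$y[b + 1] - S$y[a]
  stt <- S$tt[b + 1] - S$tt[a]; sty <- S$ty[b + 1] - S$ty[a]
  syy <- S$yy[b + 1] - S$yy[a]
  sxx <- stt - st^2 / n; sxy <- sty - st * sy / n
  if (sxx <= 0) return(max(0, syy - sy^2 / n))
  max(0, syy - sy^2 / n - sxy^2 / sxx)
}
fit_lin <- function(t, y) {
  n <- length(y)
  if (n == 0) return(c(NA_real_, NA_real_))
  if (n < 2) return(c(y, 0))
  mt <- mean(t); my <- mean(y)
  sxx <- sum((t - mt)^2)
  b <- if (sxx > 0) sum((t - mt) * (y - my)) / sxx else 0
  c(my - b * mt, b)
}

#' Segment a trace into growth-arrest plateau and differentiation rise
#'
#' Analyses the trace from `medium_change_time` on.  The default
#' (`method = "piecewise"`) fits a penalized piecewise model — constant
#' (growth-arrest plateau), then linear (differentiation rise), then an
#' optional second linear piece (saturation once full coverage is reached) —
#' over all breakpoint pairs by exact least squares, compares it against a
#' no-plateau alternative by BIC, and refines the plateau end to the
#' continuous intersection of the plateau level with the rise line (so the
#' recovered duration is not quantized to the sampling grid).
#' `method = "slope_window"` instead flags the maximal contiguous run where
#' a 6-h windowed robust local slope stays inside a noise-calibrated bound
#' (3x the standard error implied by `noise_sd`, itself estimated from the
#' trace's first differences when not supplied).
#'
#' Delta statistics follow the experiment's definitions: `delta_growth` is
#' the (raw, unsmoothed) amplitude at the medium change minus the initial
#' amplitude; `delta_max` the maximum amplitude minus the initial amplitude.
#'
#' @param trace an [amplitude_trace()] (>= 24 samples).
#' @param medium_change_time time of the switch to differentiation medium,
#'   hours; must lie within the trace span.
#' @param method `"piecewise"` (default) or `"slope_window"`.
#' @param noise_sd optional amplitude noise SD (volts) for the slope bound;
#'   estimated robustly from first differences when `NULL`.
#' @return object of class `phase_segmentation`: list with
#'   `medium_change_time`, `plateau_start`, `plateau_end` (hours),
#'   `plateau_duration` (days), `diff_slope` (volts/day), `delta_growth`,
#'   `delta_max` (volts).
#' @export
segment_phases <- function(trace, medium_change_time,
                           method = c("piecewise", "slope_window"),
                           noise_sd = NULL) {
  stopifnot(inherits(trace, "amplitude_trace"))
  method <- match.arg(method)
  t <- trace$time_h; a <- trace$amplitude_v
  if (length(t) < 24)
    stop_domain("at least 24 samples are required for segmentation")
  if (medium_change_time < t[1] || medium_change_time > t[length(t)])
    stop_domain("medium_change_time %.2f h outside trace span [%.2f, %.2f]",
                medium_change_time, t[1], t[length(t)])
  post <- which(t >= medium_change_time - 1e-9)
  if (length(post) < 8) stop_domain("too few post-change samples (%d)", length(post))

  y_all <- smooth_amplitude(a)
  tp <- t[post]; yp <- y_all[post]
  n <- length(tp)

  if (method == "slope_window" && is.null(noise_sd))
    noise_sd <- mad(diff(a[post])) / sqrt(2)  # from raw, not smoothed, data
  seg <- if (method == "piecewise")
    segment_piecewise(tp, yp) else segment_slope_window(tp, yp, noise_sd)

  plateau_start <- if (seg$has_plateau) medium_change_time else medium_change_time
  plateau_end <- if (seg$has_plateau) seg$plateau_end else medium_change_time
  duration_d <- max(0, (plateau_end - plateau_start) / 24)
  if (!seg$has_plateau) duration_d <- 0

  ## raw (unsmoothed) delta statistics
  a_mc <- approx(t, a, xout = medium_change_time, rule = 2)$y
  structure(list(medium_change_time = medium_change_time,
                 plateau_start = plateau_start,
                 plateau_end = plateau_end,
                 plateau_duration = duration_d,
                 diff_slope = seg$diff_slope,
                 delta_growth = a_mc - a[1],
                 delta_max = max(a) - a[1],
                 method = method),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("<phase_segmentation> plateau %.2f d (%.1f-%.1f h), rise %.3g V/d, dG=%.4g V, dM=%.4g V\n",
              x$plateau_duration, x$plateau_start, x$plateau_end,
              x$diff_slope, x$delta_growth, x$delta_max))
  invisible(x)
}

## piecewise constant / quadratic / linear changepoint fit on the
## post-change window.  The rise segment is quadratic because the
## calibration curve is convex: a linear rise in coverage maps to a convex
## amplitude rise, and a straight rise segment would drag the breakpoint
## late.  Time runs in days from the window start for conditioning; the
## model is affine-equivariant in the amplitudes.
segment_piecewise <- function(tp, yp) {
  n <- length(tp)
  td <- (tp - tp[1]) / 24
  ## cumulative sums for O(1) segment least squares up to quadratic order
  cs <- function(v) c(0, cumsum(v))
  S1 <- cs(rep(1, n)); St <- cs(td); St2 <- cs(td^2); St3 <- cs(td^3)
  St4 <- cs(td^4); Sy <- cs(yp); Sty <- cs(td * yp); St2y <- cs(td^2 * yp)
  Syy <- cs(yp^2)
  rng <- function(S, a, b) S[b + 1] - S[a]
  sse_poly <- function(a, b, deg) {
    m <- b - a + 1
    if (m <= deg + 1) return(0)
    G <- matrix(c(rng(S1, a, b), rng(St, a, b), rng(St2, a, b),
                  rng(St, a, b), rng(St2, a, b), rng(St3, a, b),
                  rng(St2, a, b), rng(St3, a, b), rng(St4, a, b)), 3, 3)
    g <- c(rng(Sy, a, b), rng(Sty, a, b), rng(St2y, a, b))
    k <- deg + 1
    co <- tryCatch(solve(G[1:k, 1:k, drop = FALSE], g[1:k]),
                   error = function(e) NULL)
    if (is.null(co)) return(rng(Syy, a, b) - rng(Sy, a, b)^2 / m)
    max(0, rng(Syy, a, b) - sum(co * g[1:k]))
  }
  scale2 <- max(var(yp), (1e-12 * max(abs(yp), 1))^2)
  floor_sse <- n * 1e-20 * scale2
  bic <- function(sse, p) n * log(max(sse, floor_sse) / n) + p * log(n)

  best <- list(sse = Inf, j1 = NA_integer_, j2 = NA_integer_)
  for (j1 in 2:(n - 6L)) {
    s_plat <- sse_poly(1L, j1, 0L)
    if (s_plat >= best$sse) next
    for (j2 in (j1 + 5L):n) {
      s_rise <- sse_poly(j1 + 1L, j2, 2L)
      s_tail <- if (j2 <= n - 3L) sse_poly(j2 + 1L, n, 1L) else 0
      sse <- s_plat + s_rise + s_tail
      if (sse < best$sse) best <- list(sse = sse, j1 = j1, j2 = j2)
    }
  }
  ## no-plateau alternatives: single line, single quadratic, quadratic+line
  alt <- c(line = bic(sse_poly(1L, n, 1L), 2L),
           quad = bic(sse_poly(1L, n, 2L), 3L))
  if (n >= 12L) {
    ql <- min(vapply(6:(n - 3L), function(j)
      sse_poly(1L, j, 2L) + sse_poly(j + 1L, n, 1L), numeric(1)))
    alt <- c(alt, quadline = bic(ql, 6L))
  }
  p_best <- 1L + 3L + (if (!is.na(best$j2) && best$j2 <= n - 3L) 2L else 0L) + 2L
  use_plateau <- is.finite(best$sse) &&
    bic(best$sse, p_best) < min(alt)

  if (!use_plateau) {
    co <- fit_lin(tp, yp)
    return(list(has_plateau = FALSE, plateau_end = tp[1],
                diff_slope = co[2] * 24))
  }
  j1 <- best$j1; j2 <- best$j2
  t_end <- tp[j1]
  co <- fit_lin(tp[(j1 + 1L):j2], yp[(j1 + 1L):j2])
  list(has_plateau = TRUE, plateau_end = t_end, diff_slope = co[2] * 24)
}

## spec-style alternative: maximal run of small 6-h windowed local slopes
segment_slope_window <- function(tp, yp, noise_sd = NULL, window_h = 6) {
  n <- length(tp)
  dt <- median(diff(tp))
  half <- max(1L, round(window_h / 2 / dt))
  if (is.null(noise_sd)) noise_sd <- mad(diff(yp)) / sqrt(2)
  slopes <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    fit_lin(tp[lo:hi], yp[lo:hi])[2]
  }, numeric(1))
  sxx <- sum((seq_len(2L * half + 1L) * dt -
                mean(seq_len(2L * half + 1L) * dt))^2)
  bound <- 3 * noise_sd / sqrt(max(sxx, .Machine$double.eps)) +
    1e-9 * max(abs(yp)) / 24
  flat <- abs(slopes) <= bound
  if (!flat[1]) {
    co <- fit_lin(tp, yp)
    return(list(has_plateau = FALSE, plateau_end = tp[1],
                diff_slope = co[2] * 24))
  }
  j <- which(!flat)[1]
  j1 <- if (is.na(j)) n else j - 1L
  rest <- if (j1 < n) (j1 + 1L):n else integer(0)
  co <- if (length(rest) >= 2L) fit_lin(tp[rest], yp[rest]) else c(NA_real_, 0)
  list(has_plateau = TRUE, plateau_end = tp[j1], diff_slope = co[2] * 24)
}

#' Exact two-sample rank-sum comparison
#'
#' Two-sided rank-sum (Wilcoxon-Mann-Whitney) test with midranks for ties.
#' For small samples the null distribution is enumerated exactly over all
#' assignments of the pooled values to the two groups (the only defensible
#' choice at 2-3 wells per group); for large samples a tie-corrected normal
#' approximation is used and flagged.  The two-sided p-value is
#' `min(1, 2*min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y numeric vectors (each length >= 2): the two groups.
#' @param exact_max enumerate exactly when `choose(n, nx)` does not exceed
#'   this many arrangements.
#' @return list with `statistic` (rank sum of `x`), `p_value`, `method`.
#' @export
rank_sum_exact <- function(x, y, exact_max = 2e5) {
  if (length(x) < 2 || length(y) < 2)
    stop_domain("each group needs at least 2 observations")
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  nx <- length(x); n <- length(pooled)
  w <- sum(r[seq_len(nx)])
  if (choose(n, nx) <= exact_max) {
    combs <- utils::combn(n, nx)
    ws <- colSums(matrix(r[combs], nrow = nx))
    p <- min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
    list(statistic = w, p_value = p, method = "exact")
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(r)
    sig2 <- nx * (n - nx) / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu) / sqrt(sig2)
    list(statistic = w, p_value = min(1, 2 * (1 - stats::pnorm(abs(z)))),
         method = "normal_approx")
  }
}

#' Compare amplitude deltas between differentiated and undifferentiated wells
#'
#' Two-sample comparison of the per-well `delta_max` statistics (maximum
#' amplitude minus initial amplitude).  Default is the exact two-sided
#' rank-sum test of [rank_sum_exact()]; `method = "welch"` uses Welch's t.
#'
#' @param diff_deltas per-well deltas of the differentiated group, volts.
#' @param undiff_deltas per-well deltas of the undifferentiated group.
#' @param alpha significance level.
#' @param method `"exact"` or `"welch"`.
#' @return list with `statistic`, `p_value`, `significant`, group means and
#'   SDs, group sizes, `method`, `alpha`.
#' @export
group_compare <- function(diff_deltas, undiff_deltas, alpha = 0.05,
                          method = c("exact", "welch")) {
  method <- match.arg(method)
  if (length(diff_deltas) < 2 || length(undiff_deltas) < 2)
    stop_domain("each group needs at least 2 wells")
  res <- if (method == "exact") {
    rank_sum_exact(diff_deltas, undiff_deltas)
  } else {
    tt <- stats::t.test(diff_deltas, undiff_deltas)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         method = "welch")
  }
  list(statistic = res$statistic, p_value = res$p_value,
       significant = res$p_value < alpha,
       mean_diff = mean(diff_deltas), sd_diff = sd(diff_deltas),
       mean_undiff = mean(undiff_deltas), sd_undiff = sd(undiff_deltas),
       n = c(diff = length(diff_deltas), undiff = length(undiff_deltas)),
       method = res$method, alpha = alpha)
}

#' Assemble the per-experiment resistance table
#'
#' For each experiment: the fitted gap resistances of the undifferentiated
#' wells, their mean as the differentiated wells' bulk resistance, and the
#' tissue resistance fitted from each differentiated well's full-coverage
#' amplitudes with the bulk value held fixed.  Missing inputs yield a
#' partial table with flags rather than an error.
#'
#' @param rgap data.frame with columns `experiment`, `well`, `R_gap_ohm`
#'   (one row per undifferentiated well).
#' @param diff_obs data.frame with columns `experiment`, `well`,
#'   `a_osc_volt` (several amplitude rows per differentiated well), or NULL.
#' @param config an [obt_config()] used for the tissue forward model.
#' @return object of class `study_table`: data.frame with columns
#'   `experiment`, `well`, `differentiated`, `R_gap_ohm`, `R_bulk_ohm`,
#'   `R_tissue_ohm`, `flag`.
#' @export
build_table2 <- function(rgap, diff_obs = NULL, config = default_obt_config()) {
  stopifnot(is.data.frame(rgap),
            all(c("experiment", "well", "R_gap_ohm") %in% names(rgap)))
  rows <- lapply(split(rgap, rgap$experiment), function(sub) {
    flag <- if (nrow(sub) == 1L) "n=1" else ""
    rb <- derive_rbulk(sub$R_gap_ohm)
    und <- data.frame(experiment = sub$experiment, well = sub$well,
                      differentiated = FALSE, R_gap_ohm = sub$R_gap_ohm,
                      R_bulk_ohm = NA_real_, R_tissue_ohm = NA_real_,
                      flag = flag)
    dsub <- if (!is.null(diff_obs))
      diff_obs[diff_obs$experiment == sub$experiment[1], , drop = FALSE]
    else NULL
    dif <- if (!is.null(dsub) && nrow(dsub)) {
      do.call(rbind, lapply(split(dsub, dsub$well), function(ws) {
        fit <- derive_rtissue(ws$a_osc_volt, config, rb)
        data.frame(experiment = ws$experiment[1], well = ws$well[1],
                   differentiated = TRUE, R_gap_ohm = NA_real_,
                   R_bulk_ohm = rb, R_tissue_ohm = fit$R_tissue,
                   flag = paste0(flag, if (!fit$converged) " unconverged"))
      }))
    } else NULL
    rbind(und, dif)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("study_table", "data.frame")
  out
}

#' Run the full per-study analysis pipeline
#'
#' End-to-end analysis of a set of traces: noise estimation from the
#' medium-only wells, phase segmentation of every cell-bearing well,
#' group comparison of `delta_max` between differentiated and
#' undifferentiated wells (when both groups have >= 2 monitored wells),
#' per-well gap-resistance fits from the confluent window of the
#' undifferentiated wells, and the resistance table with bulk and tissue
#' values for the differentiated wells.
#'
#' @param traces named list of [amplitude_trace()] objects.
#' @param config an [obt_config()].
#' @param calibration optional `calibration_curve` (built from `config`
#'   when missing).
#' @param medium_change_time switch time in hours; detected from the first
#'   differentiated trace via [detect_confluence_threshold()] when `NULL`.
#' @param confluence_ff coverage assumed for the undifferentiated wells'
#'   confluent plateau (used in the gap fits).
#' @param final_window_h trailing window (hours) whose amplitudes feed the
#'   resistance fits.
#' @param experiment experiment label for the table.
#' @param alpha significance level for the group test.
#' @param out_dir optional directory; when given, the report JSON and the
#'   resistance-table CSV are written there.
#' @return object of class `study_report`.
#' @export
run_pipeline <- function(traces, config = default_obt_config(),
                         calibration = NULL, medium_change_time = NULL,
                         confluence_ff = 0.95, final_window_h = 24,
                         experiment = 1, alpha = 0.05, out_dir = NULL) {
  stopifnot(is.list(traces), length(traces) > 0)
  conds <- vapply(traces, `[[`, character(1), "condition")
  if (is.null(calibration)) calibration <- build_calibration(config)

  medium_wells <- traces[conds == "medium_only"]
  noise_sd <- if (length(medium_wells))
    median(vapply(medium_wells, function(tr) mad(diff(tr$amplitude_v)) / sqrt(2),
                  numeric(1)))
  else NA_real_

  if (is.null(medium_change_time)) {
    dtr <- traces[conds == "differentiated"]
    if (!length(dtr))
      stop_domain("no differentiated trace to detect the medium change from; supply medium_change_time")
    medium_change_time <- detect_confluence_threshold(dtr[[1]], calibration)
    if (is.na(medium_change_time))
      stop_domain("confluence threshold never crossed; supply medium_change_time")
  }

  cellw <- conds %in% c("undifferentiated", "differentiated")
  segs <- lapply(traces[cellw], segment_phases,
                 medium_change_time = medium_change_time)
  deltas <- data.frame(
    well = vapply(traces[cellw], `[[`, character(1), "well"),
    condition = conds[cellw],
    delta_growth_v = vapply(segs, `[[`, numeric(1), "delta_growth"),
    delta_max_v = vapply(segs, `[[`, numeric(1), "delta_max"),
    plateau_duration_d = vapply(segs, `[[`, numeric(1), "plateau_duration"))

  dd <- deltas$delta_max_v[deltas$condition == "differentiated"]
  ud <- deltas$delta_max_v[deltas$condition == "undifferentiated"]
  test <- if (length(dd) >= 2 && length(ud) >= 2)
    group_compare(dd, ud, alpha = alpha)
  else list(p_value = NA_real_,
            message = "need >= 2 monitored wells per group for the test")

  final_obs <- function(tr) {
    keep <- tr$time_h >= max(tr$time_h) - final_window_h
    tr$amplitude_v[keep]
  }
  und <- traces[conds == "undifferentiated"]
  rgap <- if (length(und)) {
    do.call(rbind, lapply(und, function(tr) {
      obs <- data.frame(ff = confluence_ff, a_osc_volt = final_obs(tr))
      fit <- fit_interface_params(obs, config, free = "R_gap")
      data.frame(experiment = experiment, well = tr$well,
                 R_gap_ohm = unname(fit$values["R_gap"]))
    }))
  } else NULL
  dif <- traces[conds == "differentiated"]
  diff_obs <- if (length(dif))
    do.call(rbind, lapply(dif, function(tr)
      data.frame(experiment = experiment, well = tr$well,
                 a_osc_volt = final_obs(tr))))
  else NULL
  table2 <- if (!is.null(rgap)) build_table2(rgap, diff_obs, config) else NULL

  report <- structure(list(segmentations = segs, deltas = deltas,
                           group_test = test, table2 = table2,
                           noise_sd_v = noise_sd,
                           medium_change_time_h = medium_change_time,
                           confluence_ff = confluence_ff,
                           alpha = alpha),
                      class = "study_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d wells segmented; medium change %.1f h; p = %s\n",
              nrow(x$deltas), x$medium_change_time_h,
              format(x$group_test$p_value, digits = 3)))
  if (!is.null(x$table2)) print(as.data.frame(x$table2))
  invisible(x)
}

#' Write a study report to disk
#'
#' `report.json` holds the deltas, segmentation summaries and test result;
#' `table2.csv` the resistance table.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  segs <- lapply(report$segmentations, unclass)
  payload <- list(medium_change_time_h = report$medium_change_time_h,
                  noise_sd_v = report$noise_sd_v,
                  deltas = report$deltas,
                  segmentations = segs,
                  group_test = report$group_test)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (!is.null(report$table2))
    write.csv(as.data.frame(report$table2), file.path(dir, "table2.csv"),
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}
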