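#' State-space realization of an impedance (current in, voltage out)
#'
#' Internal machinery for the transient oracle: every rational impedance
#' used by the package is realized as `x' = A x + B i`, `v = C x + D i`.
#' For the covered-electrode model the states are the two capacitor
#' voltages (one in the `ff = 0/1` limits); for the tissue model the single
#' double-layer voltage; a plain resistance has no state.
#'
#' @param Z a circuit model or a single resistance.
#' @return list with matrices `A`, `B`, `C`, `D`.
#' @export
state_space <- function(Z) UseMethod("state_space")

#' @export
state_space.numeric <- function(Z) {
  check_positive(Z, "Z (resistance)")
  list(A = matrix(0, 0, 0), B = matrix(0, 0, 1), C = matrix(0, 1, 0),
       D = matrix(Z, 1, 1))
}

#' @export
state_space.cell_electrode_model <- function(Z) {
  p <- Z$params
  if (Z$ff == 0) {
    A <- matrix(-1 / (p$R_ct * p$C_dl), 1, 1)
    B <- matrix(1 / p$C_dl, 1, 1)
    C <- matrix(1, 1, 1); D <- matrix(Z$R_s_eff, 1, 1)
  } else if (Z$ff == 1) {
    A <- matrix(-1 / (p$R_ct * p$C_dl), 1, 1)
    B <- matrix(1 / p$C_dl, 1, 1)
    C <- matrix(1, 1, 1); D <- matrix(Z$R_s_eff + p$R_gap, 1, 1)
  } else {
    ## v1: voltage across C_1 (node above both branches)
    ## v2: voltage across C_2 (behind R_gap)
    A <- matrix(c(-(1 / Z$R_1 + 1 / p$R_gap) / Z$C_1, 1 / (p$R_gap * Z$C_1),
                  1 / (p$R_gap * Z$C_2), -(1 / p$R_gap + 1 / Z$R_2) / Z$C_2),
                2, 2, byrow = TRUE)
    B <- matrix(c(1 / Z$C_1, 0), 2, 1)
    C <- matrix(c(1, 0), 1, 2)
    D <- matrix(Z$R_s_eff, 1, 1)
  }
  list(A = A, B = B, C = C, D = D)
}

#' @export
state_space.tissue_model <- function(Z) {
  series <- Z$R_bulk + Z$R_tissue + if (Z$include_R_s) Z$R_s else 0
  list(A = matrix(-1 / (Z$R_ct * Z$C_dl), 1, 1),
       B = matrix(1 / Z$C_dl, 1, 1),
       C = matrix(1, 1, 1),
       D = matrix(series, 1, 1))
}

#' @export
state_space.function <- function(Z)
  stop_domain("transient simulation needs a rational impedance model, not a bare function")

## exact discrete step of x' = A x + B u for constant u over a step h:
## augmented matrix exponential [[A,B],[0,0]] gives Phi and Gamma together
discretize <- function(A, B, h) {
  n <- nrow(A)
  M <- rbind(cbind(A, B), matrix(0, 1, n + 1))
  E <- as.matrix(Matrix::expm(M * h))
  list(Phi = E[seq_len(n), seq_len(n), drop = FALSE],
       Gam = E[seq_len(n), n + 1])
}

#' Relay-feedback transient simulation of the oscillator
#'
#' Independent time-domain oracle for the harmonic-balance solver.  The
#' closed loop (comparator -> transconductance -> culture impedance ->
#' band-pass -> comparator) is piecewise linear: between comparator
#' switchings the state evolves as `x' = A x + B u` with constant
#' `u = +-Vsat`, so each step uses the exact matrix exponential; switching
#' instants (zero crossings of the band-pass output, which is the comparator
#' input) are located by cubic-Hermite root finding inside the step and the
#' state is re-advanced exactly to the crossing.  The equilibrium `x = 0` is
#' unstable but exactly invariant, so a small deterministic perturbation is
#' seeded unless `perturb = FALSE`.
#'
#' @inheritParams loop_transfer
#' @param duration optional hard time limit, seconds; default runs until
#'   steady state (plus `measure_cycles` cycles) or `max_cycles`.
#' @param steps_per_period recording steps per band-pass center period.
#' @param max_cycles safety cap on simulated oscillation cycles.
#' @param settle_rel relative cycle-amplitude change defining steady state.
#' @param settle_cycles consecutive settled cycles required.
#' @param measure_cycles extra cycles recorded after steady state.
#' @param perturb seed a small non-zero initial state (default TRUE).
#' @param x0 optional explicit initial state (length = number of loop states).
#' @return object of class `obt_waveform`: list with `time_s`,
#'   `v_out_volt`, `switch_times_s`, `cycle_amplitudes`, `steady` flag,
#'   `max_current_a` and a `message`.
#' @export
transient_simulate <- function(bp, bio, cmp, Z, duration = NULL,
                               steps_per_period = 200, max_cycles = 400,
                               settle_rel = 1e-3, settle_cycles = 5,
                               measure_cycles = 12, perturb = TRUE,
                               x0 = NULL) {
  kz <- resolve_kz(bio, cmp)
  ss <- state_space(Z)
  nz <- nrow(ss$A)
  w0 <- 2 * pi * bp$f0
  ## loop states: [x_z (nz), xb1, xb2]; input u = comparator output voltage
  n <- nz + 2L
  A <- matrix(0, n, n)
  if (nz > 0) {
    A[seq_len(nz), seq_len(nz)] <- ss$A
    A[n, seq_len(nz)] <- ss$C
  }
  A[nz + 1L, nz + 2L] <- 1
  A[n, nz + 1L] <- -w0^2
  A[n, n] <- -w0 / bp$Q
  B <- matrix(0, n, 1)
  if (nz > 0) B[seq_len(nz), 1] <- ss$B * kz * cmp$gain
  B[n, 1] <- ss$D[1, 1] * kz * cmp$gain
  Cv <- matrix(0, 1, n); Cv[1, n] <- bp$k * w0 / bp$Q
  ## comparator drive: u = sgn * Vsat * sign(v_out); with loop_sign = -1 the
  ## relay is non-inverting (harmonic balance then requires Arg(-L) = 0)
  sgn <- -cmp$loop_sign

  h <- 1 / (bp$f0 * steps_per_period)
  full <- discretize(A, B, h)

  x <- if (!is.null(x0)) {
    stopifnot(length(x0) == n); as.numeric(x0)
  } else if (perturb) {
    ## small deterministic band-pass kick to leave the unstable equilibrium;
    ## the relay then switches within the first ring-down period
    v <- numeric(n); v[nz + 2L] <- 1e-3 * cmp$Vsat / Cv[1, n]; v
  } else numeric(n)

  vout <- function(x) drop(Cv %*% x)
  dvout <- function(x, u) drop(Cv %*% (A %*% x + B * u))

  nmax <- if (is.null(duration)) 2e6 else max(10, ceiling(duration / h))
  t_rec <- numeric(4096); v_rec <- numeric(4096); nrec <- 0L
  push <- function(t, v) {
    if (nrec == length(t_rec)) {
      t_rec[2 * nrec] <<- 0; v_rec[2 * nrec] <<- 0  # grow
    }
    nrec <<- nrec + 1L; t_rec[nrec] <<- t; v_rec[nrec] <<- v
  }

  t <- 0; v <- vout(x)
  u <- sgn * cmp$Vsat * sign(if (v != 0) v else 1)
  if (all(x == 0)) {
    ## exact (unstable) equilibrium: the relay sees 0 and injects nothing,
    ## so the loop stays put — return a short flagged constant record
    ns <- 100L
    return(structure(list(time_s = h * seq_len(ns) - h,
                          v_out_volt = numeric(ns),
                          switch_times_s = numeric(0),
                          cycle_amplitudes = numeric(0), steady = FALSE,
                          max_current_a = 0, f0 = bp$f0,
                          message = "at equilibrium: zero initial state and no perturbation"),
                     class = "obt_waveform"))
  }
  push(t, v)

  switch_times <- numeric(0)
  cyc_amp <- numeric(0)
  cmax <- -Inf; cmin <- Inf
  steady <- FALSE; steady_at <- NA_integer_
  msg <- "ok"

  step <- 0L
  while (step < nmax) {
    step <- step + 1L
    x_new <- drop(full$Phi %*% x) + full$Gam * u
    v_new <- vout(x_new)
    if (u != 0 && v != 0 && sign(v_new) != sign(v) && v_new != 0) {
      ## locate the crossing with a cubic Hermite inside [t, t+h]
      d0 <- dvout(x, u); d1 <- dvout(x_new, u)
      herm <- function(s) {
        s2 <- s * s; s3 <- s2 * s
        (2 * s3 - 3 * s2 + 1) * v + (s3 - 2 * s2 + s) * h * d0 +
          (-2 * s3 + 3 * s2) * v_new + (s3 - s2) * h * d1
      }
      s_root <- tryCatch(uniroot(herm, c(0, 1), tol = 1e-14)$root,
                         error = function(e) 0.5)
      dt <- s_root * h
      part <- discretize(A, B, dt)
      x <- drop(part$Phi %*% x) + part$Gam * u
      t <- t + dt
      v <- vout(x)
      push(t, v)
      switch_times <- c(switch_times, t)
      ## full cycle = two switchings; track per-cycle amplitude
      cmax <- max(cmax, v); cmin <- min(cmin, v)
      if (length(switch_times) %% 2L == 0L) {
        cyc_amp <- c(cyc_amp, (cmax - cmin) / 2)
        cmax <- -Inf; cmin <- Inf
        nc <- length(cyc_amp)
        if (!steady && nc >= settle_cycles + 1L) {
          recent <- cyc_amp[(nc - settle_cycles):nc]
          if (max(recent) - min(recent) <= settle_rel * max(recent)) {
            steady <- TRUE; steady_at <- nc
          }
        }
        if (steady && nc >= steady_at + measure_cycles) break
        if (nc >= max_cycles) { msg <- "max_cycles reached before steady state"; break }
      }
      u <- sgn * cmp$Vsat * sign(if (v != 0) v else v_new)
      next
    }
    x <- x_new; t <- t + h; v <- v_new
    cmax <- max(cmax, v); cmin <- min(cmin, v)
    push(t, v)
    if (step > 50L * steps_per_period && length(switch_times) == 0L) {
      msg <- "no oscillation: output never crossed zero"; break
    }
  }
  if (!steady && msg == "ok")
    msg <- if (length(switch_times) < 6) "no steady oscillation within duration"
           else "stopped before steady-state criterion was met"

  structure(list(time_s = t_rec[seq_len(nrec)], v_out_volt = v_rec[seq_len(nrec)],
                 switch_times_s = switch_times, cycle_amplitudes = cyc_amp,
                 steady = steady,
                 max_current_a = kz * cmp$gain * cmp$Vsat,
                 f0 = bp$f0, message = msg),
            class = "obt_waveform")
}

#' @export
print.obt_waveform <- function(x, ...) {
  cat(sprintf("<obt_waveform> %d samples, %d switchings, steady = %s (%s)\n",
              length(x$time_s), length(x$switch_times_s), x$steady, x$message))
  invisible(x)
}

#' @export
as.data.frame.obt_waveform <- function(x, ...)
  data.frame(time_s = x$time_s, v_out_volt = x$v_out_volt)

#' Export / import a waveform as CSV
#'
#' @param wf an `obt_waveform` or data.frame with `time_s`, `v_out_volt`.
#' @param path CSV path.
#' @export
write_waveform <- function(wf, path) {
  df <- as.data.frame(wf)
  stopifnot(all(c("time_s", "v_out_volt") %in% names(df)))
  write.csv(df[c("time_s", "v_out_volt")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "v_out_volt") %in% names(df)))
    stop_domain("waveform file needs columns time_s, v_out_volt")
  df
}

#' Measure oscillation frequency and amplitude from a waveform
#'
#' Frequency is the reciprocal of the mean spacing of same-direction zero
#' crossings (linear interpolation between samples) over the last
#' `n_cycles` cycles.  Amplitude defaults to the first-harmonic (lock-in)
#' projection `a = (2/N) |sum (v - mean(v)) exp(-i 2 pi f t)|` over an
#' integer number of trailing cycles, which estimates the fundamental — the
#' quantity harmonic balance predicts — and is unbiased under additive
#' noise; `method = "peak"` returns the half peak-to-peak value instead.
#'
#' @param wf an `obt_waveform` or data.frame with `time_s`, `v_out_volt`.
#' @param n_cycles number of trailing cycles used.
#' @param method `"fundamental"` (default) or `"peak"`.
#' @return list with `f_osc` (Hz), `a_osc` (volts), `n_cycles_used`.
#' @export
measure_waveform <- function(wf, n_cycles = 10,
                             method = c("fundamental", "peak")) {
  method <- match.arg(method)
  df <- as.data.frame(wf)
  t <- df$time_s; v <- df$v_out_volt
  if (length(t) < 8) stop_domain("waveform too short to measure")
  vc <- v - mean(v)
  if (max(abs(vc)) < 1e-15 * max(1e-300, max(abs(v))) || all(vc == 0))
    stop_domain("constant signal: no oscillation to measure")
  ## upward zero crossings with a noise-calibrated hysteresis band so that
  ## sample-to-sample noise does not spray spurious crossings: a crossing is
  ## counted only once per excursion from below -tau to above +tau
  tau <- 3 * mad(diff(vc)) / sqrt(2) + 1e-12 * max(abs(vc))
  armed <- FALSE
  up <- integer(0)
  for (i in seq_along(vc)) {
    if (!armed && vc[i] < -tau) armed <- TRUE
    else if (armed && vc[i] > tau) {
      ## last sample at or below zero before this excursion
      j <- i
      while (j > 1L && vc[j] > 0) j <- j - 1L
      if (j >= 1L && j < length(vc)) up <- c(up, j)
      armed <- FALSE
    }
  }
  up <- unique(up[up >= 1L & up < length(vc)])
  if (length(up) < 4)
    stop_domain("fewer than 3 full cycles in the record")
  cross <- t[up] - vc[up] * (t[up + 1] - t[up]) / (vc[up + 1] - vc[up])
  ncyc <- min(n_cycles, length(cross) - 1L)
  cross <- tail(cross, ncyc + 1L)
  f <- ncyc / (cross[ncyc + 1L] - cross[1L])
  win <- t >= cross[1L] & t <= cross[ncyc + 1L]
  a <- if (method == "peak") {
    (max(v[win]) - min(v[win])) / 2
  } else {
    ph <- exp(-2i * pi * f * t[win])
    2 * Mod(mean((v[win] - mean(v[win])) * ph))
  }
  list(f_osc = f, a_osc = a, n_cycles_used = ncyc)
}
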