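#' Band-pass filter specification
#'
#' Second-order band-pass biquad
#' `H_BP(s) = k * (w0/Q) s / (s^2 + (w0/Q) s + w0^2)` with `w0 = 2*pi*f0`.
#' At the center frequency the gain is `k` and the phase is 0; the filter
#' selects the oscillation mode of the loop.
#'
#' @param f0 center frequency, Hz.
#' @param Q quality factor (dimensionless).
#' @param k passband gain (dimensionless).
#' @return object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(f0 = 1e4, Q = 5, k = 1) {
  check_positive(f0, "f0"); check_positive(Q, "Q"); check_positive(k, "k")
  structure(list(f0 = f0, Q = Q, k = k), class = "bandpass_spec")
}

#' Band-pass transfer function
#'
#' @param bp a [bandpass_spec()].
#' @param omega angular frequency, rad/s (vectorized).
#' @return complex gain.
#' @export
bandpass_tf <- function(bp, omega) {
  stopifnot(inherits(bp, "bandpass_spec"))
  w0 <- 2 * pi * bp$f0
  s <- 1i * omega
  bp$k * (w0 / bp$Q) * s / (s^2 + (w0 / bp$Q) * s + w0^2)
}

#' Comparator specification
#'
#' Ideal two-level comparator with output swing `+-Vsat`; its describing
#' function is `N(a) = 4*Vsat/(pi*a)` for input amplitude `a > 0`.
#' `loop_sign` fixes the feedback polarity of the loop (-1, negative
#' feedback, by default) and `gain` is the equivalent linear gain of any
#' extra comparator-path block (unity by default).
#'
#' @param Vsat output swing, volts.
#' @param loop_sign +1 or -1.
#' @param gain dimensionless comparator-path gain.
#' @return object of class `comparator_spec`.
#' @export
comparator_spec <- function(Vsat = 3.3, loop_sign = -1, gain = 1) {
  check_positive(Vsat, "Vsat"); check_positive(gain, "gain")
  if (!loop_sign %in% c(-1, 1)) stop_domain("'loop_sign' must be +1 or -1")
  structure(list(Vsat = Vsat, loop_sign = loop_sign, gain = gain),
            class = "comparator_spec")
}

#' Bioimpedance block specification
#'
#' The comparator output voltage is converted into the current injected into
#' the culture, `i = kz * v`; `kz` defaults to `current_limit / Vsat` so
#' that the injected current never exceeds the safety limit (10 uA by
#' default).  `kz * gain * Vsat <= current_limit` is enforced when the block
#' is resolved against a comparator.
#'
#' @param kz transconductance, A/V, or `NULL` to derive it from the limit.
#' @param current_limit maximum injected current, A.
#' @return object of class `bioimpedance_spec`.
#' @export
bioimpedance_spec <- function(kz = NULL, current_limit = 10e-6) {
  check_positive(current_limit, "current_limit")
  if (!is.null(kz)) check_positive(kz, "kz")
  structure(list(kz = kz, current_limit = current_limit),
            class = "bioimpedance_spec")
}

## resolve kz against the comparator swing and enforce the current limit
resolve_kz <- function(bio, cmp) {
  kz <- if (is.null(bio$kz)) bio$current_limit / (cmp$Vsat * cmp$gain)
        else bio$kz
  if (kz * cmp$Vsat * cmp$gain > bio$current_limit * (1 + 1e-12))
    stop_domain("kz * Vsat * gain = %.3g A exceeds the current limit %.3g A",
                kz * cmp$Vsat * cmp$gain, bio$current_limit)
  kz
}

#' Loop configuration bundle
#'
#' Bundles the band-pass, comparator, bioimpedance block, interface
#' parameters and electrode geometry that define one oscillator-plus-culture
#' setup.  `default_obt_config()` returns the package defaults (10 kHz, Q=5,
#' unity-gain band-pass; 3.3 V comparator; kz set by the 10 uA limit;
#' R_s=500, R_ct=1 MOhm, C_dl=4 nF, R_gap=1 kOhm).
#'
#' @param bandpass a [bandpass_spec()].
#' @param comparator a [comparator_spec()].
#' @param bioimpedance a [bioimpedance_spec()].
#' @param circuit an [interface_params()].
#' @param geometry an [electrode_geometry()].
#' @return object of class `obt_config`.
#' @export
obt_config <- function(bandpass = bandpass_spec(),
                       comparator = comparator_spec(),
                       bioimpedance = bioimpedance_spec(),
                       circuit = interface_params(),
                       geometry = electrode_geometry()) {
  stopifnot(inherits(bandpass, "bandpass_spec"),
            inherits(comparator, "comparator_spec"),
            inherits(bioimpedance, "bioimpedance_spec"),
            inherits(circuit, "interface_params"),
            inherits(geometry, "electrode_geometry"))
  resolve_kz(bioimpedance, comparator)  # validates the current limit
  structure(list(bandpass = bandpass, comparator = comparator,
                 bioimpedance = bioimpedance, circuit = circuit,
                 geometry = geometry),
            class = "obt_config")
}

#' @rdname obt_config
#' @export
default_obt_config <- function() obt_config()

#' Open-loop transfer of the oscillator
#'
#' `L(j*omega) = loop_sign * H_BP(j*omega) * kz * Z(j*omega) * gain`, the
#' product of the band-pass filter, the bioimpedance block (transconductance
#' times culture impedance) and the comparator-path gain.  The first-harmonic
#' oscillation condition is `1 + L(j*omega) * N(a) = 0`.
#'
#' @param bp a [bandpass_spec()].
#' @param bio a [bioimpedance_spec()].
#' @param cmp a [comparator_spec()].
#' @param Z impedance: circuit model, `function(omega)` or resistance.
#' @param omega angular frequency, rad/s (vectorized, > 0).
#' @return complex loop gain.
#' @export
loop_transfer <- function(bp, bio, cmp, Z, omega) {
  if (any(omega <= 0)) stop_domain("'omega' must be > 0 for loop_transfer")
  kz <- resolve_kz(bio, cmp)
  cmp$loop_sign * bandpass_tf(bp, omega) * kz * impedance(Z, omega) * cmp$gain
}

#' Solve the oscillation condition by first-harmonic balance
#'
#' Finds the limit cycle of the relay loop from
#' `1 + L(j*omega) * N(a) = 0` with `N(a) = 4*Vsat/(pi*a)`: the oscillation
#' frequency is where `L(j*omega)` is real and negative (phase crossing),
#' located by a sign scan of the loop phase on a log-spaced grid over
#' `f_range` followed by root refinement; the amplitude follows as
#' `a_osc = (4*Vsat/pi) * |L(j*2*pi*f_osc)|`.
#'
#' When several phase crossings exist, crossings with negative phase slope
#' (amplitude-stable limit cycles) are preferred and among them the one
#' closest to the band-pass center frequency is returned — the band-pass is
#' there precisely to select that mode.  If no crossing exists the
#' configuration does not oscillate and `converged = FALSE` is returned with
#' a diagnostic message (no error).
#'
#' @inheritParams loop_transfer
#' @param f_range search band in Hz, default `c(f0/20, 20*f0)`.
#' @param n_grid number of scan points (log-spaced).
#' @param tol phase residual tolerance, radians.
#' @return object of class `oscillation_solution`: list with `f_osc` (Hz),
#'   `a_osc` (volts), `converged`, `phase_residual` (radians), `message`.
#' @examples
#' sol <- solve_oscillation(bandpass_spec(), bioimpedance_spec(),
#'                          comparator_spec(), Z = 1000)
#' sol$f_osc  # = f0 for a resistive load
#' @export
solve_oscillation <- function(bp, bio, cmp, Z,
                              f_range = c(bp$f0 / 20, 20 * bp$f0),
                              n_grid = 400, tol = 1e-9) {
  kz <- resolve_kz(bio, cmp)
  ## G = -L; the oscillation condition is Arg(G) = 0 with |G| finite
  Gfun <- function(omega)
    -cmp$loop_sign * bandpass_tf(bp, omega) * kz * impedance(Z, omega) * cmp$gain
  phase <- function(f) Arg(Gfun(2 * pi * f))

  fgrid <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_grid))
  ph <- phase(fgrid)
  ## sign changes of the phase that are genuine zero crossings (exclude the
  ## +pi/-pi wrap of the negative real axis)
  cand <- which(ph[-1] * ph[-n_grid] < 0 &
                  abs(ph[-1]) + abs(ph[-n_grid]) < pi)
  if (!length(cand))
    return(structure(list(f_osc = NA_real_, a_osc = NA_real_,
                          converged = FALSE, phase_residual = NA_real_,
                          message = "no phase crossing in the search band: configuration does not oscillate"),
                     class = "oscillation_solution"))

  roots <- vapply(cand, function(i)
    uniroot(phase, c(fgrid[i], fgrid[i + 1]), tol = .Machine$double.eps^0.75)$root,
    numeric(1))
  slope_neg <- ph[cand + 1] < ph[cand]
  pick <- if (any(slope_neg)) which(slope_neg) else seq_along(roots)
  f_osc <- roots[pick][which.min(abs(log(roots[pick] / bp$f0)))]

  G <- Gfun(2 * pi * f_osc)
  residual <- abs(Arg(G))
  a_osc <- 4 * cmp$Vsat / pi * Mod(G)
  structure(list(f_osc = f_osc, a_osc = a_osc,
                 converged = residual < tol, phase_residual = residual,
                 message = if (residual < tol) "ok" else
                   sprintf("phase residual %.3g rad above tolerance", residual)),
            class = "oscillation_solution")
}

#' @export
print.oscillation_solution <- function(x, ...) {
  if (isTRUE(x$converged))
    cat(sprintf("<oscillation_solution> f_osc = %.6g Hz, a_osc = %.6g V\n",
                x$f_osc, x$a_osc))
  else
    cat(sprintf("<oscillation_solution> not converged: %s\n", x$message))
  invisible(x)
}

#' Predict the oscillation for a culture at a given fill factor
#'
#' Convenience wrapper: builds the covered-electrode model at fill factor
#' `ff` from the configured interface parameters and solves the oscillation
#' condition.
#'
#' @param config an [obt_config()].
#' @param ff fill factor in `[0, 1]`.
#' @param ... passed to [solve_oscillation()].
#' @return an `oscillation_solution`.
#' @export
predict_oscillation <- function(config, ff, ...) {
  stopifnot(inherits(config, "obt_config"))
  model <- cell_electrode_model(config$circuit, ff)
  solve_oscillation(config$bandpass, config$bioimpedance, config$comparator,
                    model, ...)
}
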