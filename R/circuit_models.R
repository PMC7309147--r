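#' Electrode-electrolyte interface parameters
#'
#' Lumped primitives of the sensing interface: the solution / reference-path
#' resistance `R_s`, the charge-transfer resistance `R_ct` and double-layer
#' capacitance `C_dl` of the fully bare sensing electrode (a parallel RC,
#' Randles-type interface without Warburg element), and the gap resistance
#' `R_gap` of the thin electrolyte cleft between an adherent cell layer and
#' the electrode surface.
#'
#' `R_s_ff_slope` is an optional hook for a fill-factor-dependent solution
#' resistance, `R_s_eff(ff) = R_s + R_s_ff_slope * ff`; the default slope of
#' 0 keeps `R_s` coverage-independent (the direction of the dependence is
#' known, its functional form is not, so it is exposed but not modeled).
#'
#' @param R_s solution resistance, Ohm.
#' @param R_ct charge-transfer resistance of the bare electrode, Ohm.
#' @param C_dl double-layer capacitance of the bare electrode, Farad.
#' @param R_gap cell-electrode gap resistance, Ohm.
#' @param R_s_ff_slope Ohm per unit fill factor, default 0.
#' @return object of class `interface_params`.
#' @examples
#' interface_params()  # package defaults: 500, 1e6, 50e-9, 1000
#' @export
interface_params <- function(R_s = 500, R_ct = 1e6, C_dl = 50e-9,
                             R_gap = 1000, R_s_ff_slope = 0) {
  check_positive(R_s, "R_s"); check_positive(R_ct, "R_ct")
  check_positive(C_dl, "C_dl"); check_positive(R_gap, "R_gap")
  if (!is.numeric(R_s_ff_slope) || length(R_s_ff_slope) != 1L ||
      !is.finite(R_s_ff_slope) || R_s_ff_slope < 0)
    stop_domain("'R_s_ff_slope' must be finite and >= 0")
  structure(list(R_s = R_s, R_ct = R_ct, C_dl = C_dl, R_gap = R_gap,
                 R_s_ff_slope = R_s_ff_slope),
            class = "interface_params")
}

#' @export
print.interface_params <- function(x, ...) {
  cat(sprintf("<interface_params> R_s=%g Ohm, R_ct=%g Ohm, C_dl=%g F, R_gap=%g Ohm\n",
              x$R_s, x$R_ct, x$C_dl, x$R_gap))
  invisible(x)
}

#' Bare-electrode impedance (parallel R_ct || C_dl)
#'
#' Faradaic interface of the uncovered electrode:
#' `Z(omega) = R_ct / (1 + j*omega*R_ct*C_dl)`.  At `omega = 0` this is
#' exactly `R_ct`; at high frequency the double layer shorts the interface.
#'
#' @param params an [interface_params()] object.
#' @param omega angular frequency, rad/s (vectorized, must be >= 0).
#' @return complex impedance, Ohm.
#' @export
bare_electrode_impedance <- function(params, omega) {
  stopifnot(inherits(params, "interface_params"))
  check_omega(omega)
  params$R_ct / (1 + 1i * omega * params$R_ct * params$C_dl)
}

#' Fill-factor-split cell-electrode model
#'
#' Two-branch model of a partially covered electrode.  A fraction `ff` of
#' the sensing area is covered by cells; the interface splits proportionally
#' into an uncovered branch `R_1 || C_1` with `R_1 = R_ct/(1-ff)`,
#' `C_1 = C_dl*(1-ff)`, and a covered branch `R_2 || C_2` with
#' `R_2 = R_ct/ff`, `C_2 = C_dl*ff`, reached through the gap resistance
#' `R_gap` of the cell-electrode cleft.  Both branch time constants equal
#' `R_ct*C_dl` for every `ff` in (0,1).  As `ff` grows, `R_1` and `C_2`
#' increase while `C_1` and `R_2` decrease.  The limits `ff = 0` and
#' `ff = 1` are represented explicitly (open covered / open uncovered
#' branch), never by division by zero.
#'
#' @param params an [interface_params()] object.
#' @param ff fill factor in `[0, 1]`.
#' @return object of class `cell_electrode_model`.
#' @examples
#' m <- cell_electrode_model(interface_params(), ff = 0.5)
#' m$R_1 * m$C_1 == m$R_2 * m$C_2
#' @export
cell_electrode_model <- function(params, ff) {
  stopifnot(inherits(params, "interface_params"))
  if (!is.numeric(ff) || length(ff) != 1L || is.na(ff) || ff < 0 || ff > 1)
    stop_domain("'ff' must be a single number in [0, 1] (got %s)", format(ff))
  with(params, {
    if (ff == 0) {
      R_1 <- R_ct; C_1 <- C_dl; R_2 <- Inf; C_2 <- 0
    } else if (ff == 1) {
      R_1 <- Inf; C_1 <- 0; R_2 <- R_ct; C_2 <- C_dl
    } else {
      R_1 <- R_ct / (1 - ff); C_1 <- C_dl * (1 - ff)
      R_2 <- R_ct / ff;       C_2 <- C_dl * ff
    }
    structure(list(params = params, ff = ff,
                   R_1 = R_1, C_1 = C_1, R_2 = R_2, C_2 = C_2,
                   R_s_eff = R_s + R_s_ff_slope * ff),
              class = "cell_electrode_model")
  })
}

#' @export
print.cell_electrode_model <- function(x, ...) {
  cat(sprintf("<cell_electrode_model> ff=%.3f (R_1=%g, C_1=%g, R_2=%g, C_2=%g)\n",
              x$ff, x$R_1, x$C_1, x$R_2, x$C_2))
  invisible(x)
}

#' Impedance of the partially covered electrode
#'
#' `Z(omega) = R_s_eff + Z_1 || (R_gap + Z_2)` with `Z_1 = R_1 || C_1`
#' (uncovered branch) and `Z_2 = R_2 || C_2` (covered branch; the gap
#' resistance sits between the cell layer and the electrode, in series with
#' the covered branch only).  At `ff = 0` this reduces exactly to
#' `R_s + bare_electrode_impedance()`; at `ff = 1` to
#' `R_s + R_gap + bare_electrode_impedance()`.
#'
#' @param model a [cell_electrode_model()].
#' @param omega angular frequency, rad/s (vectorized, >= 0).
#' @return complex impedance, Ohm.
#' @export
cell_electrode_impedance <- function(model, omega) {
  stopifnot(inherits(model, "cell_electrode_model"))
  check_omega(omega)
  p <- model$params
  bare <- p$R_ct / (1 + 1i * omega * p$R_ct * p$C_dl)
  if (model$ff == 0) return(model$R_s_eff + bare)
  if (model$ff == 1) return(model$R_s_eff + p$R_gap + bare)
  Z1 <- model$R_1 / (1 + 1i * omega * model$R_1 * model$C_1)
  Z2 <- model$R_2 / (1 + 1i * omega * model$R_2 * model$C_2)
  Zb <- p$R_gap + Z2
  model$R_s_eff + Z1 * Zb / (Z1 + Zb)
}

#' Differentiated-tissue model
#'
#' Once the culture has differentiated into a confluent tissue, the gap
#' resistance is replaced by two series resistances: `R_bulk` (electrolyte
#' between microelectrode and tissue) and `R_tissue` (the tissue itself);
#' the electrode area under the tissue keeps its faradaic interface
#' `R_ct || C_dl`.
#'
#' @param R_bulk electrode-to-tissue bulk resistance, Ohm.
#' @param R_tissue tissue resistance, Ohm.
#' @param R_ct charge-transfer resistance, Ohm.
#' @param C_dl double-layer capacitance, Farad.
#' @param R_s solution resistance, Ohm (used when `include_R_s`).
#' @param include_R_s logical; add `R_s` in series (off by default so the
#'   model matches the tissue branch alone).
#' @return object of class `tissue_model`.
#' @export
tissue_model <- function(R_bulk, R_tissue, R_ct = 1e6, C_dl = 50e-9,
                         R_s = 500, include_R_s = FALSE) {
  check_positive(R_bulk, "R_bulk"); check_positive(R_tissue, "R_tissue")
  check_positive(R_ct, "R_ct"); check_positive(C_dl, "C_dl")
  check_positive(R_s, "R_s")
  stopifnot(is.logical(include_R_s), length(include_R_s) == 1L)
  structure(list(R_bulk = R_bulk, R_tissue = R_tissue, R_ct = R_ct,
                 C_dl = C_dl, R_s = R_s, include_R_s = include_R_s),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model> R_bulk=%g, R_tissue=%g, R_ct=%g, C_dl=%g%s\n",
              x$R_bulk, x$R_tissue, x$R_ct, x$C_dl,
              if (x$include_R_s) sprintf(", R_s=%g", x$R_s) else ""))
  invisible(x)
}

#' Impedance of the differentiated-tissue model
#'
#' `Z(omega) = (R_s) + R_bulk + R_tissue + R_ct/(1 + j*omega*R_ct*C_dl)`.
#'
#' @param model a [tissue_model()].
#' @param omega angular frequency, rad/s (vectorized, >= 0).
#' @return complex impedance, Ohm.
#' @export
tissue_impedance <- function(model, omega) {
  stopifnot(inherits(model, "tissue_model"))
  check_omega(omega)
  series <- model$R_bulk + model$R_tissue +
    if (model$include_R_s) model$R_s else 0
  series + model$R_ct / (1 + 1i * omega * model$R_ct * model$C_dl)
}

#' Generic impedance evaluation
#'
#' Dispatches to the model-specific impedance; plain functions of omega and
#' single resistances are accepted wherever the oscillator engine expects an
#' impedance.
#'
#' @param Z a circuit model, a `function(omega)` returning complex Ohm, or a
#'   single resistance in Ohm.
#' @param omega angular frequency, rad/s.
#' @return complex impedance, Ohm.
#' @export
impedance <- function(Z, omega) UseMethod("impedance")

#' @export
impedance.cell_electrode_model <- function(Z, omega)
  cell_electrode_impedance(Z, omega)

#' @export
impedance.tissue_model <- function(Z, omega) tissue_impedance(Z, omega)

#' @export
impedance.function <- function(Z, omega) Z(omega)

#' @export
impedance.numeric <- function(Z, omega) {
  check_positive(Z, "Z (resistance)")
  rep(complex(real = Z, imaginary = 0), length(omega))
}

#' Cross-check the covered-electrode and tissue models at full coverage
#'
#' At `ff = 1` the covered-electrode impedance is
#' `R_s + R_gap + R_ct||C_dl`; the tissue model with
#' `R_bulk + R_tissue = R_gap`, the same interface parameters and `R_s`
#' included is algebraically identical.  The check evaluates both spectra on
#' a frequency grid and reports the residual; parameter mismatches are
#' reported in the result, never raised as an error.
#'
#' @param cell_model a [cell_electrode_model()] at `ff = 1`.
#' @param tiss a [tissue_model()].
#' @param freq_hz frequency grid, Hz.
#' @return list with `freq_hz`, `residual_ohm` (|Z_cell - Z_tissue|),
#'   `max_residual_ohm` and a character vector `mismatches` naming parameters
#'   that differ between the two models.
#' @export
consistency_check <- function(cell_model, tiss,
                              freq_hz = 10^seq(1, 6, length.out = 61)) {
  stopifnot(inherits(cell_model, "cell_electrode_model"),
            inherits(tiss, "tissue_model"))
  if (cell_model$ff != 1)
    stop_domain("consistency_check requires the cell model at ff = 1")
  omega <- 2 * pi * freq_hz
  zc <- cell_electrode_impedance(cell_model, omega)
  zt <- tissue_impedance(tiss, omega)
  if (!tiss$include_R_s) zt <- zt + cell_model$R_s_eff
  p <- cell_model$params
  mism <- character()
  if (p$R_ct != tiss$R_ct) mism <- c(mism, "R_ct")
  if (p$C_dl != tiss$C_dl) mism <- c(mism, "C_dl")
  if (tiss$include_R_s && cell_model$R_s_eff != tiss$R_s)
    mism <- c(mism, "R_s")
  if (abs(p$R_gap - (tiss$R_bulk + tiss$R_tissue)) > 1e-9 * p$R_gap)
    mism <- c(mism, "R_gap != R_bulk + R_tissue")
  res <- Mod(zc - zt)
  structure(list(freq_hz = freq_hz, residual_ohm = res,
                 max_residual_ohm = max(res), mismatches = mism),
            class = "consistency_check")
}

#' @export
print.consistency_check <- function(x, ...) {
  cat(sprintf("<consistency_check> max residual %.3g Ohm over %d frequencies%s\n",
              x$max_residual_ohm, length(x$freq_hz),
              if (length(x$mismatches))
                paste0("; mismatches: ", paste(x$mismatches, collapse = ", "))
              else ""))
  invisible(x)
}

#' Tabulate and export impedance spectra
#'
#' @param Z impedance (model, function or resistance), see [impedance()].
#' @param freq_hz frequency grid, Hz.
#' @return data.frame with columns `freq_hz`, `z_real_ohm`, `z_imag_ohm`.
#' @export
impedance_spectrum <- function(Z, freq_hz = 10^seq(1, 6, length.out = 61)) {
  z <- impedance(Z, 2 * pi * freq_hz)
  data.frame(freq_hz = freq_hz, z_real_ohm = Re(z), z_imag_ohm = Im(z))
}

#' @param spectrum data.frame as returned by [impedance_spectrum()].
#' @param path CSV file path.
#' @rdname impedance_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(all(c("freq_hz", "z_real_ohm", "z_imag_ohm") %in% names(spectrum)))
  write.csv(spectrum, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname impedance_spectrum
#' @export
read_spectrum <- function(path) {
  df <- read.csv(path)
  need <- c("freq_hz", "z_real_ohm", "z_imag_ohm")
  if (!all(need %in% names(df)))
    stop_domain("spectrum file misses columns: %s",
                paste(setdiff(need, names(df)), collapse = ", "))
  df[need]
}
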