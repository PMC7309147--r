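#' Electrode array geometry
#'
#' Geometry of one well of the culture-ware: `n_electrodes` circular gold
#' sensing microelectrodes of diameter `electrode_diameter_um` (micrometres)
#' sit in a well of area `well_area_cm2` (cm^2), next to a large reference
#' electrode.  Defaults describe one well of the commercial 8-well array used
#' throughout the package: ten 250-um electrodes in a 0.8 cm^2 well.
#'
#' @param n_electrodes integer >= 1, number of sensing electrodes.
#' @param electrode_diameter_um electrode diameter, micrometres.
#' @param well_area_cm2 culture-well area, cm^2.
#' @return an object of class `electrode_geometry` with the derived
#'   `sensing_area_cm2` (sum of the electrode disc areas, always smaller than
#'   the well area).
#' @examples
#' g <- electrode_geometry()
#' g$sensing_area_cm2  # ~4.9e-3 cm^2
#' @export
electrode_geometry <- function(n_electrodes = 10,
                               electrode_diameter_um = 250,
                               well_area_cm2 = 0.8) {
  if (!is.numeric(n_electrodes) || length(n_electrodes) != 1L ||
      is.na(n_electrodes) || n_electrodes < 1 ||
      n_electrodes != round(n_electrodes))
    stop_domain("'n_electrodes' must be an integer >= 1")
  check_positive(electrode_diameter_um, "electrode_diameter_um")
  check_positive(well_area_cm2, "well_area_cm2")

  sensing_um2 <- n_electrodes * pi * (electrode_diameter_um / 2)^2
  sensing_cm2 <- um2_to_cm2(sensing_um2)
  if (sensing_cm2 >= well_area_cm2)
    stop_domain("sensing area (%.4g cm^2) must be smaller than the well area (%.4g cm^2)",
                sensing_cm2, well_area_cm2)

  structure(list(n_electrodes = as.integer(n_electrodes),
                 electrode_diameter_um = electrode_diameter_um,
                 well_area_cm2 = well_area_cm2,
                 sensing_area_cm2 = sensing_cm2),
            class = "electrode_geometry")
}

#' @export
print.electrode_geometry <- function(x, ...) {
  cat(sprintf("<electrode_geometry> %d x %.0f um discs, well %.3g cm^2, sensing %.3g cm^2\n",
              x$n_electrodes, x$electrode_diameter_um, x$well_area_cm2,
              x$sensing_area_cm2))
  invisible(x)
}
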