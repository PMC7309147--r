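## Centralized unit conversions.  Areas are handled internally in um^2;
## well/electrode areas are user-facing in cm^2 (1 cm^2 = 1e8 um^2).

UM2_PER_CM2 <- 1e8

#' Area unit conversions
#'
#' The fill-factor arithmetic mixes um-scale single-cell areas with cm-scale
#' well areas; every conversion in the package goes through these two
#' helpers.
#'
#' @param x numeric vector of areas.
#' @return numeric vector of converted areas.
#' @examples
#' cm2_to_um2(0.8)  # 8e7 um^2
#' @export
cm2_to_um2 <- function(x) x * UM2_PER_CM2

#' @rdname cm2_to_um2
#' @export
um2_to_cm2 <- function(x) x / UM2_PER_CM2

## internal validators -------------------------------------------------------

stop_domain <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 ||
      (finite && !is.finite(x)))
    stop_domain("'%s' must be a single positive finite number (got %s)",
                name, paste(format(x), collapse = ", "))
  invisible(x)
}

check_omega <- function(omega) {
  if (!is.numeric(omega) || any(!is.finite(omega)) || any(omega < 0))
    stop_domain("'omega' must be finite and >= 0 rad/s")
  invisible(omega)
}
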