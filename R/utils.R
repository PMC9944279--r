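# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a configuration error
#'
#' All user-facing parameter validation funnels through here so that tests
#' can target a single condition class.
#' @noRd
abort_config <- function(msg, ...) {
  rlang::abort(message = paste0(msg, ...), class = "aggsink_config_error")
}

# Validate that `x` is a single finite number satisfying `ok`.
check_number <- function(x, name, ok = function(v) TRUE, what = "") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !ok(x)) {
    abort_config(sprintf("`%s` must be a single finite number%s", name,
                         if (nzchar(what)) paste0(" (", what, ")") else ""))
  }
  invisible(x)
}

# Fan a single pipeline seed out to per-stage child seeds. Offsets are keyed
# by stage name so adding a new stage never shifts existing streams; results
# stay below .Machine$integer.max.
child_seed <- function(seed, ...) {
  labels <- c(...)
  s <- as.double(seed) %% 2147483647
  for (lab in labels) {
    s <- (s * 31 + sum(utf8ToInt(as.character(lab)))) %% 2147483647
  }
  as.integer(s)
}

#' Volume of an upright cylinder in litres
#'
#' Convenience for roller-tank geometry: the rotating cylinders used to form
#' aggregates (radius 8.5 cm, height 10 cm) hold pi * 8.5^2 * 10 cm^3 = 2.3 L.
#'
#' @param radius_cm cylinder radius in cm.
#' @param height_cm cylinder height in cm.
#' @return volume in litres.
#' @examples
#' cylinder_volume_L(8.5, 10) # ~2.3 L
#' @export
cylinder_volume_L <- function(radius_cm, height_cm) {
  check_number(radius_cm, "radius_cm", function(v) v > 0, "> 0")
  check_number(height_cm, "height_cm", function(v) v > 0, "> 0")
  pi * radius_cm^2 * height_cm / 1000
}

#' Fraction of a tank volume covered by imaging
#'
#' @param imaged_L volume covered by the image sequences, in litres.
#' @param total_L total tank volume, in litres.
#' @return fraction in \[0, 1\].
#' @examples
#' imaged_volume_fraction(2 * 0.35, cylinder_volume_L(8.5, 10)) # ~0.30
#' @export
imaged_volume_fraction <- function(imaged_L, total_L) {
  check_number(imaged_L, "imaged_L", function(v) v >= 0)
  check_number(total_L, "total_L", function(v) v > 0, "> 0")
  imaged_L / total_L
}

#' log10 with an empty-bin sentinel
#'
#' Spectrum plots use log10 axes; empty size bins (value 0) are drawn at the
#' sentinel value -1.0 rather than -Inf so they stay on the axis.
#'
#' @param x non-negative numeric vector.
#' @param sentinel value substituted for `log10(0)`; default -1.0.
#' @return `log10(x)` with zeros mapped to `sentinel`.
#' @examples
#' log10_with_sentinel(c(100, 1, 0))
#' @export
log10_with_sentinel <- function(x, sentinel = -1.0) {
  if (any(x < 0, na.rm = TRUE)) {
    abort_config("`x` must be non-negative for log10 transformation")
  }
  out <- log10(x)
  out[x == 0] <- sentinel
  out
}
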