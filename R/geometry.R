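#' Volume-equivalent sphere diameter
#'
#' Converts a nodule volume in cubic millimetres to the diameter of the
#' sphere with the same volume, `d = (6 V / pi)^(1/3)`. This is the standard
#' volumetry convention used to apply size gates (e.g. the 3-30 mm inclusion
#' window) to semi-automatically segmented nodules.
#'
#' @param volume Numeric vector of volumes in mm^3; all values must be > 0.
#' @return Numeric vector of equivalent diameters in mm.
#' @seealso [volume_from_diameter()] for the inverse.
#' @examples
#' equivalent_diameter(pi / 6 * 5^3) # 5 mm sphere
#' @export
equivalent_diameter <- function(volume) {
  if (!is.numeric(volume) || any(!is.finite(volume)) || any(volume <= 0)) {
    stop("`volume` must be finite and > 0 (in mm^3)", call. = FALSE)
  }
  (6 * volume / pi)^(1 / 3)
}

#' Sphere volume from equivalent diameter
#'
#' Inverse of [equivalent_diameter()]: `V = pi/6 d^3`.
#'
#' @param diameter Numeric vector of diameters in mm; all values must be > 0.
#' @return Numeric vector of volumes in mm^3.
#' @export
volume_from_diameter <- function(diameter) {
  if (!is.numeric(diameter) || any(!is.finite(diameter)) || any(diameter <= 0)) {
    stop("`diameter` must be finite and > 0 (in mm)", call. = FALSE)
  }
  pi / 6 * diameter^3
}

# Euclidean distances between one point and a matrix of points (n x 3), mm.
dist_to_points <- function(p, xyz) {
  if (NROW(xyz) == 0L) return(numeric(0))
  sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2)
}

# Round half away from zero to `digits` decimals (table formatting
# convention; base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Format a fraction in [0,1] as a percentage rounded half-up to 1 decimal.
as_percent <- function(x, digits = 1) round_half_up(100 * x, digits)
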