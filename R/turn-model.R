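#' Wrap angles into (-180, 180]
#'
#' @param deg Numeric vector of angles in degrees.
#' @return Angles wrapped into the half-open interval (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(0, 180, -180, 270, 725))
wrap_angle <- function(deg) {
  w <- deg - 360 * floor((deg + 180) / 360)
  # floor() maps +180 to -180; the convention here keeps +180
  w[w == -180] <- 180
  w
}

#' Draw turn angles for a correlated random walker
#'
#' Turns between consecutive path segments are drawn from a zero-centred
#' Gaussian ("straight ahead" on average) whose spread is the circular
#' standard deviation (c.s.d.) in degrees, then wrapped into (-180, 180].
#' For the c.s.d. range of interest here (up to ~80 degrees) wrapping is a
#' negligible correction; it only guards against >180-degree artifacts.
#'
#' @param csd_deg Circular standard deviation of the turn-angle
#'   distribution, degrees, >= 0. Zero gives a perfectly straight walker.
#' @param n Number of draws.
#' @return Numeric vector of `n` turn angles in degrees, in (-180, 180].
#' @export
#' @examples
#' set.seed(1)
#' sd(draw_turn_angles(30, 1e4))
draw_turn_angles <- function(csd_deg, n) {
  stopifnot(is.numeric(csd_deg), length(csd_deg) == 1, is.finite(csd_deg))
  if (csd_deg < 0) stop("`csd_deg` must be >= 0", call. = FALSE)
  stopifnot(n >= 0)
  if (n == 0) return(numeric(0))
  wrap_angle(stats::rnorm(n, mean = 0, sd = csd_deg))
}
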