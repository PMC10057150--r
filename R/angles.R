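#' Circular helpers for torsion angles
#'
#' Torsion angles live on the circle; these helpers implement the wrapping,
#' distance and mean conventions used across the package. Angles are in
#' degrees and reported in the half-open interval (-180, 180].
#'
#' @param x,a,b numeric vectors of angles in degrees.
#' @return `wrap_angle()` returns angles wrapped to (-180, 180];
#'   `circular_distance()` the absolute wrapped separation in \[0, 180\];
#'   `circular_mean()` the direction of the mean resultant vector, itself
#'   wrapped to (-180, 180].
#' @examples
#' wrap_angle(190)            # -170
#' circular_distance(179, -179)  # 2
#' circular_mean(c(175, -175))   # 180
#' @name circular
NULL

#' @rdname circular
#' @export
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  # land exactly on +180 rather than -180
  w[w == -180] <- 180
  w
}

#' @rdname circular
#' @export
circular_distance <- function(a, b) {
  d <- abs(wrap_angle(a - b))
  d
}

#' @rdname circular
#' @export
circular_mean <- function(x) {
  if (length(x) == 0L) {
    abort("cannot take the circular mean of zero angles", class = "boronfit_empty_input")
  }
  s <- mean(sin(x * .DEG))
  c <- mean(cos(x * .DEG))
  wrap_angle(atan2(s, c) / .DEG)
}
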