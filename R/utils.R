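# Small angle utilities shared across modules.

#' Unwrap a sequence of angles
#'
#' Adds multiples of \eqn{2\pi} so that consecutive differences lie in
#' \eqn{(-\pi, \pi]}. Used both along the body (head-to-tail unwrapping of
#' tangent-angle profiles, removing branch artifacts in coiled shapes) and
#' along time (orientation and body-wave phase trajectories).
#'
#' @param x numeric vector of angles, radians.
#' @return numeric vector of the same length.
#' @export
unwrapAngles <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  x + c(0, cumsum(-round(d / (2 * pi)))) * 2 * pi
}

#' Wrap an angle to [0, 2*pi)
#' @param x numeric vector, radians.
#' @export
wrapAngle <- function(x) x %% (2 * pi)

# smallest absolute angular difference on the circle
circDist <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# validate a tangent-angle profile (100 finite angles)
checkProfile <- function(angles, meanSubtracted = FALSE) {
  if (length(angles) != 100L || !all(is.finite(angles)))
    stop("a tangent-angle profile must contain exactly 100 finite values")
  if (meanSubtracted && abs(mean(angles)) > 1e-9)
    stop("profile is not mean-subtracted (|mean| > 1e-9)")
  invisible(angles)
}

# validate a posture coordinate vector (a1..a5, theta)
checkCoords <- function(p) {
  if (length(p) != 6L || !all(is.finite(p)))
    stop("posture coordinates must be 6 finite values (a1..a5, theta)")
  invisible(p)
}
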