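#' @import methods
NULL

#' Eigenworm basis
#'
#' An orthonormal basis of postural eigenmodes ("eigenworms"): principal
#' directions of the tangent-angle shape covariance of a worm-posture
#' ensemble. Rows of \code{vectors} are the unit eigenworms \eqn{\hat e_i}
#' (100 entries at equidistant arc-length points, head first); any body shape
#' is approximated as \eqn{\theta(s) \approx \langle\theta\rangle + \sum_i
#' a_i \hat e_i(s)}.
#'
#' @slot vectors numeric matrix, K x 100; rows are orthonormal eigenworms.
#' @slot variances numeric, K non-negative eigenvalues of the shape
#'   covariance, non-increasing.
#' @export
setClass("EigenwormBasis",
  representation(vectors = "matrix", variances = "numeric"))

setValidity("EigenwormBasis", function(object) {
  v <- object@vectors
  if (!is.numeric(v) || ncol(v) != 100L)
    return("vectors must be a numeric K x 100 matrix")
  if (!all(is.finite(v))) return("vectors must be finite")
  if (length(object@variances) != nrow(v))
    return("one variance per basis vector required")
  if (any(object@variances < 0)) return("variances must be non-negative")
  if (is.unsorted(rev(object@variances), strictly = FALSE))
    return("variances must be sorted non-increasing")
  g <- v %*% t(v)
  if (max(abs(g - diag(nrow(v)))) > 1e-8)
    return("basis rows are not orthonormal (tolerance 1e-8)")
  TRUE
})

#' Worm body model
#'
#' Arc length and local half-thickness of a worm, in pixels: the geometry
#' needed to render a binary worm image from a backbone. \code{radii[j]} is
#' the radius of the filled disc drawn at backbone point \code{j}; the body
#' tapers toward head and tail.
#'
#' @slot arcLength numeric(1), total backbone length in px.
#' @slot radii numeric(100), positive disc radii in px.
#' @export
setClass("WormBodyModel",
  representation(arcLength = "numeric", radii = "numeric"))

setValidity("WormBodyModel", function(object) {
  r <- object@radii
  if (length(r) != 100L || any(!is.finite(r)) || any(r <= 0))
    return("radii must be 100 positive finite values")
  n <- length(r)
  if (r[1] != min(r[seq_len(n %/% 2)]) || r[n] != min(r[(n %/% 2 + 1):n]))
    return("body must taper: r[1] and r[100] must be the minima of their halves")
  if (length(object@arcLength) != 1L || !is.finite(object@arcLength))
    return("arcLength must be a single finite number")
  if (object@arcLength <= 2 * max(r))
    return("arcLength must exceed twice the maximum radius")
  TRUE
})

#' Mode trajectory
#'
#' A time-ordered trajectory through posture space: per-frame eigenmode
#' amplitudes a1..a5 and the overall orientation \eqn{\langle\theta\rangle}
#' (unwrapped along the trajectory), on a uniform time base.
#'
#' @slot frameRate numeric(1), Hz.
#' @slot modes numeric matrix, N x 5, columns a1..a5.
#' @slot orientation numeric(N), radians, unwrapped.
#' @slot provenance character, per-frame origin ("thinning", "inverse",
#'   "interpolated", "synthetic"), or length 0 when untracked.
#' @export
setClass("ModeTrajectory",
  representation(frameRate = "numeric", modes = "matrix",
                 orientation = "numeric", provenance = "character"))

setValidity("ModeTrajectory", function(object) {
  m <- object@modes
  if (ncol(m) != 5L) return("modes must have 5 columns (a1..a5)")
  if (!all(is.finite(m))) return("modes must be finite")
  if (length(object@orientation) != nrow(m))
    return("orientation must have one entry per frame")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    return("frameRate must be a single positive number")
  if (length(object@provenance) > 0 &&
      length(object@provenance) != nrow(m))
    return("provenance must be empty or one entry per frame")
  TRUE
})

#' Per-frame candidate solution set
#'
#' The candidate postures retained by the inverse search for one movie frame:
#' zero, one, or several local minima of the image error, each a point
#' (a1..a5, orientation) with its error value. Candidates are pairwise
#' separated by more than the merge box.
#'
#' @slot frame integer(1), frame index.
#' @slot coords numeric matrix, M x 6 (a1..a5, theta; theta wrapped to
#'   [0, 2pi)).
#' @slot errors numeric(M), image error of each candidate.
#' @export
setClass("FrameSolutionSet",
  representation(frame = "integer", coords = "matrix", errors = "numeric"))

setValidity("FrameSolutionSet", function(object) {
  if (nrow(object@coords) != length(object@errors))
    return("one error per candidate required")
  if (nrow(object@coords) > 0 && ncol(object@coords) != 6L)
    return("coords must have 6 columns (a1..a5, theta)")
  TRUE
})

setMethod("show", "EigenwormBasis", function(object) {
  cat("EigenwormBasis with", nrow(object@vectors), "modes\n")
  vf <- object@variances / sum(object@variances)
  cat("  variance fractions:",
      paste(sprintf("%.3f", vf), collapse = " "), "\n")
})

setMethod("show", "WormBodyModel", function(object) {
  cat(sprintf("WormBodyModel: arc length %.1f px, radii %.2f-%.2f px\n",
              object@arcLength, min(object@radii), max(object@radii)))
})

setMethod("show", "ModeTrajectory", function(object) {
  cat(sprintf("ModeTrajectory: %d frames at %g Hz (%.1f s)\n",
              nrow(object@modes), object@frameRate,
              nrow(object@modes) / object@frameRate))
})

setMethod("show", "FrameSolutionSet", function(object) {
  cat(sprintf("FrameSolutionSet: frame %d, %d candidate(s)\n",
              object@frame, nrow(object@coords)))
})

# ---- accessors ------------------------------------------------------------

#' @rdname EigenwormBasis-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("basisVectors", function(object) standardGeneric("basisVectors"))
#' @rdname EigenwormBasis-class
#' @export
setMethod("basisVectors", "EigenwormBasis", function(object) object@vectors)

#' @rdname EigenwormBasis-class
#' @export
setGeneric("modeVariances", function(object) standardGeneric("modeVariances"))
#' @rdname EigenwormBasis-class
#' @export
setMethod("modeVariances", "EigenwormBasis",
          function(object) object@variances)

#' @rdname ModeTrajectory-class
#' @export
setGeneric("modeValues", function(object) standardGeneric("modeValues"))
#' @rdname ModeTrajectory-class
#' @export
setMethod("modeValues", "ModeTrajectory", function(object) object@modes)

#' @rdname ModeTrajectory-class
#' @export
setGeneric("orientationValues",
           function(object) standardGeneric("orientationValues"))
#' @rdname ModeTrajectory-class
#' @export
setMethod("orientationValues", "ModeTrajectory",
          function(object) object@orientation)

#' @rdname ModeTrajectory-class
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname ModeTrajectory-class
#' @export
setMethod("frameRate", "ModeTrajectory", function(object) object@frameRate)

#' @rdname ModeTrajectory-class
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @rdname ModeTrajectory-class
#' @export
setMethod("frameTimes", "ModeTrajectory", function(object)
  (seq_len(nrow(object@modes)) - 1) / object@frameRate)

#' @rdname FrameSolutionSet-class
#' @export
setGeneric("candidates", function(object) standardGeneric("candidates"))
#' @rdname FrameSolutionSet-class
#' @export
setMethod("candidates", "FrameSolutionSet", function(object) object@coords)

#' @rdname FrameSolutionSet-class
#' @export
setGeneric("candidateErrors",
           function(object) standardGeneric("candidateErrors"))
#' @rdname FrameSolutionSet-class
#' @export
setMethod("candidateErrors", "FrameSolutionSet",
          function(object) object@errors)

#' Number of frames / candidates
#' @param x a \code{ModeTrajectory} or \code{FrameSolutionSet}.
#' @export
setMethod("length", "ModeTrajectory", function(x) nrow(x@modes))
#' @rdname length-ModeTrajectory-method
#' @export
setMethod("length", "FrameSolutionSet", function(x) nrow(x@coords))

# constructors used throughout the package ----------------------------------

newModeTrajectory <- function(modes, orientation, frameRate,
                              provenance = character(0)) {
  colnames(modes) <- paste0("a", 1:5)
  new("ModeTrajectory", frameRate = frameRate, modes = modes,
      orientation = as.numeric(orientation), provenance = provenance)
}
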