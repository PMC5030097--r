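# The two-metric image error f_err = f_outline * f_pixel that defines the
# tracker's fitness landscape.

#' Error-function configuration
#'
#' Weights and geometry of the image error. \code{C0} (per-rad^2) weights the
#' squared outline-angle difference, \code{C1} (per-px^2) the squared
#' perimeter difference; both were left "arbitrary" in the original method,
#' and the defaults here are calibrated on the package's synthetic scale so
#' that good matches score well below the retention threshold of 1.0 while
#' mismatched coils score above it. \code{mergeBox} gives the per-mode
#' half-widths within which candidate solutions are merged; orientation is
#' merged on the circle with its own tolerance.
#'
#' @param C0 outline-angle weight (rad^-2).
#' @param C1 perimeter weight (px^-2).
#' @param blockPx edge of the coarse-graining blocks, px.
#' @param keepThreshold largest retained candidate error.
#' @param mergeBox numeric(5), per-mode merge half-widths.
#' @param mergeOrient orientation merge tolerance, rad (circular).
#' @param nSegments number of equal-arc outline segments.
#' @param smoothSigma Gaussian arc-length smoothing of the traced boundary,
#'   px; removes pixel staircase before resampling.
#' @return a list of class \code{coil_error_config}.
#' @export
errorConfig <- function(C0 = 1.0, C1 = 1 / 100, blockPx = 10L,
                        keepThreshold = 1.0,
                        mergeBox = c(3, 3, 3, 3, 2.5), mergeOrient = 0.5,
                        nSegments = 201L, smoothSigma = 3) {
  stopifnot(C0 > 0, C1 > 0, blockPx >= 2, length(mergeBox) == 5,
            all(mergeBox > 0), mergeOrient > 0, nSegments >= 8)
  structure(list(C0 = C0, C1 = C1, blockPx = as.integer(blockPx),
                 keepThreshold = keepThreshold, mergeBox = mergeBox,
                 mergeOrient = mergeOrient, nSegments = as.integer(nSegments),
                 smoothSigma = smoothSigma),
            class = "coil_error_config")
}

checkImage <- function(img) {
  if (!is.matrix(img) || !is.logical(img))
    stop("a binary worm image must be a logical matrix")
  if (!any(img)) stop("image has no foreground pixels")
  invisible(img)
}

#' Equal-arc outline signature of a binary shape
#'
#' Traces the outer boundary of the (single) foreground component, smooths
#' it with a periodic Gaussian in arc length, resamples the closed curve
#' into \code{nSegments} segments of equal length, and returns the exterior
#' turning angles between consecutive segments together with the perimeter.
#' The open-chain signature drops the angle at the starting junction; the
#' full cyclic angle vector is kept alongside for start-invariant
#' comparisons.
#'
#' @param img logical matrix, one foreground component.
#' @param start integer junction offset at which the open chain is cut
#'   (default 0 = the canonical topmost-leftmost start).
#' @param config an \code{\link{errorConfig}}.
#' @return list with \code{psi} (nSegments - 1 angles, radians),
#'   \code{psiCyclic} (all nSegments junction angles), \code{perimeter}
#'   (px), and \code{points} (the resampled outline).
#' @export
outlineSignature <- function(img, start = 0L, config = errorConfig()) {
  checkImage(img)
  if (componentCount(img) > 1L)
    stop("image has multiple foreground components")
  sig <- cpp_outline_signature(img, config$nSegments, config$smoothSigma)
  n <- length(sig$psi)
  rot <- ((seq_len(n) - 1 + start) %% n) + 1
  psiCyc <- sig$psi[rot]
  list(psi = psiCyc[-1], psiCyclic = psiCyc, perimeter = sig$perimeter,
       points = sig$points)
}

componentCount <- function(img) {
  cpp_component_count(img)
}

#' Outline shape error between two binary images
#'
#' \eqn{f_{outline} = \min [ C_0 \|\psi_1 - \psi_2\|^2 + C_1 (\ell_1 -
#' \ell_2)^2 ]}, minimized over all cyclic starting offsets and both trace
#' directions of the second signature — the equal-arc analog of choosing the
#' pair of boundary starting points that minimizes the error. Symmetric in
#' its arguments.
#'
#' @param img1,img2 logical matrices (binary worm images).
#' @param config an \code{\link{errorConfig}}.
#' @return non-negative scalar.
#' @export
fOutline <- function(img1, img2, config = errorConfig()) {
  s1 <- outlineSignature(img1, config = config)
  s2 <- outlineSignature(img2, config = config)
  cpp_f_outline(s1$psiCyclic, s1$perimeter, s2$psiCyclic, s2$perimeter,
                config$C0, config$C1)
}

#' Coarse-grained pixel-density error
#'
#' Shifts the second image by the nearest-integer offset that aligns the two
#' centroids, overlays a grid of \code{blockPx} x \code{blockPx} blocks on
#' the union bounding box (anchored at its top-left corner; partial blocks
#' padded with background), and returns the mean squared difference of the
#' per-block foreground fractions. Always in [0, 1].
#'
#' @inheritParams fOutline
#' @export
fPixel <- function(img1, img2, config = errorConfig()) {
  checkImage(img1)
  checkImage(img2)
  cpp_f_pixel(img1, img2, config$blockPx)
}

#' Combined image error
#'
#' \eqn{f_{err} = f_{outline} \cdot f_{pixel}}. Zero on identical images
#' (and whenever either factor vanishes — a documented consequence of the
#' product form).
#'
#' @inheritParams fOutline
#' @export
fErr <- function(img1, img2, config = errorConfig()) {
  fOutline(img1, img2, config) * fPixel(img1, img2, config)
}
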