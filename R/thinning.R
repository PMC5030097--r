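# "Classic" thinning tracker for uncrossed frames: segmentation, skeleton
# centerline, crossed-frame labeling.

#' Segment a single dark worm from a grayscale frame
#'
#' Thresholds (Otsu by default, or a fixed level), keeps the largest
#' connected foreground component, and records — without filling — any
#' enclosed background holes (attribute \code{"holes"}).
#'
#' @param gray numeric matrix in [0, 1]; dark worm on light background
#'   unless \code{invert}.
#' @param threshold fixed threshold in [0, 1], or NULL for Otsu.
#' @param invert set TRUE for a light worm on dark background.
#' @return logical matrix with attribute \code{"holes"}.
#' @export
segmentWorm <- function(gray, threshold = NULL, invert = FALSE) {
  if (is.logical(gray)) gray <- 1 - gray * 1  # already binary: worm dark
  if (invert) gray <- 1 - gray
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  fg <- gray < threshold
  if (!any(fg)) stop("segmentation produced an empty foreground")
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  labm <- as.matrix(EBImage::imageData(lab))
  counts <- tabulate(labm[labm > 0])
  mask <- labm == which.max(counts)
  filled <- fillHoles(mask)
  attr(mask, "holes") <- filled & !mask
  mask
}

fillHoles <- function(mask) {
  f <- EBImage::fillHull(EBImage::Image(mask * 1))
  as.matrix(EBImage::imageData(f)) > 0
}

# fill enclosed-background components below maxArea px (pixel-noise pepper);
# genuine coil holes are far larger
fillSmallHoles <- function(mask, maxArea = 5L) {
  holes <- fillHoles(mask) & !mask
  if (!any(holes)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(holes * 1))
  labm <- as.matrix(EBImage::imageData(lab))
  sizes <- tabulate(labm[labm > 0])
  small <- which(sizes < maxArea)
  keep <- matrix(labm %in% small, nrow(labm)) & labm > 0
  mask | keep
}

#' Is a worm image self-occluded (crossed)?
#'
#' TRUE iff the foreground encloses at least one background hole of at
#' least \code{minHoleArea} px, or the morphological skeleton retains a
#' branch point after pruning spurs shorter than 5 px. Hole detection
#' catches closed coils; branch detection catches tangencies where the
#' body touches without enclosing background. The hole-area floor keeps
#' single flipped pixels from pixel noise from counting as coils.
#'
#' @param img logical matrix (segmented worm).
#' @param spurLength minimum spur length kept during pruning, px.
#' @param minHoleArea smallest enclosed-background area that counts, px.
#' @export
isCrossed <- function(img, spurLength = 5L, minHoleArea = 5L) {
  checkImage(img)
  holes <- fillHoles(img) & !img
  if (any(holes)) {
    lab <- EBImage::bwlabel(EBImage::Image(holes * 1))
    if (max(tabulate(as.integer(lab[lab > 0]))) >= minHoleArea) return(TRUE)
  }
  # sub-threshold holes are pixel noise: fill them so they cannot create
  # skeleton loops around themselves
  skel <- cpp_prune_spurs(cpp_skeletonize(fillSmallHoles(img, minHoleArea)),
                          spurLength)
  info <- cpp_skeleton_info(skel)
  length(info$branch_x) > 0
}

#' Thinning centerline of an uncrossed worm image
#'
#' Skeletonizes the shape, prunes short spurs, takes the longest
#' endpoint-to-endpoint skeleton path, extends it to the body tips, and
#' resamples to 100 equidistant points. Status is \code{"crossed"} when
#' \code{\link{isCrossed}} fires and \code{"failed"} for degenerate
#' skeletons; head/tail orientation of the returned points is arbitrary
#' (the sequence filter owns that decision).
#'
#' @param img logical matrix.
#' @return list(status = "ok" | "crossed" | "failed", points = 100 x 2
#'   (x, y) or NULL).
#' @export
thinCenterline <- function(img) {
  checkImage(img)
  if (isCrossed(img)) return(list(status = "crossed", points = NULL))
  img <- fillSmallHoles(img)
  skel <- cpp_prune_spurs(cpp_skeletonize(img), 5L)
  path <- cpp_longest_path(skel)
  if (nrow(path) < 5) return(list(status = "failed", points = NULL))
  path <- extendToTips(path, img)
  # the raw skeleton path is pixel-jagged; smooth it before the equal-arc
  # resampling so tangent angles are not dominated by grid noise
  pts <- smoothPolyline(resamplePolyline(path, 100L), sigma = 2)
  pts <- resamplePolyline(pts, 100L)
  list(status = "ok", points = pts)
}

# extend a centerline path beyond the skeleton ends to the body tips,
# marching along the end tangent while inside the foreground
extendToTips <- function(path, img) {
  H <- nrow(img); W <- ncol(img)
  inside <- function(p) {
    i <- round(p[2]) + 1
    j <- round(p[1]) + 1
    i >= 1 && i <= H && j >= 1 && j <= W && img[i, j]
  }
  extend <- function(pts) {
    n <- nrow(pts)
    k <- min(5, n - 1)
    dir <- pts[n, ] - pts[n - k, ]
    dir <- dir / sqrt(sum(dir^2))
    p <- pts[n, ]
    added <- NULL
    for (s in seq(0.5, 30, by = 0.5)) {
      q <- pts[n, ] + dir * s
      if (!inside(q)) break
      p <- q
    }
    if (!isTRUE(all.equal(p, pts[n, ]))) rbind(pts, p) else pts
  }
  path <- extend(path)
  path <- extend(path[nrow(path):1, ])
  path[nrow(path):1, ]
}

# open-curve Gaussian smoothing in index space (sigma in points); the
# kernel is truncated and renormalized at the ends
smoothPolyline <- function(pts, sigma = 2) {
  n <- nrow(pts)
  hw <- ceiling(3 * sigma)
  kern <- exp(-(-hw:hw)^2 / (2 * sigma^2))
  out <- pts
  for (i in seq_len(n)) {
    j <- max(1, i - hw):min(n, i + hw)
    w <- kern[j - i + hw + 1]
    out[i, ] <- c(sum(w * pts[j, 1]), sum(w * pts[j, 2])) / sum(w)
  }
  out
}

resamplePolyline <- function(pts, n) {
  seglen <- sqrt(rowSums(diff(pts)^2))
  cs <- c(0, cumsum(seglen))
  L <- cs[length(cs)]
  target <- seq(0, L, length.out = n)
  cbind(x = stats::approx(cs, pts[, 1], xout = target, ties = "ordered")$y,
        y = stats::approx(cs, pts[, 2], xout = target, ties = "ordered")$y)
}

#' Tangent-angle profile from an ordered centerline
#'
#' \eqn{\theta_k} is the direction of point k+1 minus point k (k < 100);
#' the last angle repeats the 99th. Angles are unwrapped head-to-tail.
#'
#' @param points numeric 100 x 2 ordered (x, y) centerline positions.
#' @return numeric(100) tangent angles, radians.
#' @export
anglesFromCenterline <- function(points) {
  if (nrow(points) != 100L) stop("centerline must contain 100 points")
  d <- diff(points)
  if (any(rowSums(d^2) == 0))
    stop("duplicate consecutive centerline points")
  th <- atan2(d[, 2], d[, 1])
  unwrapAngles(c(th, th[99]))
}
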