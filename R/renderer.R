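# Forward model: posture -> binary worm image.
#
# Image convention (package-wide): x right, y down, origin at the top-left
# pixel center; angles from +x toward +y. A binary worm image is a logical
# matrix with rows = y and columns = x.

#' Construct a worm body model
#'
#' Default synthetic geometry: body length 120 px, maximum half-thickness
#' 5 px, smoothly tapered over the 15 points nearest each end. Coiled shapes
#' at this scale fit a 160 x 160 canvas with margin.
#'
#' @param arcLength total backbone length, px.
#' @param maxRadius mid-body disc radius, px.
#' @param taperPoints number of backbone points over which each end tapers.
#' @return a \code{\linkS4class{WormBodyModel}}.
#' @export
wormBodyModel <- function(arcLength = 120, maxRadius = 5, taperPoints = 15) {
  j <- 1:100
  taper <- pmin(1, pmin(j, 101 - j) / taperPoints)
  radii <- maxRadius * sin(pi / 2 * taper)
  radii <- pmax(radii, 0.9)
  new("WormBodyModel", arcLength = arcLength, radii = radii)
}

#' Backbone positions from a tangent-angle profile
#'
#' Integrates the tangent angles into 100 (x, y) backbone points: point 1 at
#' \code{anchor}, and segment k (of length arcLength/99) directed along the
#' mean of the angles at its two endpoints. The mean-angle rule makes
#' head/tail reversal an exact geometric involution.
#'
#' @param profile numeric(100) tangent angles, radians.
#' @param arcLength total backbone length, px.
#' @param anchor numeric(2), (x, y) of the first point.
#' @return numeric matrix 100 x 2 of (x, y) positions.
#' @export
backboneFromAngles <- function(profile, arcLength, anchor = c(0, 0)) {
  checkProfile(profile)
  if (arcLength <= 0) stop("arcLength must be positive")
  seg <- arcLength / 99
  mid <- (profile[-100] + profile[-1]) / 2
  x <- anchor[1] + c(0, cumsum(seg * cos(mid)))
  y <- anchor[2] + c(0, cumsum(seg * sin(mid)))
  cbind(x = x, y = y)
}

#' Render a binary worm image from posture coordinates
#'
#' The generative forward model: reconstructs the tangent-angle profile from
#' \code{coords}, integrates the backbone, and draws the union of 100 filled
#' discs with the body-model radii. A pixel is foreground iff its center
#' lies within distance r_j of backbone point j for some j (inclusive
#' boundary). The shape is placed by translating the backbone centroid to
#' the exact canvas center — a purely geometric rule, invariant under
#' head/tail reversal — unless an \code{anchor} for backbone point 1 is
#' supplied. Errors if the shape cannot fit, naming the required canvas.
#'
#' @param coords numeric(6) posture coordinates (a1..a5, theta), or a
#'   numeric(100) tangent-angle profile.
#' @param basis an \code{EigenwormBasis} (ignored when a full profile is
#'   given).
#' @param body a \code{WormBodyModel}.
#' @param canvas integer(2), c(rows, cols) of the output image.
#' @param anchor optional numeric(2) (x, y) for backbone point 1; disables
#'   centroid centering.
#' @return logical matrix (rows x cols) with attribute \code{"backbone"}:
#'   the 100 x 2 backbone positions in canvas coordinates.
#' @export
renderWorm <- function(coords, basis = NULL, body = wormBodyModel(),
                       canvas = c(160, 160), anchor = NULL) {
  theta <- if (length(coords) == 100L) coords
           else reconstructProfile(coords, basis)
  res <- cpp_render(theta, body@arcLength, body@radii,
                    as.integer(canvas[1]), as.integer(canvas[2]),
                    is.null(anchor),
                    if (is.null(anchor)) 0 else anchor[1],
                    if (is.null(anchor)) 0 else anchor[2],
                    TRUE)
  mask <- res$mask
  attr(mask, "backbone") <- res$points
  mask
}

#' Estimate a worm body model from segmented uncrossed frames
#'
#' For each uncrossed frame, extracts the thinning centerline and the
#' 4-connected outline, and measures r_j as the minimum distance from
#' backbone point j to the outline; radii and arc length are averaged across
#' frames (the paper's per-worm thickness calibration).
#'
#' @param frames list of binary worm images (logical matrices).
#' @return a \code{WormBodyModel}.
#' @export
estimateBodyModel <- function(frames) {
  if (is.matrix(frames)) frames <- list(frames)
  radii <- NULL
  lens <- c()
  for (img in frames) {
    cl <- thinCenterline(img)
    if (cl$status != "ok") next
    pts <- cl$points
    # outer outline only (holes from pixel noise would bias radii down);
    # boundary pixel centers sit about half a pixel inside the true edge
    edge <- outlinePixels(fillHoles(img))
    d2 <- outer(pts[, 1], edge[, 1], "-")^2 + outer(pts[, 2], edge[, 2], "-")^2
    rj <- sqrt(apply(d2, 1, min)) + 0.5
    radii <- rbind(radii, rj)
    lens <- c(lens, sum(sqrt(rowSums(diff(pts)^2))))
  }
  if (is.null(radii))
    stop("no uncrossed frame with a valid thinning centerline")
  r <- colMeans(radii)
  # enforce the tapered-ends invariant against pixel-level noise
  n <- length(r)
  r[1] <- min(r[seq_len(n %/% 2)])
  r[n] <- min(r[(n %/% 2 + 1):n])
  new("WormBodyModel", arcLength = mean(lens), radii = pmax(r, 0.9))
}

# foreground pixels with at least one 4-connected background neighbour,
# as (x, y) centers
outlinePixels <- function(img) {
  H <- nrow(img); W <- ncol(img)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- img
  core <- pad[2:(H + 1), 2:(W + 1)]
  nbg <- !pad[1:H, 2:(W + 1)] | !pad[3:(H + 2), 2:(W + 1)] |
         !pad[2:(H + 1), 1:W] | !pad[2:(H + 1), 3:(W + 2)]
  idx <- which(core & nbg, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

#' Read / write a body model file
#'
#' CSV with a header comment carrying the arc length and two columns (j,
#' r_j).
#' @param body a \code{WormBodyModel}.
#' @param path file path.
#' @export
writeBodyModel <- function(body, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# arc_length=%s", format(body@arcLength, digits = 17)),
             con)
  utils::write.table(data.frame(j = 1:100, r = body@radii), con, sep = ",",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeBodyModel
#' @export
readBodyModel <- function(path) {
  lines <- readLines(path, n = 1)
  al <- as.numeric(sub("^# arc_length=", "", lines))
  df <- utils::read.csv(path, skip = 1)
  new("WormBodyModel", arcLength = al, radii = df$r)
}

#' Write a binary image (or stack) to PNG / TIFF
#'
#' 8-bit single channel, 0 = background, 255 = worm.
#' @param img logical matrix, or a list / 3-d array of them for TIFF stacks.
#' @param path output path; extension selects the format.
#' @export
writeWormImage <- function(img, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(matrix(as.numeric(img), nrow(img)), path)
  } else {
    if (is.list(img)) img <- simplify2array(img)
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    frames <- lapply(seq_len(dim(img)[3]),
                     function(k) matrix(as.numeric(img[, , k]), dim(img)[1]))
    tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' @rdname writeWormImage
#' @param threshold gray level above which a pixel counts as worm.
#' @export
readWormImage <- function(path, threshold = 0.5) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    g <- png::readPNG(path)
    if (length(dim(g)) == 3L) g <- g[, , 1]
    return(g > threshold)
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  masks <- lapply(frames, function(g) {
    if (length(dim(g)) == 3L) g <- g[, , 1]
    g > threshold
  })
  if (length(masks) == 1L) masks[[1]] else masks
}
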