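# Sequence filtering: choose one candidate per frame minimizing total
# sequence error under continuity constraints; interpolate gaps; resolve
# head/tail orientation.

#' Sequence-filter configuration
#'
#' \code{vMax} is the maximum per-frame change of each mode; the
#' orientation rate limit (default ~pi rad/s, scaled by the frame rate) is
#' what rules out head/tail flips between frames. Gap frames (no retained
#' candidate) cost \code{gapPenalty} each and may span at most
#' \code{maxGap} frames; the per-coordinate limits scale linearly with the
#' span when bridging a gap.
#'
#' @param vMax numeric(5), max per-frame mode change (mode units).
#' @param orientationRateLimit rad per second.
#' @param gapPenalty cost per skipped frame.
#' @param maxGap maximum gap length, frames.
#' @return a list of class \code{coil_filter_config}.
#' @export
filterConfig <- function(vMax = c(3, 3, 4, 3, 2),
                         orientationRateLimit = pi, gapPenalty = 1.0,
                         maxGap = 8L) {
  stopifnot(length(vMax) == 5, all(vMax > 0), orientationRateLimit > 0,
            gapPenalty > 0, maxGap >= 1)
  structure(list(vMax = vMax, orientationRateLimit = orientationRateLimit,
                 gapPenalty = gapPenalty, maxGap = as.integer(maxGap)),
            class = "coil_filter_config")
}

transitionFeasible <- function(p, q, span, config, frameRate) {
  all(abs(q[1:5] - p[1:5]) <= config$vMax * span) &&
    circDist(q[6], p[6]) <=
      config$orientationRateLimit / frameRate * span
}

#' Minimum-total-error path through per-frame candidate sets
#'
#' Dynamic programming (Viterbi-style, exact for this cost structure) over
#' the layered candidate graph: node cost = candidate error, gap nodes cost
#' \code{gapPenalty}, and edges exist only between velocity-feasible
#' candidate pairs (limits scaled by the spanned frame count across gaps).
#' Returns the feasible choice vector b (0 = gap) minimizing the total
#' sequence error E(b).
#'
#' @param sets list of \code{\linkS4class{FrameSolutionSet}}.
#' @param config a \code{\link{filterConfig}}.
#' @param frameRate Hz (converts the orientation rate limit to per-frame).
#' @return list(choices = integer(N), totalError, feasible).
#' @export
selectPath <- function(sets, config = filterConfig(), frameRate = 16) {
  N <- length(sets)
  if (N < 1) stop("need at least one frame")
  M <- vapply(sets, length, 1L)
  err <- lapply(sets, candidateErrors)
  crd <- lapply(sets, candidates)
  gp <- config$gapPenalty
  maxGap <- config$maxGap

  # cost[[j]][k]: best cost of a path ending at candidate k of frame j
  cost <- lapply(M, function(m) rep(Inf, m))
  back <- lapply(M, function(m) vector("list", m))
  for (j in seq_len(N)) {
    for (k in seq_len(M[j])) {
      # start of path: j - 1 leading gap frames
      best <- if (j - 1 <= maxGap) (j - 1) * gp + err[[j]][k] else Inf
      bptr <- NULL
      for (g in 0:min(maxGap, j - 2)) {
        jp <- j - g - 1
        if (jp < 1) break
        for (kp in seq_len(M[jp])) {
          if (!is.finite(cost[[jp]][kp])) next
          cand <- cost[[jp]][kp] + g * gp + err[[j]][k]
          if (cand < best &&
              transitionFeasible(crd[[jp]][kp, ], crd[[j]][k, ],
                                 g + 1, config, frameRate)) {
            best <- cand
            bptr <- c(jp, kp)
          }
        }
      }
      cost[[j]][k] <- best
      back[[j]][k] <- list(bptr)
    }
  }

  # best terminal: candidate at frame j plus N - j trailing gaps
  best <- Inf
  endj <- 0L
  endk <- 0L
  for (j in seq_len(N)) {
    if (N - j > maxGap) next
    for (k in seq_len(M[j])) {
      v <- cost[[j]][k] + (N - j) * gp
      if (v < best) {
        best <- v
        endj <- j
        endk <- k
      }
    }
  }
  if (!is.finite(best)) {
    span <- which(M == 0)
    stop("no feasible path through the candidate sets (first infeasible ",
         "frame span starts at frame ",
         if (length(span)) span[1] else 1L, ")")
  }
  choices <- integer(N)
  j <- endj
  k <- endk
  while (!is.null(j)) {
    choices[j] <- k
    ptr <- back[[j]][[k]]
    if (is.null(ptr)) break
    j <- ptr[1]
    k <- ptr[2]
  }
  list(choices = choices, totalError = best,
       feasible = TRUE)
}

#' Interpolate gap frames with cubic splines
#'
#' Gap frames (choice 0) are filled per coordinate by an interpolating
#' cubic spline (Forsythe-Malcolm-Moler end conditions, so cubic
#' trajectories are reproduced exactly) through the chosen frames; non-gap
#' frames pass through unchanged. Orientation is unwrapped before
#' splining.
#'
#' @param path result of \code{\link{selectPath}}.
#' @param sets the candidate sets used to build the path.
#' @param frameRate Hz.
#' @return a \code{\linkS4class{ModeTrajectory}} with per-frame provenance
#'   \code{"candidate"} or \code{"interpolated"}.
#' @export
interpolateGaps <- function(path, sets, frameRate = 16) {
  N <- length(sets)
  choices <- path$choices
  known <- which(choices > 0)
  if (length(known) < 1) stop("path has no chosen candidates")
  gaps <- which(choices == 0)
  vals <- matrix(NA_real_, N, 6)
  for (j in known) vals[j, ] <- candidates(sets[[j]])[choices[j], ]
  # unwrap orientation along chosen frames
  vals[known, 6] <- unwrapAngles(vals[known, 6])
  if (length(gaps) > 0) {
    edgeGap <- any(gaps < known[1]) || any(gaps > known[length(known)])
    if (edgeGap && length(known) < 2)
      stop("gap at the sequence edge with fewer than 2 supporting frames")
    for (c in 1:6) {
      sp <- stats::spline(known, vals[known, c], method = "fmm",
                          xout = gaps)
      vals[gaps, c] <- sp$y
    }
  }
  prov <- ifelse(choices > 0, "candidate", "interpolated")
  newModeTrajectory(vals[, 1:5, drop = FALSE], vals[, 6], frameRate, prov)
}

#' Head/tail swap of a posture
#'
#' Reconstructs the tangent angles, reverses the body index order, adds pi
#' to every angle, re-unwraps and re-projects. With the package's
#' reversal-symmetric basis and mean-angle backbone integration, the
#' rendered images of a posture and its swap are pixel-identical, and the
#' swap is an exact involution.
#'
#' @param coords numeric(6) posture coordinates.
#' @param basis an \code{EigenwormBasis}.
#' @return numeric(6) swapped coordinates.
#' @export
swapHeadTail <- function(coords, basis) {
  th <- reconstructProfile(coords, basis)
  p <- projectPosture(unwrapAngles(rev(th) + pi), basis)
  p[6] <- wrapAngle(p[6])
  p
}

#' Resolve head/tail orientation through a tracked segment
#'
#' Implements the orientation-resolution ladder: (1) every uncrossed frame
#' offers both its thinning solution and the head/tail-swapped version;
#' (2) the orientation rate limit in \code{\link{selectPath}} forbids
#' inter-frame flips; (3) the selected path is compared, by total rendered
#' image error over all frames, against its globally swapped version and
#' the lower-error one is kept; (4) a review flag is raised when the margin
#' between the two is below 5\% relative — silhouettes alone cannot
#' distinguish a worm from its reversal, so near-ties are expected and
#' flagged for external resolution.
#'
#' @param sets list of \code{FrameSolutionSet} (already containing swapped
#'   alternatives for uncrossed frames, as built by \code{runTracking}).
#' @param frames list of binary images (for the global error comparison).
#' @param basis,body rendering model.
#' @param config a \code{\link{filterConfig}}.
#' @param searchCfg a \code{\link{searchConfig}} (error configuration).
#' @param frameRate Hz.
#' @return list(trajectory = ModeTrajectory, reviewFlag, margin,
#'   totalError).
#' @export
resolveHeadTail <- function(sets, frames, basis, body,
                            config = filterConfig(),
                            searchCfg = searchConfig(), frameRate = 16) {
  path <- selectPath(sets, config, frameRate)
  traj <- interpolateGaps(path, sets, frameRate)
  swapped <- swapTrajectory(traj, basis)
  eA <- trajectoryImageError(traj, frames, basis, body, searchCfg$error)
  eB <- trajectoryImageError(swapped, frames, basis, body, searchCfg$error)
  margin <- abs(eA - eB) / max(eA, eB, .Machine$double.eps)
  keep <- if (eB < eA) swapped else traj
  list(trajectory = keep, reviewFlag = margin < 0.05, margin = margin,
       totalError = min(eA, eB))
}

swapTrajectory <- function(traj, basis) {
  m <- modeValues(traj)
  o <- orientationValues(traj)
  out <- t(vapply(seq_len(nrow(m)), function(j)
    swapHeadTail(c(m[j, ], o[j]), basis), numeric(6)))
  newModeTrajectory(out[, 1:5, drop = FALSE], unwrapAngles(out[, 6]),
                    frameRate(traj), traj@provenance)
}

# total f_err of a trajectory's renders against the observed frames
trajectoryImageError <- function(traj, frames, basis, body, ec) {
  m <- modeValues(traj)
  o <- orientationValues(traj)
  tot <- 0
  for (j in seq_along(frames)) {
    img <- tryCatch(renderWorm(c(m[j, ], o[j]), basis, body,
                               canvas = dim(frames[[j]])),
                    error = function(e) NULL)
    tot <- tot + if (is.null(img)) 10 else fErr(frames[[j]], img, ec)
  }
  tot
}
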