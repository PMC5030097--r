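# Inverse tracker: per-frame global search in the 6-D (a1..a5, orientation)
# space by multi-restart generalized pattern search.

#' Search configuration for the inverse tracker
#'
#' Bounds, feasibility limits, and pattern-search mesh parameters. The mode
#' bounds (18, 18, 34, 12, 6) and the local-curvature limit of 1.95 rad over
#' a 10-index separation restrict the search to naturally occurring shapes;
#' candidates are kept below \code{keepThreshold} and merged within the
#' merge box.
#'
#' @param modeBounds numeric(5), per-mode absolute bounds.
#' @param curvatureLimit max |theta(k+sep) - theta(k)|, rad.
#' @param curvatureSep index separation for the curvature limit.
#' @param restarts number of random pattern-search restarts per frame.
#' @param meshInit,meshTol,expand,contract generalized-pattern-search mesh:
#'   initial size (mode units), termination size, and the success / failure
#'   scale factors.
#' @param meshMax cap on mesh growth under repeated successes; capping at
#'   the initial mesh size keeps restarts exploring at a controlled scale
#'   and measurably improves minimum recovery per evaluation.
#' @param maxIter iteration cap per restart.
#' @param error an \code{\link{errorConfig}} (supplies keep threshold and
#'   merge box).
#' @return a list of class \code{coil_search_config}.
#' @export
searchConfig <- function(modeBounds = c(18, 18, 34, 12, 6),
                         curvatureLimit = 1.95, curvatureSep = 10L,
                         restarts = 300L, meshInit = 4.0, meshTol = 0.05,
                         expand = 2.0, contract = 0.5, meshMax = meshInit,
                         maxIter = 400L, error = errorConfig()) {
  stopifnot(length(modeBounds) == 5, all(modeBounds > 0), restarts >= 1,
            meshTol < meshInit, expand > 1, contract < 1)
  structure(list(modeBounds = modeBounds, curvatureLimit = curvatureLimit,
                 curvatureSep = as.integer(curvatureSep),
                 restarts = as.integer(restarts), meshInit = meshInit,
                 meshTol = meshTol, expand = expand, contract = contract,
                 meshMax = meshMax, maxIter = as.integer(maxIter),
                 error = error),
            class = "coil_search_config")
}

#' Local-curvature feasibility of a tangent-angle profile
#'
#' TRUE iff no two (body-unwrapped) tangent angles 10 indices apart differ
#' by more than the limit — ruling out unnaturally coiled shapes.
#'
#' @param profile numeric(100) tangent angles.
#' @param limit maximum angle difference, rad.
#' @param separation index gap.
#' @export
curvatureOk <- function(profile, limit = 1.95, separation = 10L) {
  th <- unwrapAngles(profile)
  n <- length(th)
  idx <- seq_len(n - separation)
  max(abs(th[idx + separation] - th[idx])) <= limit
}

#' Generalized pattern search
#'
#' Derivative-free minimization: polls the 2n points one mesh step along
#' +/- each coordinate (clamped to the bounds), moves to the best improving
#' poll and expands the mesh on success, contracts it on failure, and stops
#' when the mesh drops below \code{meshTol}. The returned value never
#' exceeds the objective at the start.
#'
#' @param objective function(numeric(n)) -> scalar; must be finite at
#'   \code{start}.
#' @param start numeric(n) starting point, within bounds.
#' @param lower,upper numeric(n) box bounds (may be +/-Inf).
#' @param meshInit,meshTol,expand,contract,maxIter mesh parameters (see
#'   \code{\link{searchConfig}}).
#' @return list(par, value, evaluations).
#' @export
patternSearch <- function(objective, start, lower, upper, meshInit = 4.0,
                          meshTol = 0.05, expand = 2.0, contract = 0.5,
                          maxIter = 400L, meshMax = Inf) {
  x <- pmin(pmax(start, lower), upper)
  fx <- objective(x)
  if (!is.finite(fx)) stop("objective is not finite at the starting point")
  mesh <- meshInit
  n <- length(x)
  evals <- 1L
  for (it in seq_len(maxIter)) {
    if (mesh < meshTol) break
    bestF <- fx
    bestX <- NULL
    for (i in seq_len(n)) {
      for (s in c(1, -1)) {
        cand <- x
        cand[i] <- min(max(cand[i] + s * mesh, lower[i]), upper[i])
        if (cand[i] == x[i]) next
        f <- objective(cand)
        evals <- evals + 1L
        if (f < bestF) {
          bestF <- f
          bestX <- cand
        }
      }
    }
    if (!is.null(bestX)) {
      x <- bestX
      fx <- bestF
      mesh <- min(mesh * expand, meshMax)
    } else {
      mesh <- mesh * contract
    }
  }
  list(par = x, value = fx, evaluations = evals)
}

#' Per-frame inverse search
#'
#' Runs \code{restarts} pattern searches from starting points drawn
#' uniformly within the mode bounds (orientation uniform on [0, 2*pi)),
#' minimizing \eqn{f_{err}(\mathrm{image}, \mathrm{render}(p))}; postures
#' violating the curvature limit (or not fitting the canvas) score +Inf.
#' Minima with error below the keep threshold are retained and merged
#' within the merge box (orientation compared on the circle), keeping the
#' lowest-error member of each cluster. An empty candidate set is a legal
#' result.
#'
#' Uses R's RNG: call \code{set.seed} first for reproducible candidate
#' sets.
#'
#' @param image logical matrix, the segmented movie frame.
#' @param basis an \code{EigenwormBasis}.
#' @param body a \code{WormBodyModel}.
#' @param config a \code{\link{searchConfig}}.
#' @param frame frame index stored in the result.
#' @return a \code{\linkS4class{FrameSolutionSet}}.
#' @export
searchFrame <- function(image, basis, body, config = searchConfig(),
                        frame = 1L) {
  checkImage(image)
  ec <- config$error
  target <- outlineSignature(image, config = ec)
  vec <- basisVectors(basis)[1:5, , drop = FALSE]
  H <- nrow(image)
  W <- ncol(image)
  obj <- function(p) {
    cpp_frame_objective(p, vec, body@arcLength, body@radii, H, W,
                        target$psiCyclic, target$perimeter, image,
                        ec$C0, ec$C1, ec$blockPx, ec$nSegments,
                        ec$smoothSigma, config$curvatureLimit,
                        config$curvatureSep)
  }
  b <- config$modeBounds
  lower <- c(-b, -Inf)
  upper <- c(b, Inf)
  coords <- matrix(numeric(0), 0, 6)
  errors <- numeric(0)
  for (r in seq_len(config$restarts)) {
    # redraw until the start is curvature-feasible (finite objective)
    f0 <- Inf
    for (try in 1:50) {
      start <- c(stats::runif(5, -b, b), stats::runif(1, 0, 2 * pi))
      f0 <- obj(start)
      if (is.finite(f0)) break
    }
    if (!is.finite(f0)) next
    res <- patternSearch(obj, start, lower, upper, config$meshInit,
                         config$meshTol, config$expand, config$contract,
                         config$maxIter, config$meshMax)
    if (res$value < ec$keepThreshold) {
      p <- res$par
      p[6] <- wrapAngle(p[6])
      coords <- rbind(coords, p)
      errors <- c(errors, res$value)
    }
  }
  merged <- mergeCandidates(coords, errors, ec$mergeBox, ec$mergeOrient)
  rownames(merged$coords) <- NULL
  colnames(merged$coords) <- c(paste0("a", 1:5), "theta")
  new("FrameSolutionSet", frame = as.integer(frame),
      coords = merged$coords, errors = merged$errors)
}

#' Merge nearby candidate solutions
#'
#' Candidates whose modes all lie within the per-mode merge half-widths and
#' whose orientations are within the circular tolerance are clustered;
#' only the lowest-error member of each cluster survives. Greedy in order
#' of increasing error, hence idempotent.
#'
#' @param coords M x 6 matrix of candidate coordinates.
#' @param errors numeric(M).
#' @param mergeBox numeric(5) per-mode half-widths.
#' @param mergeOrient circular orientation tolerance, rad.
#' @return list(coords, errors) of the surviving candidates.
#' @export
mergeCandidates <- function(coords, errors, mergeBox = c(3, 3, 3, 3, 2.5),
                            mergeOrient = 0.5) {
  if (nrow(coords) == 0)
    return(list(coords = coords, errors = errors))
  ord <- order(errors)
  keep <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (k in keep) {
      if (all(abs(coords[i, 1:5] - coords[k, 1:5]) <= mergeBox) &&
          circDist(coords[i, 6], coords[k, 6]) <= mergeOrient) {
        dup <- TRUE
        break
      }
    }
    if (!dup) keep <- c(keep, i)
  }
  keep <- sort(keep)
  list(coords = coords[keep, , drop = FALSE], errors = errors[keep])
}

#' Dump a frame's candidate solutions as JSON lines
#'
#' One JSON object per candidate: frame, a1..a5, theta, err.
#'
#' @param sets a \code{FrameSolutionSet} or a list of them.
#' @param path output file.
#' @export
writeCandidates <- function(sets, path) {
  if (is(sets, "FrameSolutionSet")) sets <- list(sets)
  con <- file(path, "w")
  on.exit(close(con))
  for (fs in sets) {
    cc <- candidates(fs)
    ee <- candidateErrors(fs)
    for (i in seq_len(nrow(cc))) {
      rec <- c(list(frame = fs@frame),
               as.list(stats::setNames(cc[i, ],
                                       c(paste0("a", 1:5), "theta"))),
               list(err = ee[i]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}
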