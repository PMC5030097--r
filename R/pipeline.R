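# End-to-end orchestration: route frames to thinning or inverse search,
# filter, analyze, and report.

#' Split a crossed-flag sequence into tracking segments
#'
#' A segment is a maximal run of non-crossed frames, followed by crossed
#' frames, followed by non-crossed frames; uncrossed stretches between two
#' crossed runs are split at their midpoint so that the segments tile the
#' sequence exactly once. A movie with no crossed frames is a single
#' uncrossed segment; an entirely crossed movie is a single segment with a
#' warning.
#'
#' @param crossed logical per frame.
#' @return data.frame(start, end, hasCrossed).
#' @export
segmentRuns <- function(crossed) {
  n <- length(crossed)
  if (n == 0) stop("empty flag sequence")
  if (all(crossed)) {
    warning("movie is entirely crossed")
    return(data.frame(start = 1L, end = n, hasCrossed = TRUE))
  }
  r <- rle(crossed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  crossedRuns <- which(r$values)
  if (!length(crossedRuns))
    return(data.frame(start = 1L, end = n, hasCrossed = FALSE))
  # cut points: midpoints of uncrossed runs separating two crossed runs
  cuts <- integer(0)
  for (k in which(!r$values)) {
    if (k > 1 && k < length(r$values))
      cuts <- c(cuts, starts[k] + r$lengths[k] %/% 2)
  }
  bounds <- c(1L, cuts, n + 1L)
  out <- data.frame(start = bounds[-length(bounds)],
                    end = bounds[-1] - 1L)
  out$hasCrossed <- vapply(seq_len(nrow(out)), function(i)
    any(crossed[out$start[i]:out$end[i]]), logical(1))
  out
}

#' Track a movie end to end
#'
#' Runs the full pipeline: (optional 2x temporal down-sampling,) thinning
#' on all frames with crossed-frame labeling, inverse pattern search on
#' crossed frames, per-segment sequence filtering with gap interpolation
#' and head/tail resolution, and re-assembly into one trajectory plus a
#' run manifest.
#'
#' Uncrossed frames contribute two candidates (the thinning solution and
#' its head/tail swap) with their rendered image errors; crossed frames
#' contribute the inverse-search candidate set.
#'
#' @param frames list of binary images (logical matrices), or grayscale
#'   matrices to be segmented.
#' @param basis an \code{EigenwormBasis}.
#' @param body a \code{WormBodyModel}; NULL to estimate it from the
#'   uncrossed frames.
#' @param searchCfg a \code{\link{searchConfig}}.
#' @param filterCfg a \code{\link{filterConfig}}.
#' @param frameRate Hz of the input movie.
#' @param downsample halve the frame rate by dropping every second frame.
#' @param seed RNG seed for the inverse search.
#' @return list(trajectory = \code{ModeTrajectory}, manifest).
#' @export
runTracking <- function(frames, basis, body = NULL,
                        searchCfg = searchConfig(),
                        filterCfg = filterConfig(), frameRate = 16,
                        downsample = FALSE, seed = 1L) {
  set.seed(seed)
  if (downsample) {
    frames <- frames[seq(1, length(frames), by = 2)]
    frameRate <- frameRate / 2
  }
  masks <- lapply(frames, function(f)
    if (is.logical(f)) f else segmentWorm(f))
  thin <- lapply(masks, thinCenterline)
  crossed <- vapply(thin, function(x) x$status != "ok", logical(1))
  if (is.null(body)) body <- estimateBodyModel(masks[!crossed])
  ec <- searchCfg$error
  nInverse <- 0L
  sets <- vector("list", length(masks))
  for (j in seq_along(masks)) {
    if (!crossed[j]) {
      p <- projectPosture(anglesFromCenterline(thin[[j]]$points), basis)
      p[6] <- wrapAngle(p[6])
      ps <- swapHeadTail(p, basis)
      ps[6] <- wrapAngle(ps[6])
      err <- tryCatch(
        fErr(masks[[j]], renderWorm(p, basis, body, dim(masks[[j]])), ec),
        error = function(e) ec$keepThreshold / 2)
      sets[[j]] <- new("FrameSolutionSet", frame = j,
                       coords = rbind(p, ps, deparse.level = 0),
                       errors = c(err, err))
    } else {
      sets[[j]] <- searchFrame(masks[[j]], basis, body, searchCfg, j)
      nInverse <- nInverse + 1L
    }
  }
  segs <- segmentRuns(crossed)
  trajParts <- list()
  flags <- logical(nrow(segs))
  for (si in seq_len(nrow(segs))) {
    idx <- segs$start[si]:segs$end[si]
    res <- resolveHeadTail(sets[idx], masks[idx], basis, body, filterCfg,
                           searchCfg, frameRate)
    trajParts[[si]] <- res$trajectory
    flags[si] <- res$reviewFlag
  }
  modes <- do.call(rbind, lapply(trajParts, modeValues))
  orient <- unwrapAngles(do.call(c, lapply(trajParts, orientationValues)))
  prov <- do.call(c, lapply(trajParts, function(x) x@provenance))
  prov[crossed & prov == "candidate"] <- "inverse"
  prov[!crossed & prov == "candidate"] <- "thinning"
  traj <- newModeTrajectory(modes, orient, frameRate, prov)
  manifest <- list(nFrames = length(masks), frameRate = frameRate,
                   seed = seed, crossed = crossed, nInverse = nInverse,
                   segments = segs, reviewFlags = flags,
                   version = as.character(utils::packageVersion("coilTrack")))
  list(trajectory = traj, manifest = manifest)
}

#' Run the behavioral analysis suite on mode trajectories
#'
#' Detects large-amplitude a3 extrema per trajectory, classifies them,
#' brackets turns and measures reorientations, and — when several worms
#' are given — computes sliding-window turn rates and the omega/delta
#' event mutual information. Optionally writes events / rates CSVs and an
#' MI JSON under \code{outDir}.
#'
#' @param trajs list of \code{ModeTrajectory}.
#' @param basis an \code{EigenwormBasis}.
#' @param outDir optional output directory.
#' @param rates compute turn-rate adaptation (needs multi-minute records).
#' @param mi compute omega/delta mutual information.
#' @return list(events, rates, mi).
#' @export
runAnalysis <- function(trajs, basis, outDir = NULL, rates = TRUE,
                        mi = TRUE) {
  if (is(trajs, "ModeTrajectory")) trajs <- list(trajs)
  if (!length(trajs)) {
    warning("no trajectories given; empty analysis")
    return(list(events = NULL, rates = NULL, mi = NULL))
  }
  events <- NULL
  for (wi in seq_along(trajs)) {
    traj <- trajs[[wi]]
    m <- modeValues(traj)
    pk <- detectExtrema(m[, 3])
    if (!nrow(pk)) next
    pk$worm <- wi
    pk$time_s <- frameTimes(traj)[pk$frame]
    pk$class <- vapply(pk$amplitude, classifyTurn, character(1))
    bounds <- lapply(pk$frame, function(a) turnBounds(m[, 3], m[, 4], a))
    pk$start <- vapply(bounds, function(b) if (is.null(b)) NA_integer_
                       else b[["start"]], numeric(1))
    pk$end <- vapply(bounds, function(b) if (is.null(b)) NA_integer_
                     else b[["end"]], numeric(1))
    pk$delta_theta <- vapply(seq_len(nrow(pk)), function(i) {
      if (is.na(pk$start[i])) return(NA_real_)
      tryCatch(as.numeric(orientationChange(traj, pk$frame[i], basis)),
               error = function(e) NA_real_)
    }, numeric(1))
    events <- rbind(events, pk)
  }
  duration <- max(vapply(trajs, function(x) length(x) / frameRate(x),
                         numeric(1)))
  ratesOut <- NULL
  if (rates && !is.null(events) && duration > 800)
    ratesOut <- turnRates(events, duration)
  miOut <- NULL
  if (mi && !is.null(events)) {
    tA <- events$time_s[events$class == "omega"]
    tB <- events$time_s[events$class == "delta"]
    if (length(tA) && length(tB))
      miOut <- eventMutualInfo(tA, tB, duration)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(events))
      utils::write.csv(events, file.path(outDir, "events.csv"),
                       row.names = FALSE)
    if (!is.null(ratesOut))
      utils::write.csv(ratesOut, file.path(outDir, "rates.csv"),
                       row.names = FALSE)
    if (!is.null(miOut))
      jsonlite::write_json(miOut, file.path(outDir, "mi.json"),
                           dataframe = "rows", auto_unbox = TRUE)
  }
  list(events = events, rates = ratesOut, mi = miOut)
}
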