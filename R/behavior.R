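# Turn and escape analytics on mode trajectories: peak detection and
# classification, turn bounds, reorientation through coils, escape
# segmentation, rate adaptation, event mutual information, and tracking
# validation metrics.

#' Detect large-amplitude extrema in the turning mode a3
#'
#' Local maxima of a3 and of -a3 (a point strictly greater than its
#' immediate neighbours), with topographic prominence computed per peak;
#' extrema below the prominence floor or the amplitude floor are dropped,
#' and shoulder sub-peaks are discarded: when two same-sign peaks belong to
#' one continuous excursion (the series never returns below the straight
#' level of 3 between them), only the higher survives.
#'
#' @param a3 numeric series of third-mode amplitudes (ventral positive).
#' @param minProminence prominence floor (default 0.5).
#' @param minAmp amplitude floor: only |a3| >= minAmp extrema are kept
#'   (default 10, the large-amplitude turn threshold).
#' @return data.frame(frame, amplitude, prominence, windowLo, windowHi);
#'   amplitude is the signed a3 value at the extremum.
#' @export
detectExtrema <- function(a3, minProminence = 0.5, minAmp = 10) {
  if (length(a3) < 3) stop("series must contain at least 3 points")
  up <- peaksWithProminence(a3)
  dn <- peaksWithProminence(-a3)
  if (nrow(dn)) dn$height <- -dn$height
  up$sign <- rep(1, nrow(up))
  dn$sign <- rep(-1, nrow(dn))
  pk <- rbind(up, dn)
  if (!nrow(pk))
    return(data.frame(frame = integer(0), amplitude = numeric(0),
                      prominence = numeric(0), windowLo = integer(0),
                      windowHi = integer(0)))
  pk <- pk[pk$prominence >= minProminence & abs(pk$height) >= minAmp, ,
           drop = FALSE]
  # shoulder discard: same-sign peaks on one continuous excursion (never
  # dropping below the straight level of 3 between them) are one turn;
  # keep the higher
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    for (j in seq_len(nrow(pk))) {
      if (i == j || pk$sign[i] != pk$sign[j] || !keep[j]) next
      if (abs(pk$height[i]) > abs(pk$height[j])) next
      if (abs(pk$height[i]) == abs(pk$height[j]) && i < j) next
      between <- seq(min(pk$frame[i], pk$frame[j]),
                     max(pk$frame[i], pk$frame[j]))
      if (min(pk$sign[i] * a3[between]) > 3) keep[i] <- FALSE
    }
  }
  pk <- pk[keep, , drop = FALSE]
  pk <- pk[order(pk$frame), , drop = FALSE]
  data.frame(frame = pk$frame, amplitude = pk$height,
             prominence = pk$prominence, windowLo = pk$lo,
             windowHi = pk$hi, row.names = NULL)
}

# local maxima with MATLAB-style topographic prominence: extend left/right
# until a strictly higher value (or the series edge); the prominence is the
# height above the higher of the two interval minima
peaksWithProminence <- function(x) {
  n <- length(x)
  i <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  if (!length(i))
    return(data.frame(frame = integer(0), height = numeric(0),
                      prominence = numeric(0), lo = integer(0),
                      hi = integer(0)))
  res <- lapply(i, function(p) {
    h <- x[p]
    lo <- p
    while (lo > 1 && x[lo - 1] <= h) lo <- lo - 1
    hi <- p
    while (hi < n && x[hi + 1] <= h) hi <- hi + 1
    base <- max(min(x[lo:p]), min(x[p:hi]))
    data.frame(frame = p, height = h, prominence = h - base, lo = lo,
               hi = hi)
  })
  do.call(rbind, res)
}

#' Classify a large-amplitude a3 extremum
#'
#' Ventral amplitudes in [10, 20] are omega turns; amplitudes above 20 are
#' delta turns; negative (dorsal) amplitudes are never omega or delta —
#' they form the dorsal mirror population used for background subtraction.
#'
#' @param amplitude signed a3 amplitude of a detected extremum.
#' @return one of "omega", "delta", "shallow_dorsal".
#' @export
classifyTurn <- function(amplitude) {
  if (abs(amplitude) < 10)
    stop("not a large-amplitude peak: |a3| = ", format(amplitude), " < 10")
  if (amplitude > 20) return("delta")
  if (amplitude >= 10) return("omega")
  "shallow_dorsal"
}

#' Turn bounds around an a3 apex
#'
#' The end of a turn is the first frame — after the first sign change of a4
#' following the apex — at which a3 < 3 (a relatively straight shape whose
#' overall orientation is interpretable); the start applies the mirrored
#' criterion scanning backward. Returns NULL (\code{not_found}) when either
#' side fails, in which case callers exclude the trial.
#'
#' @param a3,a4 numeric mode series.
#' @param apex frame index of the detected peak.
#' @return integer(2) c(start, end) frames, or NULL.
#' @export
turnBounds <- function(a3, a4, apex) {
  n <- length(a3)
  zc <- function(idx) {
    # first index in idx at which a4 changes sign w.r.t. the next step
    for (t in idx) {
      t2 <- t + sign(idx[length(idx)] - idx[1] + 0.5)
      if (t2 < 1 || t2 > n) break
      if (a4[t] == 0 || a4[t] * a4[t2] < 0) return(t)
    }
    NA_integer_
  }
  endStart <- zc(seq(apex, n - 1))
  end <- NA_integer_
  if (!is.na(endStart)) {
    after <- seq(endStart, n)
    hit <- after[a3[after] < 3]
    if (length(hit)) end <- hit[1]
  }
  begStart <- if (apex >= 2) zc(seq(apex, 2)) else NA_integer_
  start <- NA_integer_
  if (!is.na(begStart)) {
    before <- seq(begStart, 1)
    hit <- before[a3[before] < 3]
    if (length(hit)) start <- hit[1]
  }
  if (is.na(start) || is.na(end)) return(NULL)
  c(start = start, end = end)
}

#' Straight-shape mask of a trajectory
#'
#' A frame is "straight" iff the reconstructed tangent-angle profile has a
#' maximum local curvature below the threshold: max |theta(k+10) -
#' theta(k)| < threshold. Only for such flat shapes does the overall
#' orientation have its intuitive meaning.
#'
#' @param traj a \code{ModeTrajectory}.
#' @param basis an \code{EigenwormBasis}.
#' @param threshold rad over a 10-index separation (default 0.8).
#' @param separation index gap.
#' @return logical per frame.
#' @export
straightMask <- function(traj, basis, threshold = 0.8, separation = 10L) {
  m <- modeValues(traj)
  vapply(seq_len(nrow(m)), function(j) {
    th <- reconstructProfile(c(m[j, ], 0), basis)
    idx <- seq_len(length(th) - separation)
    max(abs(th[idx + separation] - th[idx])) < threshold
  }, logical(1))
}

#' Reorientation across a turn
#'
#' Compares the unwrapped overall orientation between two reference frames:
#' the last straight frame before the apex and the first straight frame
#' after it. Because the orientation is followed continuously through the
#' coil, over-turning reorientations (e.g. -1.3 pi) are distinguished from
#' their aliases (+0.7 pi).
#'
#' @param traj a \code{ModeTrajectory} (orientation unwrapped in time).
#' @param apex apex frame of the turn.
#' @param basis an \code{EigenwormBasis}.
#' @param threshold straightness threshold, rad.
#' @return signed reorientation, radians, with attributes "before" and
#'   "after" (the reference frames).
#' @export
orientationChange <- function(traj, apex, basis, threshold = 0.8) {
  straight <- straightMask(traj, basis, threshold)
  before <- which(straight & seq_along(straight) < apex)
  after <- which(straight & seq_along(straight) > apex)
  if (!length(before) || !length(after))
    stop("no straight reference frame on one side of the apex")
  b <- before[length(before)]
  a <- after[1]
  o <- orientationValues(traj)
  structure(o[a] - o[b], before = b, after = a)
}

#' Segment an escape response
#'
#' Finds the omega-turn apex as the largest a3 peak in (stimTime, 29 s],
#' brackets the turn with \code{\link{turnBounds}}, defines the reversal as
#' the first post-stimulus frame with negative body-wave phase velocity
#' (discrete derivative smoothed over 3 frames) through the turn start, and
#' the post-turn segment from the turn end to the record end. Trials with
#' no large post-stimulus peak or unresolvable bounds are excluded (with a
#' reason), mirroring the exclusion rule of the original analysis.
#'
#' @param traj a \code{ModeTrajectory} spanning the recording.
#' @param basis an \code{EigenwormBasis}.
#' @param stimTime stimulus time, s (default 10).
#' @param recordEnd end of the recording, s (default 30).
#' @param apexWindowEnd end of the apex search window, s (default 29).
#' @return list(excluded, reason, stimFrame, apex, reversal, turn, post,
#'   deltaTheta) — segment index ranges and per-segment reorientations
#'   (reversal, turn, post, total).
#' @export
segmentEscape <- function(traj, basis, stimTime = 10, recordEnd = 30,
                          apexWindowEnd = 29) {
  fr <- frameRate(traj)
  t <- frameTimes(traj)
  m <- modeValues(traj)
  n <- nrow(m)
  excluded <- function(reason)
    list(excluded = TRUE, reason = reason)
  pk <- detectExtrema(m[, 3], minAmp = 10)
  pk <- pk[t[pk$frame] > stimTime & t[pk$frame] <= apexWindowEnd &
             pk$amplitude > 0, , drop = FALSE]
  if (!nrow(pk)) return(excluded("no large-amplitude a3 peak after stimulus"))
  apex <- pk$frame[which.max(pk$amplitude)]
  bounds <- turnBounds(m[, 3], m[, 4], apex)
  if (is.null(bounds)) return(excluded("turn bounds not found"))
  phase <- bodyPhase(traj)
  dphi <- diff(phase)
  dphi <- stats::filter(dphi, rep(1 / 3, 3), sides = 2)
  dphi[is.na(dphi)] <- 0
  stimFrame <- which(t >= stimTime)[1]
  negAfter <- which(dphi < 0 & seq_along(dphi) >= stimFrame)
  if (!length(negAfter)) return(excluded("no reversal after stimulus"))
  revStart <- negAfter[1]
  if (revStart >= bounds["start"])
    revStart <- stimFrame  # reversal onset merged into turn onset
  straight <- straightMask(traj, basis)
  before <- which(straight & seq_len(n) < apex & seq_len(n) >= revStart)
  after <- which(straight & seq_len(n) > apex)
  if (!length(before) || !length(after))
    return(excluded("no straight reference frame around the turn"))
  s1 <- before[length(before)]
  s2 <- after[1]
  o <- orientationValues(traj)
  dth <- c(reversal = o[s1] - o[revStart],
           turn = o[s2] - o[s1],
           post = o[n] - o[s2])
  dth <- c(dth, total = unname(o[n] - o[revStart]))
  list(excluded = FALSE, reason = NA_character_,
       stimFrame = stimFrame, apex = apex,
       reversal = c(start = revStart, end = unname(bounds["start"]) - 1L),
       turn = c(start = unname(bounds["start"]), end = unname(bounds["end"])),
       post = c(start = unname(bounds["end"]) + 1L, end = n),
       deltaTheta = dth)
}

#' Sliding-window turn rates with dorsal background subtraction
#'
#' Counts per window: omega = N(amplitude in [10, 20]) - N(amplitude in
#' [-20, -10]); delta = N(amplitude > 20) - N(amplitude < -20) — the
#' dorsal tail of the symmetric shallow-turn distribution estimates the
#' ventral contamination. Rates are per minute, averaged across worms, in
#' 10-minute windows shifted by 5 minutes with the first 200 s discarded;
#' errors are bootstrap SDs over worms.
#'
#' @param events data.frame with columns \code{worm}, \code{time_s},
#'   \code{amplitude} (all detected |a3| >= 10 extrema).
#' @param duration recording length, s.
#' @param window,step,discard window geometry, s.
#' @param nBoot bootstrap resamples over worms.
#' @return data.frame(window_center_s, omega_rate_per_min,
#'   delta_rate_per_min, omega_se, delta_se, n_worms); attribute
#'   \code{"totals"} holds total counts with bootstrap errors.
#' @export
turnRates <- function(events, duration, window = 600, step = 300,
                      discard = 200, nBoot = 500) {
  if (duration <= discard + window)
    stop("recording shorter than discard + window")
  worms <- sort(unique(events$worm))
  nw <- length(worms)
  starts <- seq(discard, duration - window, by = step)
  if (nw == 0) {
    out <- data.frame(window_center_s = starts + window / 2,
                      omega_rate_per_min = 0, delta_rate_per_min = 0,
                      omega_se = NA_real_, delta_se = NA_real_, n_worms = 0)
    attr(out, "totals") <- rbind(omega = c(total = 0, se = NA),
                                 delta = c(total = 0, se = NA))
    return(out)
  }
  countsFor <- function(ev) {
    om <- sapply(starts, function(s0) {
      w <- ev$time_s >= s0 & ev$time_s < s0 + window
      sum(w & ev$amplitude >= 10 & ev$amplitude <= 20) -
        sum(w & ev$amplitude <= -10 & ev$amplitude >= -20)
    })
    de <- sapply(starts, function(s0) {
      w <- ev$time_s >= s0 & ev$time_s < s0 + window
      sum(w & ev$amplitude > 20) - sum(w & ev$amplitude < -20)
    })
    cbind(om, de)
  }
  perWorm <- lapply(worms, function(w) countsFor(events[events$worm == w, ]))
  om <- sapply(perWorm, function(x) x[, 1])
  de <- sapply(perWorm, function(x) x[, 2])
  om <- matrix(om, nrow = length(starts))
  de <- matrix(de, nrow = length(starts))
  toRate <- function(x) x / (window / 60)
  bootSD <- function(mat) {
    if (nw < 2) return(rep(NA_real_, nrow(mat)))
    bs <- replicate(nBoot, {
      idx <- sample(nw, nw, replace = TRUE)
      rowMeans(mat[, idx, drop = FALSE])
    })
    apply(bs, 1, stats::sd)
  }
  keep <- events$time_s >= discard
  netTotal <- function(posSel, negSel) {
    perw <- vapply(worms, function(w)
      sum(posSel & events$worm == w & keep) -
        sum(negSel & events$worm == w & keep), numeric(1))
    bs <- replicate(nBoot, sum(perw[sample(nw, nw, replace = TRUE)]))
    c(total = sum(perw), se = stats::sd(bs))
  }
  totals <- rbind(
    omega = netTotal(events$amplitude >= 10 & events$amplitude <= 20,
                     events$amplitude <= -10 & events$amplitude >= -20),
    delta = netTotal(events$amplitude > 20, events$amplitude < -20))
  out <- data.frame(window_center_s = starts + window / 2,
                    omega_rate_per_min = toRate(rowMeans(om)),
                    delta_rate_per_min = toRate(rowMeans(de)),
                    omega_se = toRate(bootSD(om)),
                    delta_se = toRate(bootSD(de)),
                    n_worms = nw)
  attr(out, "totals") <- totals
  out
}

#' Shifted mutual information between two event time series
#'
#' Event times are floored onto a grid of the given bin width to form
#' binary occupancy series; the plug-in mutual information (bits) between
#' the two series is computed at each relative shift, together with a
#' shuffle control (MI after random permutation of one series' bins, which
#' vanishes in the infinite-data limit) and a bootstrap-over-bins
#' finite-sampling error.
#'
#' @param timesA,timesB event times, s.
#' @param duration series length, s.
#' @param binWidths bin widths, s (default c(2, 4, 10, 20)).
#' @param maxShift largest |shift|, s (default 60); the shift grid is in
#'   steps of one bin.
#' @param nShuffles shuffle repetitions.
#' @param nBoot bootstrap resamples over bins.
#' @return data.frame(bin_width, shift_s, mi_bits, shuffle_mean,
#'   shuffle_sd, err).
#' @export
eventMutualInfo <- function(timesA, timesB, duration,
                            binWidths = c(2, 4, 10, 20), maxShift = 60,
                            nShuffles = 20, nBoot = 100) {
  if (!length(timesA) || !length(timesB))
    stop("both event series must be non-empty")
  out <- NULL
  for (w in binWidths) {
    nb <- ceiling(duration / w)
    occ <- function(tt) {
      v <- integer(nb)
      v[pmin(nb, floor(tt / w) + 1)] <- 1L
      v
    }
    A <- occ(timesA)
    B <- occ(timesB)
    shiftsBins <- unique(round(seq(-maxShift, maxShift, by = w) / w))
    for (s in shiftsBins) {
      ov <- overlapIdx(nb, s)
      a <- A[ov$ia]
      b <- B[ov$ib]
      mi <- binaryMI(a, b)
      sh <- replicate(nShuffles, binaryMI(sample(a), b))
      bs <- replicate(nBoot, {
        idx <- sample(length(a), replace = TRUE)
        binaryMI(a[idx], b[idx])
      })
      out <- rbind(out, data.frame(bin_width = w, shift_s = s * w,
                                   mi_bits = mi, shuffle_mean = mean(sh),
                                   shuffle_sd = stats::sd(sh),
                                   err = stats::sd(bs)))
    }
  }
  out
}

overlapIdx <- function(nb, shift) {
  # indices so that A[ia] aligns with B shifted by `shift` bins
  ia <- seq_len(nb)
  ib <- ia + shift
  ok <- ib >= 1 & ib <= nb
  list(ia = ia[ok], ib = ib[ok])
}

#' Plug-in mutual information of two binary series (bits)
#' @param a,b binary vectors of equal length.
#' @export
binaryMI <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (va in 0:1) for (vb in 0:1) {
    p <- sum(a == va & b == vb) / n
    if (p > 0) {
      pa <- sum(a == va) / n
      pb <- sum(b == vb) / n
      mi <- mi + p * log2(p / (pa * pb))
    }
  }
  mi
}

#' Time-normalized average turn profile
#'
#' Resamples the a1..a4 time courses of each turn onto a fixed 101-point
#' [0, 1] normalized-time grid and returns the pointwise mean and SD.
#'
#' @param trajList list of \code{ModeTrajectory} (one per event, or a
#'   single trajectory shared by all events).
#' @param events data.frame with columns \code{start}, \code{end} (frames)
#'   and optionally \code{traj} (index into trajList).
#' @param nGrid grid resolution (default 101).
#' @return list(grid, mean = nGrid x 4, sd = nGrid x 4, n).
#' @export
averageTurnProfile <- function(trajList, events, nGrid = 101L) {
  if (is(trajList, "ModeTrajectory")) trajList <- list(trajList)
  if (nrow(events) < 2) stop("need at least 2 events with valid bounds")
  grid <- seq(0, 1, length.out = nGrid)
  curves <- array(NA_real_, c(nGrid, 4, nrow(events)))
  for (e in seq_len(nrow(events))) {
    ti <- if ("traj" %in% names(events)) events$traj[e] else 1L
    m <- modeValues(trajList[[ti]])
    fr <- seq(events$start[e], events$end[e])
    x <- (fr - fr[1]) / (fr[length(fr)] - fr[1])
    for (c in 1:4)
      curves[, c, e] <- stats::approx(x, m[fr, c], xout = grid)$y
  }
  list(grid = grid,
       mean = apply(curves, c(1, 2), mean),
       sd = apply(curves, c(1, 2), stats::sd),
       n = nrow(events))
}

#' Tracking-error summaries between two posture series
#'
#' Per-frame Euclidean distances between 100-vector tangent-angle profiles
#' (delta-theta) and per-mode absolute differences, with median and 95th
#' percentile summaries — the validation metrics comparing the inverse
#' tracker against thinning or ground truth.
#'
#' @param a,b either N x 100 matrices of tangent-angle profiles, or
#'   \code{ModeTrajectory} objects (then \code{basis} is required to
#'   reconstruct profiles).
#' @param basis an \code{EigenwormBasis} (for trajectory input).
#' @return list(deltaTheta, perMode (N x 5 or NULL), summary).
#' @export
trackingErrors <- function(a, b, basis = NULL) {
  perMode <- NULL
  if (is(a, "ModeTrajectory")) {
    if (length(a) != length(b)) stop("trajectories have different lengths")
    perMode <- abs(modeValues(a) - modeValues(b))
    if (!is.null(basis)) {
      pa <- cbind(modeValues(a), orientationValues(a))
      pb <- cbind(modeValues(b), orientationValues(b))
      ta <- t(apply(pa, 1, reconstructProfile, basis = basis))
      tb <- t(apply(pb, 1, reconstructProfile, basis = basis))
      dth <- sqrt(rowSums((ta - tb)^2))
    } else dth <- NULL
  } else {
    a <- as.matrix(a)
    b <- as.matrix(b)
    if (!all(dim(a) == dim(b))) stop("profile matrices differ in shape")
    dth <- sqrt(rowSums((a - b)^2))
  }
  summ <- function(x) c(median = stats::median(x),
                        p95 = unname(stats::quantile(x, 0.95)))
  list(deltaTheta = dth, perMode = perMode,
       summary = list(
         deltaTheta = if (!is.null(dth)) summ(dth),
         perMode = if (!is.null(perMode)) apply(perMode, 2, summ)))
}

#' Dimensionality-reduction discrepancy of tangent-angle profiles
#'
#' Per-frame norm of the component of the mean-subtracted profile outside
#' the span of the basis — the information lost by keeping only the
#' postural eigenmodes. A comparator for tracking-error distributions.
#'
#' @param profiles N x 100 matrix of tangent-angle profiles.
#' @param basis an \code{EigenwormBasis}.
#' @export
dimReductionError <- function(profiles, basis) {
  v <- basisVectors(basis)
  ctr <- profiles - rowMeans(profiles)
  resid <- ctr - (ctr %*% t(v)) %*% v
  sqrt(rowSums(resid^2))
}

#' Consecutive-frame posture distance
#'
#' Euclidean distance between tangent-angle profiles of consecutive frames
#' — the finite-time-resolution comparator for tracking errors.
#' @inheritParams dimReductionError
#' @export
consecutiveDistance <- function(profiles) {
  sqrt(rowSums(diff(profiles)^2))
}
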