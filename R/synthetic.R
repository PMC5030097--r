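# Synthetic ground truth: worm-like posture ensembles, mode-space
# trajectories (crawl, escape, foraging), and rendered noisy movies.

#' Generator parameters
#'
#' Defaults emulate the recording conditions the analytics expect: 16 Hz
#' framing; a crawling body wave of amplitude 7 (giving ~1 rad tangent-angle
#' undulations) at 0.5 Hz; unimodal raised-cosine a3 pulses (peak ~15 for
#' omega, ~23 for delta, durations ~6-7 s) and bimodal a4 head-swing
#' pulses; and an orientation-curvature coupling calibrated so a peak-15,
#' 7-s ventral pulse reorients by about -0.9 pi.
#'
#' @param frameRate Hz.
#' @param waveAmp body-wave amplitude A in the (a1, a2) plane.
#' @param waveOmega body-wave angular speed, rad/s.
#' @param jitterSD mode jitter SD (baseline noise on all modes).
#' @param omegaAmp,deltaAmp mean a3 pulse peaks for the two turn classes.
#' @param omegaDur,deltaDur pulse durations, s.
#' @param headSwingAmp,headSwingDur a4 bimodal pulse amplitude / duration.
#' @param thetaCoupling kappa in d<theta>/dt = -kappa * a3 * sign(dphi/dt),
#'   rad/s per a3 unit.
#' @param pixelNoise pixel-flip probability for rendered movies.
#' @param seed RNG seed; every generator output is bit-reproducible given
#'   the seed.
#' @return list of class \code{coil_generator_params}.
#' @export
generatorParams <- function(frameRate = 16, waveAmp = 4.5, waveOmega = pi,
                            jitterSD = 0.2, omegaAmp = 15, deltaAmp = 23,
                            omegaDur = 7, deltaDur = 6, headSwingAmp = 6,
                            headSwingDur = 2,
                            thetaCoupling = 0.9 * pi / (15 * 7 / 2),
                            pixelNoise = 0.01, seed = 1L) {
  structure(as.list(environment()), class = "coil_generator_params")
}

# Fixed worm-like shape components on 100 arc-length points: a quadrature
# pair of ~2-wavelength travelling-wave shapes, an overall-bend (turning)
# shape, and symmetric/antisymmetric end-bump shapes. All unit-norm,
# mutually orthogonal, and individually symmetric or antisymmetric under
# body reversal.
shapeComponents <- function() {
  s <- (0:99) / 99
  unit <- function(v) v / sqrt(sum(v^2))
  ctr <- function(v) v - mean(v)
  # 1.5 body wavelengths: the sine is reversal-symmetric, the cosine
  # antisymmetric, and both are nearly orthogonal to the overall-bend ramp,
  # keeping the bend mode smooth (low local curvature per unit amplitude)
  uc <- unit(ctr(cos(3 * pi * s)))
  us <- unit(ctr(sin(3 * pi * s)))
  gs <- function(v, basis) {
    for (b in basis) v <- v - sum(v * b) * b
    unit(v)
  }
  u3 <- gs(ctr(s - 0.5), list(uc, us))
  gh <- exp(-(s - 0.08)^2 / (2 * 0.11^2))
  gt <- rev(gh)
  u4 <- gs(ctr(gh + gt), list(uc, us, u3))
  u5 <- gs(ctr(gh - gt), list(uc, us, u3, u4))
  list(uc = uc, us = us, u3 = u3, u4 = u4, u5 = u5, s = s)
}

#' Synthetic worm-posture ensemble
#'
#' Mean-subtracted tangent-angle profiles: superposed travelling body waves
#' of 1.8-2.2 body wavelengths (quadrature pair with per-profile wavelength
#' jitter), an overall-bend component with occasional deep-turn excursions,
#' localized end-curvature bumps, and white angle noise. The crawl+turn
#' ensemble on which the default eigenworm basis is computed.
#'
#' @param n number of profiles.
#' @return n x 100 matrix, each row mean-subtracted.
#' @export
syntheticPostureEnsemble <- function(n = 5000L) {
  comp <- shapeComponents()
  s <- comp$s
  unit <- function(v) v / sqrt(sum(v^2))
  others <- list(comp$u3, comp$u4, comp$u5)
  gs <- function(v) {
    v <- v - mean(v)
    for (b in others) v <- v - sum(v * b) * b
    unit(v)
  }
  out <- matrix(0, n, 100)
  for (i in seq_len(n)) {
    nw <- 1.5 + 0.06 * stats::rnorm(1)
    # wave shapes are kept orthogonal to the bend/bump channels so that
    # wavelength jitter does not alias into them
    cc <- gs(cos(2 * pi * nw * s))
    ss <- gs(sin(2 * pi * nw * s))
    w <- stats::rnorm(2, 0, 6)
    c3 <- if (stats::runif(1) < 0.06)
      sample(c(-1, 1), 1) * stats::rnorm(1, 19, 3) else stats::rnorm(1, 0, 3)
    c4 <- stats::rnorm(1, 0, 3)
    c5 <- stats::rnorm(1, 0, 1.5)
    p <- w[1] * cc + w[2] * ss + c3 * comp$u3 + c4 * comp$u4 +
      c5 * comp$u5 + stats::rnorm(100, 0, 0.12)
    out[i, ] <- p - mean(p)
  }
  out
}

.basisCache <- new.env(parent = emptyenv())

#' Default eigenworm basis
#'
#' PCA of 5,000 synthetic postures (fixed seed), post-processed for exact
#' head/tail-reversal symmetry: each eigenworm is projected onto its
#' dominant symmetric or antisymmetric part, the set re-orthonormalized,
#' re-ordered by captured ensemble variance, and sign-fixed (largest entry
#' positive, so a3 > 0 is a ventral bend). Reversal symmetry of the basis
#' makes the head/tail swap an exact involution on posture coordinates.
#'
#' @param seed RNG seed for the generating ensemble.
#' @param n ensemble size.
#' @return an \code{\linkS4class{EigenwormBasis}}.
#' @export
defaultBasis <- function(seed = 2016L, n = 5000L) {
  key <- paste0(seed, "_", n)
  if (!is.null(.basisCache[[key]])) return(.basisCache[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  profiles <- syntheticPostureEnsemble(n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  # eigendecompose the reversal-symmetrized covariance (C + PCP)/2, whose
  # eigenvectors are inherently symmetric or antisymmetric under body
  # reversal; then snap each to its dominant part for exact symmetry
  C <- cov(profiles)
  Cs <- (C + C[100:1, 100:1]) / 2
  e <- eigen(Cs, symmetric = TRUE)
  sym <- t(e$vectors[, 1:5, drop = FALSE])
  for (i in 1:5) {
    v <- sym[i, ]
    a <- (v + rev(v)) / 2
    b <- (v - rev(v)) / 2
    w <- if (sum(a^2) >= sum(b^2)) a else b
    sym[i, ] <- w / sqrt(sum(w^2))
  }
  vars <- apply(profiles %*% t(sym), 2, stats::var)
  ord <- order(vars, decreasing = TRUE)
  sym <- fixEigenSign(sym[ord, , drop = FALSE])
  basis <- new("EigenwormBasis", vectors = sym, variances = vars[ord])
  .basisCache[[key]] <- basis
  basis
}

# raised-cosine pulse of unit peak: support |t - center| < dur/2
rcPulse <- function(t, center, dur) {
  u <- (t - center) / dur
  ifelse(abs(u) < 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

# bimodal (one positive, one negative lobe) head-swing pulse, unit peak
hsPulse <- function(t, center, dur) {
  u <- (t - center) / dur
  ifelse(abs(u) < 0.5, sin(2 * pi * u), 0)
}

#' Generate a forward-crawl trajectory
#'
#' Phase-locked sinusoids in (a1, a2) — a circular trajectory of radius
#' \code{waveAmp} traversed so that the body-wave phase increases — with
#' mode jitter on a3..a5 and an orientation drifting with the a3 baseline.
#'
#' @param params \code{\link{generatorParams}}.
#' @param duration s.
#' @param phase0 initial body-wave phase.
#' @param seed optional override of \code{params$seed}.
#' @return a \code{ModeTrajectory} (provenance "synthetic").
#' @export
generateCrawl <- function(params = generatorParams(), duration = 10,
                          phase0 = 0, seed = params$seed) {
  set.seed(seed)
  fr <- params$frameRate
  t <- seq(0, duration - 1 / fr, by = 1 / fr)
  ph <- params$waveOmega * t + phase0
  A <- params$waveAmp
  jit <- function() stats::rnorm(length(t), 0, params$jitterSD)
  m <- cbind(a1 = A * cos(ph) + jit(), a2 = -A * sin(ph) + jit(),
             a3 = jit(), a4 = jit(), a5 = jit())
  orient <- cumsum(-params$thetaCoupling * m[, 3] / fr)
  newModeTrajectory(m, orient, fr,
                    provenance = rep("synthetic", length(t)))
}

#' Generate a synthetic escape response
#'
#' 10 s of forward crawl; at the stimulus the body-wave phase reverses
#' (reversal); a bimodal a4 head swing marks the reversal end; a unimodal
#' raised-cosine a3 pulse (peak \code{omegaAmp}) executes the omega turn
#' while the phase resumes increasing; forward crawl continues to the
#' record end. The overall orientation integrates an imposed rotation
#' profile (reversal / turn / post contributions summing to
#' \code{dthetaTotal}); the turn's share follows the a3 pulse shape.
#'
#' Ground truth (attribute \code{"truth"}): stimulus time/frame, segment
#' boundaries — with the turn start/end defined by the a3 = 3 crossings of
#' the noiseless pulse, the same straightness rule the detector uses —
#' pulse support, apex, and per-segment imposed rotations.
#'
#' @param params \code{\link{generatorParams}}.
#' @param duration recording length, s.
#' @param stimTime stimulus time, s.
#' @param reversalDur reversal duration, s.
#' @param dthetaSegments imposed rotation per segment (reversal, turn,
#'   post), rad; defaults mirror the escape phenomenology and sum to
#'   -0.9 pi.
#' @param seed optional override.
#' @return a \code{ModeTrajectory} with attribute \code{"truth"}.
#' @export
generateEscape <- function(params = generatorParams(), duration = 30,
                           stimTime = 10, reversalDur = 2.5,
                           dthetaSegments = c(reversal = 0.13 * pi,
                                              turn = -0.91 * pi,
                                              post = -0.12 * pi),
                           seed = params$seed) {
  set.seed(seed)
  fr <- params$frameRate
  t <- seq(0, duration - 1 / fr, by = 1 / fr)
  n <- length(t)
  A <- params$waveAmp
  w <- params$waveOmega
  tHS <- stimTime + reversalDur          # head swing / turn onset
  apex <- tHS + params$omegaDur / 2
  # body-wave phase: forward, reversed during [stim, tHS), forward again
  dphi <- ifelse(t >= stimTime & t < tHS, -w, w)
  phi <- cumsum(dphi) / fr
  jit <- function() stats::rnorm(n, 0, params$jitterSD)
  a3pulse <- params$omegaAmp * rcPulse(t, apex, params$omegaDur)
  a4pulse <- params$headSwingAmp * hsPulse(t, tHS, params$headSwingDur)
  m <- cbind(a1 = A * cos(phi) + jit(), a2 = -A * sin(phi) + jit(),
             a3 = a3pulse + jit(), a4 = a4pulse + jit(), a5 = jit())
  # imposed rotation profile
  dth <- numeric(n)
  revIdx <- t >= stimTime & t < tHS
  postIdx <- t >= tHS + params$omegaDur
  dth[revIdx] <- dthetaSegments[["reversal"]] / sum(revIdx)
  dth[postIdx] <- dthetaSegments[["post"]] / sum(postIdx)
  pulseWeight <- a3pulse / sum(a3pulse)
  dth <- dth + dthetaSegments[["turn"]] * pulseWeight
  orient <- cumsum(dth)
  traj <- newModeTrajectory(m, orient, fr, rep("synthetic", n))
  # a3 = 3 crossings of the clean pulse (the straightness boundary rule)
  half <- acos(2 * 3 / params$omegaAmp - 1) * params$omegaDur / (2 * pi)
  attr(traj, "truth") <- list(
    stimTime = stimTime, stimFrame = which(t >= stimTime)[1],
    reversalStart = stimTime, turnStart = apex - half,
    turnEnd = apex + half, apexTime = apex,
    pulseSupport = c(tHS, tHS + params$omegaDur),
    dthetaSegments = dthetaSegments,
    dthetaTotal = sum(dthetaSegments))
  traj
}

#' Generate synthetic foraging recordings with omega/delta events
#'
#' Per worm: independent inhomogeneous Poisson streams of omega and delta
#' turns with rate \eqn{r(t) = r_\infty + (r_0 - r_\infty) e^{-t/\tau}}
#' (the turn-frequency adaptation law), ventral-only deep events —
#' omega peaks ~ N(omegaAmp, 1) clipped to [10, 20], delta ~ N(deltaAmp,
#' 1) clipped to (20, 30] — plus an optional symmetric shallow-deep
#' background in +/-[10, 14] and sub-threshold shallow wiggles. Events
#' closer than one pulse duration are re-drawn. The crawl wave runs
#' throughout; each deep event carries an a4 head swing and its share of
#' orientation change.
#'
#' @param params \code{\link{generatorParams}}.
#' @param duration s (default 2100 = 35 min).
#' @param nWorms number of independent worms.
#' @param r0,rInf initial and asymptotic deep-turn rates per class,
#'   events/min.
#' @param tau adaptation time constant, s.
#' @param deepBackgroundRate symmetric +/-[10, 14] contamination rate,
#'   events/min each sign (0 disables).
#' @param shallowRate sub-threshold (|a3| < 10) background rate,
#'   events/min each sign.
#' @param seed optional override; worm w uses seed + w.
#' @return list with \code{worms} (list of \code{ModeTrajectory}) and
#'   \code{events} (ground-truth data.frame: worm, time_s, class,
#'   amplitude, start_s, end_s).
#' @export
generateForaging <- function(params = generatorParams(), duration = 2100,
                             nWorms = 12L, r0 = 0.6, rInf = 0.15,
                             tau = 600, deepBackgroundRate = 0.1,
                             shallowRate = 1.0, seed = params$seed) {
  worms <- vector("list", nWorms)
  events <- NULL
  for (wi in seq_len(nWorms)) {
    set.seed(seed + wi)
    g <- foragingWorm(params, duration, r0, rInf, tau,
                      deepBackgroundRate, shallowRate, wi)
    worms[[wi]] <- g$traj
    events <- rbind(events, g$events)
  }
  list(worms = worms, events = events)
}

# inhomogeneous Poisson times by thinning; exponential-decay rate in 1/min
poissonTimes <- function(duration, r0, rInf, tau) {
  if (r0 <= 0 && rInf <= 0) return(numeric(0))
  lmax <- max(r0, rInf) / 60
  tt <- c()
  t <- 0
  repeat {
    t <- t - log(stats::runif(1)) / lmax
    if (t > duration) break
    r <- (rInf + (r0 - rInf) * exp(-t / tau)) / 60
    if (stats::runif(1) < r / lmax) tt <- c(tt, t)
  }
  tt
}

foragingWorm <- function(params, duration, r0, rInf, tau,
                         deepBackgroundRate, shallowRate, wormId) {
  fr <- params$frameRate
  t <- seq(0, duration - 1 / fr, by = 1 / fr)
  n <- length(t)
  drawClass <- function(rate0, rateInf, cls) {
    tt <- poissonTimes(duration, rate0, rateInf, tau)
    if (!length(tt)) return(NULL)
    data.frame(time_s = tt, class = cls)
  }
  ev <- rbind(drawClass(r0, rInf, "omega"), drawClass(r0, rInf, "delta"),
              drawClass(deepBackgroundRate, deepBackgroundRate, "bg_ventral"),
              drawClass(deepBackgroundRate, deepBackgroundRate, "bg_dorsal"))
  minSep <- max(params$omegaDur, params$deltaDur)
  if (!is.null(ev) && nrow(ev) > 1) {
    # enforce minimum separation: conflicting events are re-drawn from the
    # same inhomogeneous process so the adaptation profile is preserved
    rmax <- max(r0, rInf, deepBackgroundRate)
    redraw <- function() {
      repeat {
        tt <- stats::runif(1, minSep, duration - minSep)
        r <- rInf + (r0 - rInf) * exp(-tt / tau)
        if (stats::runif(1) < r / rmax) return(tt)
      }
    }
    ev <- ev[order(ev$time_s), ]
    for (pass in 1:50) {
      d <- diff(ev$time_s)
      bad <- which(d < minSep) + 1L
      if (!length(bad)) break
      ev$time_s[bad] <- vapply(bad, function(i) redraw(), numeric(1))
      ev <- ev[order(ev$time_s), ]
    }
    d <- diff(ev$time_s)
    ev <- ev[c(TRUE, d >= minSep), ]
  }
  amp <- function(cls) switch(cls,
    omega = min(20, max(10, stats::rnorm(1, params$omegaAmp, 1))),
    delta = min(30, max(20 + 1e-6, stats::rnorm(1, params$deltaAmp, 1))),
    bg_ventral = stats::runif(1, 10, 14),
    bg_dorsal = -stats::runif(1, 10, 14))
  dur <- function(cls)
    if (cls == "delta") params$deltaDur else params$omegaDur
  a3 <- stats::rnorm(n, 0, params$jitterSD)
  a4 <- stats::rnorm(n, 0, params$jitterSD)
  rows <- NULL
  if (!is.null(ev) && nrow(ev)) {
    ev$amplitude <- vapply(seq_len(nrow(ev)),
                           function(i) amp(ev$class[i]), numeric(1))
    ev$dur <- vapply(ev$class, dur, numeric(1))
    for (i in seq_len(nrow(ev))) {
      a3 <- a3 + ev$amplitude[i] * rcPulse(t, ev$time_s[i], ev$dur[i])
      a4 <- a4 + params$headSwingAmp * sign(ev$amplitude[i]) *
        hsPulse(t, ev$time_s[i] - ev$dur[i] / 2, params$headSwingDur)
    }
    half <- function(a, d) acos(pmin(1, 2 * 3 / abs(a) - 1)) * d / (2 * pi)
    h <- half(ev$amplitude, ev$dur)
    rows <- data.frame(worm = wormId, time_s = ev$time_s, class = ev$class,
                       amplitude = ev$amplitude,
                       start_s = ev$time_s - h, end_s = ev$time_s + h)
  }
  # sub-threshold shallow wiggles (never reach |a3| >= 10)
  sh <- poissonTimes(duration, shallowRate * 2, shallowRate * 2, tau = 1e9)
  for (ts in sh)
    a3 <- a3 + sample(c(-1, 1), 1) * stats::runif(1, 3, 8) *
      rcPulse(t, ts, 4)
  ph <- params$waveOmega * t + stats::runif(1, 0, 2 * pi)
  A <- params$waveAmp
  jit <- function() stats::rnorm(n, 0, params$jitterSD)
  m <- cbind(A * cos(ph) + jit(), -A * sin(ph) + jit(), a3, a4, jit())
  orient <- cumsum(-params$thetaCoupling * a3 / fr)
  traj <- newModeTrajectory(m, orient, fr, rep("synthetic", n))
  list(traj = traj, events = rows)
}

#' Render a trajectory into a noisy binary movie
#'
#' Renders every frame of a mode trajectory (centroid-centered on the
#' canvas), optionally flips each pixel with probability
#' \code{params$pixelNoise}, and returns the frames together with the
#' per-frame ground-truth coordinates.
#'
#' @param traj a \code{ModeTrajectory}.
#' @param basis an \code{EigenwormBasis}.
#' @param body a \code{WormBodyModel}.
#' @param params \code{\link{generatorParams}} (noise and seed).
#' @param canvas c(rows, cols).
#' @param seed optional override.
#' @return list(frames = list of logical matrices, truth = data.frame with
#'   frame, a1..a5, theta).
#' @export
renderMovie <- function(traj, basis, body = wormBodyModel(),
                        params = generatorParams(), canvas = c(160, 160),
                        seed = params$seed) {
  set.seed(seed)
  m <- modeValues(traj)
  o <- orientationValues(traj)
  frames <- vector("list", nrow(m))
  for (j in seq_len(nrow(m))) {
    img <- renderWorm(c(m[j, ], o[j]), basis, body, canvas)
    attr(img, "backbone") <- NULL
    if (params$pixelNoise > 0) {
      flip <- matrix(stats::runif(length(img)) < params$pixelNoise,
                     nrow(img))
      img <- xor(img, flip)
    }
    frames[[j]] <- img
  }
  truth <- data.frame(frame = seq_len(nrow(m)), m,
                      theta = o)
  names(truth) <- c("frame", paste0("a", 1:5), "theta")
  list(frames = frames, truth = truth)
}
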