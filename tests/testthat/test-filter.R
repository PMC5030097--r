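# Sequence filter: optimal path selection, gap interpolation, head/tail.

# build a FrameSolutionSet quickly from a coordinate matrix
fss <- function(frame, coords, errors) {
  if (is.null(dim(coords))) coords <- matrix(coords, 1)
  new("FrameSolutionSet", frame = as.integer(frame),
      coords = coords, errors = errors)
}

# exhaustive-enumeration oracle over all feasible choice vectors
enumPath <- function(sets, config, frameRate) {
  N <- length(sets)
  M <- vapply(sets, length, 1L)
  feasible <- function(p, q, span) {
    all(abs(q[1:5] - p[1:5]) <= config$vMax * span) &&
      min((q[6] - p[6]) %% (2 * pi), (p[6] - q[6]) %% (2 * pi)) <=
        config$orientationRateLimit / frameRate * span
  }
  best <- Inf
  bestB <- NULL
  grids <- lapply(M, function(m) 0:m)
  for (idx in seq_len(prod(M + 1)) - 1) {
    b <- integer(N)
    r <- idx
    for (j in 1:N) {
      b[j] <- r %% (M[j] + 1)
      r <- r %/% (M[j] + 1)
    }
    known <- which(b > 0)
    if (!length(known)) next
    gapruns <- c(known[1] - 1, diff(known) - 1, N - known[length(known)])
    if (any(gapruns > config$maxGap)) next
    cost <- sum(b == 0) * config$gapPenalty
    ok <- TRUE
    for (j in known) cost <- cost + candidateErrors(sets[[j]])[b[j]]
    if (length(known) > 1) {
      for (k in seq_len(length(known) - 1)) {
        j1 <- known[k]
        j2 <- known[k + 1]
        if (!feasible(candidates(sets[[j1]])[b[j1], ],
                      candidates(sets[[j2]])[b[j2], ], j2 - j1)) ok <- FALSE
      }
    }
    if (ok && cost < best) {
      best <- cost
      bestB <- b
    }
  }
  list(choices = bestB, totalError = best)
}

randomSets <- function(N, maxM, seed) {
  set.seed(seed)
  lapply(seq_len(N), function(j) {
    m <- sample(0:maxM, 1, prob = c(0.15, rep(1, maxM)))
    if (m == 0)
      return(fss(j, matrix(numeric(0), 0, 6), numeric(0)))
    coords <- cbind(matrix(rnorm(m * 5, 0, 2), m), runif(m, 0, 2 * pi))
    # random walk-ish continuity for some candidates
    fss(j, coords, runif(m, 0, 0.9))
  })
}

test_that("select_path matches exhaustive enumeration on small instances", {
  cfg <- filterConfig(vMax = rep(4, 5), orientationRateLimit = 16 * pi,
                      gapPenalty = 1, maxGap = 3)
  nAgree <- 0
  for (trial in 1:50) {
    sets <- randomSets(N = sample(3:6, 1), maxM = 3, seed = 600 + trial)
    oracle <- enumPath(sets, cfg, 16)
    if (!is.finite(oracle$totalError)) {
      expect_error(selectPath(sets, cfg, 16), "feasible")
      next
    }
    path <- selectPath(sets, cfg, 16)
    expect_equal(path$totalError, oracle$totalError, tolerance = 1e-12)
    nAgree <- nAgree + 1
  }
  expect_gt(nAgree, 30)
})

test_that("a single-candidate chain is selected as-is", {
  sets <- lapply(1:5, function(j)
    fss(j, c(0, 0, 0, 0, 0, 1 + 0.01 * j), 0.1))
  path <- selectPath(sets, filterConfig(), 16)
  expect_equal(path$choices, rep(1L, 5))
  expect_equal(path$totalError, 0.5, tolerance = 1e-12)
})

test_that("an orientation flip decoy is excluded by the rate limit", {
  base <- c(1, 0, 0, 0, 0, 1.0)
  sets <- lapply(1:5, function(j) {
    if (j == 3) {
      # decoy flipped by pi has lower error but violates continuity
      fss(j, rbind(base, base + c(0, 0, 0, 0, 0, pi)), c(0.5, 0.01))
    } else fss(j, base, 0.5)
  })
  path <- selectPath(sets, filterConfig(), 16)
  expect_equal(path$choices[3], 1L)
})

test_that("gap interpolation reproduces cubics and passes non-gaps through", {
  cfg <- filterConfig()
  # exact cubic per coordinate across a 3-frame interior gap
  tt <- 1:12
  poly <- function(t) 0.02 * t^3 - 0.3 * t^2 + t + 2
  sets <- lapply(tt, function(j)
    fss(j, c(poly(j), -poly(j) / 2, 0.1 * j, 0, 0, 0.05 * j), 0.1))
  sets[5:7] <- lapply(5:7, function(j)
    fss(j, matrix(numeric(0), 0, 6), numeric(0)))
  path <- selectPath(sets, cfg, 16)
  expect_equal(path$choices[5:7], rep(0L, 3))
  traj <- interpolateGaps(path, sets, 16)
  expect_equal(modeValues(traj)[5:7, 1], poly(5:7), tolerance = 1e-6)
  expect_equal(modeValues(traj)[1:4, 1], poly(1:4), tolerance = 1e-12)
  expect_equal(traj@provenance[5], "interpolated")
  # a smooth non-polynomial trajectory: interpolation tracks the truth
  smooth <- function(t) 3 * sin(0.15 * t) + 0.5 * cos(0.3 * t)
  sets2 <- lapply(tt, function(j)
    fss(j, c(smooth(j), 0, 0, 0, 0, 0), 0.1))
  sets2[6:7] <- lapply(6:7, function(j)
    fss(j, matrix(numeric(0), 0, 6), numeric(0)))
  path2 <- selectPath(sets2, filterConfig(vMax = rep(10, 5)), 16)
  traj2 <- interpolateGaps(path2, sets2, 16)
  expect_lt(max(abs(modeValues(traj2)[6:7, 1] - smooth(6:7))), 0.05)
})

test_that("gapless paths pass through interpolation unchanged", {
  sets <- lapply(1:4, function(j) fss(j, c(j, 0, 0, 0, 0, 0.1 * j), 0.2))
  path <- selectPath(sets, filterConfig(), 16)
  traj <- interpolateGaps(path, sets, 16)
  expect_equal(modeValues(traj)[, 1], 1:4)
  expect_true(all(traj@provenance == "candidate"))
})

test_that("head/tail swap is an involution and preserves the image", {
  set.seed(61)
  b <- fixtureBasis()
  body <- fixtureBody()
  for (rep in 1:5) {
    p <- c(runif(5, -1, 1) * c(10, 10, 15, 5, 2), runif(1, 0, 2 * pi))
    s <- swapHeadTail(p, b)
    expect_equal(unname(swapHeadTail(s, b)), unname(p), tolerance = 1e-9)
    i1 <- renderWorm(p, b, body)
    i2 <- renderWorm(s, b, body)
    expect_identical(unname(i1[, ]), unname(i2[, ]))
  }
  # straight worm: swap adds pi to the orientation
  pS <- c(0, 0, 0, 0, 0, 0.8)
  expect_equal(unname(swapHeadTail(pS, b)[6]), 0.8 + pi, tolerance = 1e-9)
  expect_equal(unname(swapHeadTail(pS, b)[1:5]), rep(0, 5),
               tolerance = 1e-9)
})

test_that("head/tail resolution keeps consistent segments and fixes global swaps", {
  set.seed(62)
  b <- fixtureBasis()
  body <- fixtureBody()
  fcfg <- filterConfig()
  scfg <- searchConfig()
  # a smooth uncrossed synthetic segment: wave advancing over 10 frames
  truth <- t(vapply(1:10, function(j) {
    ph <- 0.3 * j
    c(4 * cos(ph), -4 * sin(ph), 2, 0, 0, wrapAngle(0.02 * j)) },
    numeric(6)))
  frames <- lapply(1:10, function(j) renderWorm(truth[j, ], b, body))
  mkSets <- function(tr) lapply(1:10, function(j) {
    p <- tr[j, ]
    sw <- swapHeadTail(p, b)
    fss(j, rbind(p, sw, deparse.level = 0), c(0.05, 0.05))
  })
  res <- resolveHeadTail(mkSets(truth), frames, b, body, fcfg, scfg, 16)
  expect_false(any(abs(diff(orientationValues(res$trajectory))) >
                     pi / 16 + 1e-6))
  o <- orientationValues(res$trajectory)
  agree <- mean(abs((o - truth[, 6] + pi) %% (2 * pi) - pi) < 0.3)
  expect_true(agree > 0.9 || agree < 0.1)  # consistent head choice

  # inject a mid-sequence flip into the input: output stays continuous
  flipped <- truth
  flipped[6, ] <- swapHeadTail(truth[6, ], b)
  res2 <- resolveHeadTail(mkSets(flipped), frames, b, body, fcfg, scfg, 16)
  expect_false(any(abs(diff(orientationValues(res2$trajectory))) >
                     pi / 16 + 1e-6))

  # globally swapped input resolves to a continuous trajectory equivalent
  # to the truth up to the (silhouette-invisible) global head choice
  swAll <- t(vapply(1:10, function(j) swapHeadTail(truth[j, ], b),
                    numeric(6)))
  res3 <- resolveHeadTail(mkSets(swAll), frames, b, body, fcfg, scfg, 16)
  o3 <- orientationValues(res3$trajectory)
  d <- abs((o3 - truth[, 6] + pi) %% (2 * pi) - pi)
  dsw <- abs((o3 - truth[, 6]) %% (2 * pi) - pi)
  expect_true(all(d < 0.3) || all(dsw < 0.3))
})
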