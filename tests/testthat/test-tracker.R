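# Inverse tracker: curvature gate, pattern search, per-frame search,
# candidate merging.

test_that("curvature feasibility matches a direct scan oracle", {
  expect_true(curvatureOk(rep(0.3, 100)))
  # uniform turning 0.25 rad/index: difference over 10 indices is 2.5
  expect_false(curvatureOk(cumsum(rep(0.25, 100))))
  set.seed(51)
  for (rep in 1:20) {
    prof <- cumsum(rnorm(100, 0, 0.12))
    oracle <- max(vapply(1:90, function(k) abs(prof[k + 10] - prof[k]),
                         numeric(1))) <= 1.95
    expect_identical(curvatureOk(prof), oracle)
  }
})

test_that("pattern search minimizes a convex quadratic to mesh tolerance", {
  cen <- c(2.3, -1.1, 0.4, 7.9, -3.2, 0.1)
  obj <- function(x) sum((x - cen)^2)
  res <- patternSearch(obj, rep(0, 6), rep(-20, 6), rep(20, 6),
                       meshTol = 0.05)
  expect_lt(max(abs(res$par - cen)), 0.1)
  expect_lte(res$value, obj(rep(0, 6)))
})

test_that("pattern search never ascends and respects a minimizer start", {
  obj <- function(x) sum(x^2)
  res <- patternSearch(obj, c(0, 0), c(-5, -5), c(5, 5))
  expect_equal(res$value, 0)
  expect_error(patternSearch(function(x) NaN, 0, -1, 1), "finite")
})

test_that("pattern search beats a dense grid on a 2-D rendered-worm slice", {
  b <- fixtureBasis()
  body <- fixtureBody()
  cfg <- errorConfig()
  pT <- c(3, -2, 16, 1, 0, 0.8)
  img <- renderWorm(pT, b, body)
  slice <- function(x) {
    p <- pT
    p[3] <- x[1]
    p[6] <- x[2]
    img2 <- tryCatch(renderWorm(p, b, body), error = function(e) NULL)
    if (is.null(img2)) return(Inf)
    fErr(img, img2, cfg)
  }
  # the slice is multimodal (rotation near-symmetry of coils), so poll
  # from several starts as the frame search itself does
  set.seed(54)
  best <- Inf
  for (r in 1:12) {
    st <- c(runif(1, 5, 30), runif(1, -pi, pi + 2))
    res <- patternSearch(slice, st, c(5, -pi), c(30, pi + 2),
                         meshInit = 2, meshMax = 2)
    best <- min(best, res$value)
  }
  grid <- expand.grid(a3 = seq(5, 30, length.out = 41),
                      th = seq(0, 2, length.out = 41))
  gv <- min(vapply(seq_len(nrow(grid)),
                   function(i) slice(as.numeric(grid[i, ])), numeric(1)))
  expect_lte(best, gv + 1e-6)
})

test_that("candidate merging keeps the best of each cluster and is idempotent", {
  coords <- rbind(c(0, 0, 10, 0, 0, 1.0),
                  c(1, 1, 11, 0.5, 0.2, 1.2),   # within box of first
                  c(0, 0, 20, 0, 0, 1.0),        # far in a3
                  c(0, 0, 10, 0, 0, 4.0))        # far in orientation
  errs <- c(0.5, 0.1, 0.2, 0.3)
  m <- mergeCandidates(coords, errs)
  expect_equal(nrow(m$coords), 3)
  expect_true(0.1 %in% m$errors)   # cluster keeps its lowest error
  expect_false(0.5 %in% m$errors)
  m2 <- mergeCandidates(m$coords, m$errors)
  expect_identical(m2, m)
  # orientation is compared on the circle: 0.1 vs 2*pi - 0.1 are close
  cc <- rbind(c(0, 0, 10, 0, 0, 0.1), c(0, 0, 10, 0, 0, 2 * pi - 0.1))
  m3 <- mergeCandidates(cc, c(0.2, 0.1))
  expect_equal(nrow(m3$coords), 1)
})

test_that("the inverse search recovers a rendered coil (round trip)", {
  b <- fixtureBasis()
  body <- fixtureBody()
  set.seed(52)
  pT <- c(4.5 * cos(1.1), -4.5 * sin(1.1), 18, -2, 0, 5.2)
  img <- renderWorm(pT, b, body)
  set.seed(7)
  fs <- searchFrame(img, b, body, searchConfig(restarts = 60))
  cc <- candidates(fs)
  ee <- candidateErrors(fs)
  expect_gt(nrow(cc), 0)
  devs <- apply(cc, 1, coilDeviation, truth = pT, basis = b)
  expect_lte(min(devs), 2.0)
  # orientation of the matching candidate (or its swap)
  k <- which.min(devs)
  sw <- swapHeadTail(cc[k, ], b)
  dth <- min(abs(c(cc[k, 6], sw[6]) - pT[6]) %% (2 * pi),
             (2 * pi - abs(c(cc[k, 6], sw[6]) - pT[6])) %% (2 * pi))
  expect_lte(min(dth), 0.2)
  # postcondition audit: bounds, curvature, threshold
  expect_true(all(ee < searchConfig()$error$keepThreshold))
  bounds <- c(18, 18, 34, 12, 6)
  for (i in seq_len(nrow(cc))) {
    expect_true(all(abs(cc[i, 1:5]) <= bounds + 1e-9))
    expect_true(curvatureOk(reconstructProfile(cc[i, ], b)))
  }
})

test_that("a straight worm yields a head/tail-swapped candidate pair", {
  b <- fixtureBasis()
  body <- fixtureBody()
  pT <- c(4, 1, 0, 0, 0, 1.0)
  img <- renderWorm(pT, b, body)
  set.seed(8)
  fs <- searchFrame(img, b, body, searchConfig(restarts = 50))
  cc <- candidates(fs)
  expect_gte(nrow(cc), 2)
  # some pair of candidates related by the head/tail swap (orientation pi
  # apart, matching modes)
  found <- FALSE
  for (i in seq_len(nrow(cc))) {
    sw <- swapHeadTail(cc[i, ], b)
    for (j in seq_len(nrow(cc))) {
      if (i != j && max(abs(sw[1:5] - cc[j, 1:5])) < 3 &&
          min((sw[6] - cc[j, 6]) %% (2 * pi),
              (cc[j, 6] - sw[6]) %% (2 * pi)) < 0.5) found <- TRUE
    }
  }
  expect_true(found)
})

test_that("candidate dumps round-trip through JSON lines", {
  fs <- new("FrameSolutionSet", frame = 3L,
            coords = rbind(c(1, 2, 12, 0, -1, 0.5), c(0, 1, 15, 2, 0, 2.1)),
            errors = c(0.2, 0.4))
  f <- tempfile(fileext = ".jsonl")
  writeCandidates(fs, f)
  recs <- lapply(readLines(f), jsonlite::fromJSON)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$frame, 3)
  expect_equal(recs[[2]]$a3, 15)
  expect_equal(recs[[2]]$err, 0.4)
})

test_that("the search is deterministic given the seed", {
  b <- fixtureBasis()
  body <- fixtureBody()
  img <- renderWorm(c(2, -3, 14, 1, 0, 2.0), b, body)
  cfg <- searchConfig(restarts = 6)
  set.seed(99)
  f1 <- searchFrame(img, b, body, cfg)
  set.seed(99)
  f2 <- searchFrame(img, b, body, cfg)
  expect_identical(candidates(f1), candidates(f2))
  expect_identical(candidateErrors(f1), candidateErrors(f2))
})

test_that("most rendered coils are recovered within tolerance", {
  # reduced-n version of the success-rate property; the acceptance suite
  # runs the full 20-frame variant
  b <- fixtureBasis()
  body <- fixtureBody()
  set.seed(53)
  truths <- t(replicate(5, drawCoil(b)))
  ok <- 0
  for (i in 1:5) {
    img <- renderWorm(truths[i, ], b, body)
    set.seed(200 + i)
    fs <- searchFrame(img, b, body, searchConfig(restarts = 60))
    cc <- candidates(fs)
    if (nrow(cc) == 0) next
    devs <- apply(cc, 1, coilDeviation, truth = truths[i, ], basis = b)
    if (min(devs) <= 2.0) ok <- ok + 1
  }
  expect_gte(ok, 4)
})
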