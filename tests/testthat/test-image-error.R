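# Two-metric image error: outline signature, f_outline, f_pixel, f_err.

test_that("a rasterized disc has a uniform outline signature", {
  disc <- discImage(r = 20)
  s <- outlineSignature(disc)
  expect_length(s$psi, 200)
  expect_lt(diff(range(s$psiCyclic)), 0.04)   # all angles equal within 0.02
  expect_equal(abs(sum(s$psiCyclic)), 2 * pi, tolerance = 0.15)
  expect_equal(s$perimeter, 2 * pi * 20, tolerance = 0.05 * 2 * pi * 20)
})

test_that("a filled rectangle concentrates its turning at four corners", {
  img <- matrix(FALSE, 60, 90)
  img[15:45, 10:80] <- TRUE
  s <- outlineSignature(img)
  psi <- abs(s$psiCyclic)
  expect_equal(abs(sum(s$psiCyclic)), 2 * pi, tolerance = 0.15)
  # turning concentrates at the four (smoothed) corners; sides are straight
  expect_gt(sum(sort(psi, decreasing = TRUE)[1:40]), 0.75 * 2 * pi)
  expect_lt(stats::median(psi), 0.02)
})

test_that("outline signature rejects degenerate input", {
  expect_error(outlineSignature(matrix(FALSE, 10, 10)), "foreground")
  one <- matrix(FALSE, 10, 10)
  one[5, 5] <- TRUE
  expect_error(outlineSignature(one), "degenerate")
  two <- matrix(FALSE, 20, 20)
  two[2:6, 2:6] <- TRUE
  two[14:18, 14:18] <- TRUE
  expect_error(outlineSignature(two), "components")
})

test_that("f_outline is zero on identical images, symmetric, and matches the exhaustive-offset oracle", {
  set.seed(41)
  b <- fixtureBasis()
  body <- fixtureBody()
  cfg <- errorConfig()
  imgs <- lapply(1:3, function(i) renderWorm(drawCoil(b), b, body))
  expect_equal(fOutline(imgs[[1]], imgs[[1]], cfg), 0)
  for (pair in list(c(1, 2), c(2, 3), c(1, 3))) {
    i1 <- imgs[[pair[1]]]
    i2 <- imgs[[pair[2]]]
    expect_equal(fOutline(i1, i2, cfg), fOutline(i2, i1, cfg),
                 tolerance = 1e-12)
    # oracle: explicit minimization over all cyclic offsets x 2 directions
    s1 <- outlineSignature(i1, config = cfg)
    s2 <- outlineSignature(i2, config = cfg)
    n <- length(s1$psiCyclic)
    best <- Inf
    for (dir in 1:2) {
      p2 <- if (dir == 1) s2$psiCyclic
            else -s2$psiCyclic[c(1, n:2)]
      for (o in 0:(n - 1)) {
        ss <- sum((s1$psiCyclic - p2[((seq_len(n) - 1 + o) %% n) + 1])^2)
        best <- min(best, cfg$C0 * ss +
                      cfg$C1 * (s1$perimeter - s2$perimeter)^2)
      }
    }
    expect_equal(fOutline(i1, i2, cfg), best, tolerance = 1e-10)
  }
})

test_that("f_pixel matches a naive block-density oracle and is bounded", {
  set.seed(42)
  b <- fixtureBasis()
  body <- fixtureBody()
  cfg <- errorConfig()
  naiveFPixel <- function(img1, img2, blk) {
    cen <- function(m) {
      idx <- which(m, arr.ind = TRUE)
      c(mean(idx[, 2] - 1), mean(idx[, 1] - 1))  # (x, y)
    }
    sh <- round(cen(img1) - cen(img2))
    pts1 <- which(img1, arr.ind = TRUE)
    pts2 <- which(img2, arr.ind = TRUE)
    pts2[, 2] <- pts2[, 2] + sh[1]
    pts2[, 1] <- pts2[, 1] + sh[2]
    allr <- range(c(pts1[, 1], pts2[, 1]))
    allc <- range(c(pts1[, 2], pts2[, 2]))
    nby <- (allr[2] - allr[1]) %/% blk + 1
    nbx <- (allc[2] - allc[1]) %/% blk + 1
    tot <- 0
    for (by in seq_len(nby)) for (bx in seq_len(nbx)) {
      rs <- allr[1] + (by - 1) * blk
      cs <- allc[1] + (bx - 1) * blk
      inblk <- function(p) sum(p[, 1] >= rs & p[, 1] < rs + blk &
                                 p[, 2] >= cs & p[, 2] < cs + blk)
      tot <- tot + (inblk(pts1) / blk^2 - inblk(pts2) / blk^2)^2
    }
    tot / (nbx * nby)
  }
  for (rep in 1:3) {
    i1 <- renderWorm(drawCoil(b), b, body)
    i2 <- renderWorm(drawCoil(b), b, body)
    v <- fPixel(i1, i2, cfg)
    expect_equal(v, naiveFPixel(i1, i2, cfg$blockPx), tolerance = 1e-12)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  expect_equal(fPixel(i1, i1, cfg), 0)
})

test_that("f_pixel attains exact hand-computed values on aligned blocks", {
  # both images share the centroid (no shift); 2 x 2 grid of 10 px blocks
  i1 <- matrix(FALSE, 20, 20)
  i1[1:10, 1:10] <- TRUE
  i1[11:20, 11:20] <- TRUE
  i2 <- matrix(FALSE, 20, 20)
  i2[1:10, 11:20] <- TRUE
  i2[11:20, 1:10] <- TRUE
  expect_equal(fPixel(i1, i2, errorConfig()), 1)  # every block fully differs
  # two blocks at half density via a centro-symmetric checkerboard: the
  # centroids still coincide, d = (1, .5, .5, 1) vs (1, 1, 1, 1)
  full <- matrix(TRUE, 20, 20)
  chk <- outer(1:10, 1:10, function(r, c) (r + c) %% 2 == 0)
  ihalf <- full
  ihalf[1:10, 11:20] <- chk
  ihalf[11:20, 1:10] <- chk
  expect_equal(fPixel(full, ihalf, errorConfig()), (1 / 4) * 2 * 0.5^2)
})

test_that("f_err is the product of its factors and translation-invariant", {
  b <- fixtureBasis()
  body <- fixtureBody()
  cfg <- errorConfig()
  set.seed(43)
  p <- drawCoil(b)
  i1 <- renderWorm(p, b, body)
  i2 <- renderWorm(drawCoil(b), b, body)
  expect_equal(fErr(i1, i1, cfg), 0)
  expect_equal(fErr(i1, i2, cfg),
               fOutline(i1, i2, cfg) * fPixel(i1, i2, cfg))
  # shifting the content of one image changes nothing after alignment
  shifted <- matrix(FALSE, nrow(i2), ncol(i2))
  shifted[1:(nrow(i2) - 15), 1:(ncol(i2) - 15)] <-
    i2[16:nrow(i2), 16:ncol(i2)]
  expect_equal(fPixel(i1, shifted, cfg), fPixel(i1, i2, cfg),
               tolerance = 1e-12)
  expect_equal(fErr(i1, shifted, cfg), fErr(i1, i2, cfg), tolerance = 1e-10)
})

test_that("the error landscape rises away from a rendered posture", {
  # mode perturbations increase the error monotonically near the optimum;
  # orientation perturbations increase it but lose monotonicity on deep
  # coils, whose silhouettes are nearly rotation-symmetric
  set.seed(44)
  b <- fixtureBasis()
  body <- fixtureBody()
  cfg <- errorConfig()
  for (rep in 1:5) {
    p <- drawCoil(b)
    img <- renderWorm(p, b, body)
    for (i in sample(5, 2)) {
      vals <- vapply(c(0, 1, 2), function(eps) {
        q <- p
        q[i] <- q[i] + eps
        img2 <- tryCatch(renderWorm(q, b, body), error = function(e) NULL)
        if (is.null(img2)) return(NA_real_)
        fErr(img, img2, cfg)
      }, numeric(1))
      vals <- vals[!is.na(vals)]
      expect_true(all(diff(vals) > -1e-6))
    }
    rot <- fErr(img, renderWorm(p + c(0, 0, 0, 0, 0, 1), b, body), cfg)
    expect_gt(rot, 0)
  }
})
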