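test_that("a vertical step yields a near-vertical segment; flat images none", {
  step <- IonImage(cbind(matrix(0, 64, 32), matrix(100, 64, 32)))
  segs <- detectEdgeSegments(step)
  expect_gte(nrow(segs), 1L)
  expect_true(any(abs(segs$angle - 90) < 5))

  expect_equal(nrow(detectEdgeSegments(IonImage(matrix(5, 64, 64)))), 0L)
  expect_equal(nrow(detectEdgeSegments(IonImage(matrix(0, 64, 64)))), 0L)
})

test_that("phantom edges are recovered with their known orientations", {
  ph <- makePhantom(c(64, 64), "squares", seed = 1)
  segs <- detectEdgeSegments(ph)
  expect_gte(nrow(segs), 2L)
  horiz <- segs$angle < 5 | segs$angle > 175
  vert <- abs(segs$angle - 90) < 5
  expect_true(any(horiz))
  expect_true(any(vert))
  # detected lines lie on the generator's edge list (within 2 px)
  truth <- ph@metadata$edges
  for (i in which(horiz)) {
    expect_true(min(abs(segs$r0[i] - truth$r0[truth$angle == 0])) <= 2)
  }
})

test_that("perpendicular profiles are monotone across a clean step", {
  step <- IonImage(cbind(matrix(0, 64, 32), matrix(100, 64, 32)))
  segs <- detectEdgeSegments(step)
  prof <- extractProfiles(step, segs[1, ], halfLength = 5)
  expect_gt(length(prof), 10)
  for (p in prof[1:5]) {
    dp <- diff(p)
    # monotone up to interpolation round-off; polarity may flip
    expect_true(all(dp >= -1e-9) || all(dp <= 1e-9))
  }
})

test_that("profiles across a Gaussian-blurred step match the erf model", {
  step <- IonImage(cbind(matrix(0, 64, 32), matrix(100, 64, 32)))
  bl <- degradeImage(step, twoSigma = 4)   # PSF sigma = 2
  segs <- detectEdgeSegments(bl)
  prof <- extractProfiles(bl, segs[1, ], halfLength = 8)
  expect_gt(length(prof), 0)
  p <- prof[[ceiling(length(prof) / 2)]]
  # compare interior samples to the analytically convolved step, locating
  # the edge centre by interpolating the 50% crossing
  x <- seq_along(p)
  i <- max(which(p < 50))
  edgePos <- i + (50 - p[i]) / (p[i + 1] - p[i])
  model <- 100 * pnorm((x - edgePos) / 2)
  expect_lt(max(abs(p - model)[4:(length(p) - 3)]), 3)
  fit <- fitLSF(p)
  expect_true(fit$accepted)
  expect_lt(abs(fit$sigma - 2) / 2, 0.1)
})

test_that("spacing larger than the segment yields exactly one profile", {
  step <- IonImage(cbind(matrix(0, 64, 32), matrix(100, 64, 32)))
  seg <- data.frame(r0 = 20, c0 = 32.5, r1 = 45, c1 = 32.5)
  prof <- extractProfiles(step, seg, halfLength = 5, spacing = 1e4)
  expect_length(prof, 1L)
})

test_that("profiles crossing missing pixels or image borders are skipped", {
  m <- cbind(matrix(0, 64, 32), matrix(100, 64, 32))
  msk <- matrix(FALSE, 64, 64); msk[30:34, 28:36] <- TRUE
  img <- IonImage(m, mask = msk)
  seg <- data.frame(r0 = 5, c0 = 32.5, r1 = 60, c1 = 32.5)
  withMask <- extractProfiles(img, seg, halfLength = 6)
  noMask <- extractProfiles(IonImage(m), seg, halfLength = 6)
  expect_lt(length(withMask), length(noMask))
  # a segment hugging the border yields no profiles
  edgeSeg <- data.frame(r0 = 5, c0 = 2, r1 = 60, c1 = 2)
  expect_length(extractProfiles(img, edgeSeg, halfLength = 6), 0L)
})

test_that("the LSF fit recovers sigma from a Gaussian CDF profile", {
  x <- 0:20
  prof <- 100 * pnorm((x - 10) / 2)
  fit <- fitLSF(prof)
  expect_true(fit$accepted)
  expect_gt(fit$rSquared, 0.99)
  expect_lt(abs(fit$sigma - 2) / 2, 0.05)
  expect_lt(abs(fit$center - 11), 0.5)   # profile coordinates are 1-based
})

test_that("noise profiles are rejected in at least 18 of 20 seeds", {
  rejected <- 0L
  for (s in 1:20) {
    set.seed(s)
    if (!fitLSF(runif(17))$accepted) rejected <- rejected + 1L
  }
  expect_gte(rejected, 18L)
})

test_that("a perfectly sharp step fits at or below the pixel limit", {
  fit <- fitLSF(c(rep(0, 8), rep(100, 9)))
  expect_true(!fit$accepted || fit$sigma <= 1)
})

test_that("blur width is recovered within 15% for true widths 2, 4, 6", {
  ph <- makePhantom(c(64, 64), "squares", seed = 1)
  est <- vapply(c(2, 4, 6), function(ts) {
    twoSigma(estimatePSFWidth(degradeImage(ph, twoSigma = ts)))
  }, numeric(1))
  expect_lt(abs(est[1] - 2) / 2, 0.15)
  expect_lt(abs(est[2] - 4) / 4, 0.15)
  expect_lt(abs(est[3] - 6) / 6, 0.15)
  expect_true(all(diff(est) > 0))   # monotone in true blur
})

test_that("width estimates are rotation-robust within 10%", {
  bl <- degradeImage(makePhantom(c(64, 64), "squares", seed = 2),
                     twoSigma = 4)
  w <- twoSigma(estimatePSFWidth(bl))
  rot <- IonImage(t(pixels(bl))[ncol(pixels(bl)):1, ])
  wr <- twoSigma(estimatePSFWidth(rot))
  expect_lt(abs(w - wr) / w, 0.10)
})

test_that("images without coherent edges are flagged not estimable", {
  set.seed(3)
  noise <- IonImage(matrix(runif(64 * 64), 64, 64))
  expect_error(estimatePSFWidth(noise), class = "notEstimableError")
  small <- IonImage(matrix(1:100 + 0, 10, 10))
  expect_error(detectEdgeSegments(small), "16 x 16")
})

test_that("gaussianKernel is normalized, centred, isotropic and correct", {
  k <- kernelWeights(gaussianKernel(2, size = 5))
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_equal(which.max(k), 13L)                 # centre of a 5x5
  expect_identical(k, t(k))
  expect_identical(k, k[5:1, 5:1])                # 180-degree rotation
  k7 <- kernelWeights(gaussianKernel(2, size = 7))
  # sd = twoSigma/2 = 1: neighbour/centre ratio is exp(-1/2)
  expect_equal(k7[4, 5] / k7[4, 4], exp(-0.5), tolerance = 1e-12)
  # default size: smallest odd >= 3 * twoSigma, minimum 3
  expect_equal(dim(gaussianKernel(4)), c(13L, 13L))
  expect_equal(dim(gaussianKernel(0.5)), c(3L, 3L))
  expect_error(gaussianKernel(0), "positive")
  expect_error(gaussianKernel(-2), "positive")
})
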