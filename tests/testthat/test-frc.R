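test_that("checkerboard split halves dimensions after even-trimming", {
  img <- IonImage(matrix(runif(35 * 70), 35, 70), pixelSize = 100)
  halves <- checkerboardSplit(img)
  expect_identical(dim(halves$a), c(17L, 35L))
  expect_identical(dim(halves$b), c(17L, 35L))
  expect_equal(pixelSize(halves$a), 200)
})

test_that("checkerboard split of small and constant images", {
  m8 <- IonImage(matrix(runif(64), 8, 8))
  halves8 <- checkerboardSplit(m8)
  expect_identical(dim(halves8$a), c(4L, 4L))
  expect_error(checkerboardSplit(IonImage(matrix(1, 7, 7))),
               "under-sampled")
  const <- checkerboardSplit(IonImage(matrix(3, 10, 10)))
  expect_identical(pixels(const$a), pixels(const$b))
  # diagonal interleave: sub-image a starts at (1,1), b at (2,2)
  m <- matrix(as.numeric(seq_len(64)), 8, 8)
  halves <- checkerboardSplit(IonImage(m))
  expect_identical(pixels(halves$a)[1, 1], 1)
  expect_identical(pixels(halves$b)[1, 1], m[2, 2])
})

test_that("self-correlation is 1 in every ring and FRC is symmetric", {
  set.seed(31)
  a <- matrix(runif(32 * 32), 32, 32)
  b <- matrix(runif(32 * 32), 32, 32)
  self <- frcCurve(a, a)
  expect_true(all(abs(self@values - 1) < 1e-9))
  expect_identical(frcCurve(a, b)@values, frcCurve(b, a)@values)
})

test_that("independent white noise decorrelates to ~0", {
  set.seed(1); a <- matrix(rnorm(128 * 128), 128, 128)
  set.seed(2); b <- matrix(rnorm(128 * 128), 128, 128)
  cv <- frcCurve(a, b)
  expect_lt(abs(mean(cv@values)), 0.1)
})

test_that("ring values match a brute-force DFT loop on an 8x8 pair", {
  set.seed(32)
  a <- matrix(runif(64), 8, 8)
  b <- matrix(runif(64), 8, 8)
  got <- frcCurve(a, b, window = "none")
  oracle <- bruteFRC(a, b)
  expect_equal(got@freqs, oracle$freqs, tolerance = 1e-12)
  expect_equal(got@nPerRing, oracle$n)
  expect_equal(got@values, oracle$values, tolerance = 1e-10)
})

test_that("half-bit threshold has the right limit, values and monotonicity", {
  expect_lt(abs(halfBitThreshold(1e8) - 0.2071 / 1.2071), 1e-3)
  expect_equal(halfBitThreshold(1),
               (0.2071 + 1.9102) / (1.2071 + 0.9102), tolerance = 1e-12)
  n <- c(1, 2, 5, 10, 100, 1e4, 1e6)
  expect_true(all(diff(halfBitThreshold(n)) < 0))
  expect_error(halfBitThreshold(c(4, 0)), "at least one")
})

test_that("cutoff interpolation, no-crossing and low-SNR paths", {
  mk <- function(freqs, values, thr)
    new("FRCCurve", freqs = freqs, values = values,
        nPerRing = rep(10, length(freqs)), threshold = thr)
  # linear interpolation between ring centres
  cv <- mk(c(0.4, 0.6), c(0.5, 0.1), c(0.3, 0.3))
  expect_equal(findCutoff(cv), 0.5, tolerance = 1e-12)
  # correlation never below threshold -> Nyquist
  cv2 <- mk(c(0.25, 0.5, 0.75, 1), rep(1, 4), rep(0.2, 4))
  expect_equal(findCutoff(cv2), 1.0)
  # starts below threshold -> first ring frequency with warning
  cv3 <- mk(c(0.25, 0.5), c(0.1, 0.05), c(0.3, 0.3))
  expect_warning(f <- findCutoff(cv3), "low SNR")
  expect_equal(f, 0.25)
})

test_that("a constructed band limit is found within one ring width", {
  # shared band-limited signal + independent wide-band noise: the FRC is
  # high below the band edge and ~0 above it
  set.seed(33)
  n <- 64
  base <- matrix(rnorm(n * n), n, n)
  Fb <- stats::fft(base)
  fAxis <- function(n) {
    k <- seq_len(n) - 1; k[k > n / 2] <- k[k > n / 2] - n; 2 * k / n
  }
  rad <- sqrt(outer(fAxis(n)^2, fAxis(n)^2, `+`))
  Fb[rad > 0.5] <- 0
  sig <- Re(stats::fft(Fb, inverse = TRUE)) / (n * n)
  sig <- 50 * sig / stats::sd(sig)
  a <- sig + matrix(rnorm(n * n), n, n)
  b <- sig + matrix(rnorm(n * n), n, n)
  cv <- frcCurve(a, b, window = "none")
  expect_lt(abs(findCutoff(cv) - 0.5), 1 / length(cv@freqs) + 0.02)
})

test_that("resolution conversion follows delta_x = 2 * pixel / fthresh", {
  expect_equal(resolutionFromCutoff(1.0, 100), 200)
  expect_equal(resolutionFromCutoff(0.5, 10), 40)
  f <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(resolutionFromCutoff(f, 10)) < 0))
  expect_error(resolutionFromCutoff(0, 10), "fthresh")
  expect_error(resolutionFromCutoff(1.2, 10), "fthresh")
})

test_that("single-image resolution prefers sharp over blurred phantoms", {
  ph <- makePhantom(c(64, 64), "squares", seed = 5, pixelSize = 100)
  sharp <- degradeImage(ph, twoSigma = 0, noiseModel = "poisson",
                        snr = 20, seed = 5)
  blurred <- degradeImage(ph, twoSigma = 6, noiseModel = "poisson",
                          snr = 20, seed = 5)
  fs <- cutoffFrequency(singleImageResolution(sharp))
  fb <- cutoffFrequency(singleImageResolution(blurred))
  expect_gt(fs, fb)
})

test_that("fthresh stays in (0, 1] and resolution respects Nyquist", {
  ph <- makePhantom(c(64, 64), "squares", seed = 7, pixelSize = 100)
  set.seed(7)
  cases <- list(
    degradeImage(ph, twoSigma = 2, noiseModel = "poisson", snr = 10,
                 seed = 1),
    degradeImage(ph, twoSigma = 6, noiseModel = "gaussian", snr = 3,
                 seed = 2),
    IonImage(matrix(runif(64 * 64), 64, 64), pixelSize = 100))
  for (img in cases) {
    r <- suppressWarnings(singleImageResolution(img))
    expect_gt(cutoffFrequency(r), 0)
    expect_lte(cutoffFrequency(r), 1)
    expect_gte(resolutionValue(r), 2 * 100 - 1e-9)
  }
})

test_that("more blur and more noise both lower the cutoff", {
  ph <- makePhantom(c(64, 64), "squares", seed = 5, pixelSize = 100)
  fth <- vapply(c(2, 4, 6), function(ts) {
    img <- degradeImage(ph, twoSigma = ts, noiseModel = "poisson",
                        snr = 20, seed = 5)
    cutoffFrequency(singleImageResolution(img))
  }, numeric(1))
  expect_true(all(diff(fth) < 0))
  fSNR <- vapply(c(5, 50), function(s) {
    img <- degradeImage(ph, twoSigma = 4, noiseModel = "poisson",
                        snr = s, seed = 5)
    cutoffFrequency(singleImageResolution(img))
  }, numeric(1))
  expect_lt(fSNR[1], fSNR[2])
})

test_that("small images carry the limited-accuracy warning", {
  img <- IonImage(matrix(runif(35 * 70), 35, 70) + 1, pixelSize = 100)
  # a noise image also trips the low-SNR warning; both are expected
  expect_warning(expect_warning(r <- singleImageResolution(img), "32 px"))
  expect_true(r@smallImage)
  big <- IonImage(matrix(runif(70 * 70), 70, 70) + 1, pixelSize = 100)
  rb <- suppressWarnings(singleImageResolution(big))
  expect_false(rb@smallImage)
})

test_that("pure noise lands on the low-SNR path near the first ring", {
  set.seed(9)
  img <- IonImage(matrix(runif(64 * 64), 64, 64), pixelSize = 100)
  expect_warning(r <- singleImageResolution(img), "low SNR")
  expect_true(r@lowSNR)
  expect_lte(cutoffFrequency(r), 2 / length(r@curve@freqs))
})
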