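test_that("rlUpdate matches a loop-based brute-force oracle", {
  set.seed(21)
  for (boundary in c("reflect", "periodic")) {
    for (rep in 1:3) {
      e <- matrix(runif(25, 0.1, 2), 5, 5)
      o <- matrix(runif(25, 0.1, 2), 5, 5)
      k <- matrix(runif(9), 3, 3); k <- k / sum(k)
      got <- rlUpdate(e, k, o, boundary = boundary)
      expect_equal(got, bruteRLUpdate(e, k, o, boundary),
                   tolerance = 1e-10)
    }
  }
})

test_that("a delta kernel is an exact fixed point of the RL update", {
  set.seed(22)
  y <- matrix(runif(25, 0.5, 2), 5, 5)
  u <- rlUpdate(y, matrix(1, 1, 1), y)
  expect_equal(u, y, tolerance = 1e-12)
})

test_that("the 1x3 hat-kernel update matches the hand-expanded formula", {
  # observed = (0,1,0) row embedded in a 3x3 grid; kernel smooths along
  # columns only, so each row behaves as the 1-D case under reflection
  o <- rbind(c(0, 1, 0), c(0, 1, 0), c(0, 1, 0))
  k <- matrix(c(0.25, 0.5, 0.25), 1, 3)
  got <- rlUpdate(o, k, o, boundary = "reflect")
  # hand expansion for one row under mirror boundaries:
  # conv = (0.25, 0.5, 0.25) -> ratio = (0, 2, 0)
  # update = e * corr(ratio, k): (0 * 1, 1 * 1, 0 * 1) = (0, 1, 0)
  expect_equal(got, o, tolerance = 1e-12)
})

test_that("RL conserves flux under periodic boundaries", {
  set.seed(23)
  x <- matrix(runif(16 * 16, 0.5, 2), 16, 16)
  k <- kernelWeights(gaussianKernel(2))
  obs <- deblurMSI:::fftConv2(x, k, "periodic")
  est <- obs
  for (i in 1:25) est <- rlUpdate(est, k, obs, boundary = "periodic")
  expect_lt(abs(sum(est) - sum(obs)) / sum(obs), 1e-6)
  expect_true(all(est >= 0))
})

test_that("blind iterations reduce the model residual and keep the PSF sane", {
  obj <- pixels(makePhantom(c(32, 32), "squares", seed = 10))
  k0 <- kernelWeights(gaussianKernel(3))
  obs <- deblurMSI:::fftConv2(obj, k0, "reflect")
  est <- obs
  psf <- gaussianKernel(3)
  resid <- function(e, p)
    sqrt(sum((deblurMSI:::fftConv2(e, kernelWeights(p), "reflect") - obs)^2))
  r0 <- resid(est, psf)
  for (i in 1:10) {
    s <- blindRLIterate(est, psf, obs)
    est <- s$estimate
    psf <- s$psf
    expect_equal(sum(kernelWeights(psf)), 1, tolerance = 1e-9)
    expect_true(all(kernelWeights(psf) >= 0))
  }
  expect_lt(resid(est, psf), r0)
})

test_that("an identity PSF makes the image a blind fixed point", {
  set.seed(24)
  obs <- matrix(runif(25, 0.5, 2), 5, 5)
  s <- blindRLIterate(obs, matrix(1, 1, 1), obs)
  expect_equal(s$estimate, obs, tolerance = 1e-9)
})

test_that("auto-deconvolution reduces the estimated width on noisy data", {
  obs <- makeObservation(twoSigma = 4, snr = 20, seed = 3)
  res <- autoDeconvolve(obs)
  tr <- widthTrajectory(res)
  expect_gte(length(tr), 6L)
  expect_lt(tr[length(tr)], tr[1])
  expect_true(all(is.finite(tr)))
  expect_true(stopReason(res) %in% c("plateau", "blur_increase", "max_iter"))
  expect_gte(res@iterations, 5L)
  expect_true(all(pixels(restored(res)) >= 0))
  expect_identical(dim(restored(res)), dim(obs))
})

test_that("sub-pixel initial widths trigger the guard untouched", {
  sharp <- makePhantom(c(64, 64), "squares", seed = 2)
  res <- autoDeconvolve(sharp)
  expect_identical(stopReason(res), "subpixel_guard")
  expect_identical(res@iterations, 0L)
  expect_identical(pixels(restored(res)), pixels(sharp))
  expect_length(widthTrajectory(res), 1L)
  expect_lte(widthTrajectory(res)[1], 1)
})

test_that("images without edge evidence pass through unchanged", {
  set.seed(3)
  noise <- IonImage(matrix(runif(64 * 64), 64, 64))
  res <- autoDeconvolve(noise)
  expect_identical(stopReason(res), "not_estimable")
  expect_identical(pixels(restored(res)), pixels(noise))
  expect_identical(res@iterations, 0L)
})

test_that("missing pixels are filled for deconvolution and re-masked after", {
  obs <- makeObservation(twoSigma = 4, snr = 20, seed = 6)
  holey <- degradeImage(obs, twoSigma = 0, dropoutFraction = 0.05,
                        seed = 6)
  res <- autoDeconvolve(holey)
  expect_identical(imageMask(restored(res)), imageMask(holey))
  expect_true(all(pixels(restored(res))[imageMask(holey)] == 0))
})
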