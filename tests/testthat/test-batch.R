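test_that("uniform improvement gives statistic 0 and p = 2^-n", {
  res <- pairedWilcoxonOneSided(before = (1:10) + 1,
                                after = as.numeric(1:10),
                                alternative = "less")
  expect_equal(res$statistic, 0)
  expect_equal(res$pValue, 2^-10, tolerance = 1e-15)
  expect_equal(res$nPairs, 10L)
})

test_that("identical before/after is a degenerate-data error", {
  x <- as.numeric(1:8)
  expect_error(pairedWilcoxonOneSided(x, x), "degenerate")
  expect_error(pairedWilcoxonOneSided(1:4 + 0, 1:4 + 1), "at least 5")
})

test_that("exact p-values match brute-force enumeration (100 seeded cases)", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(5:10, 1)
    before <- rnorm(n)
    after <- rnorm(n)
    alt <- if (s %% 2 == 0) "less" else "greater"
    got <- pairedWilcoxonOneSided(before, after, alternative = alt)
    expect_equal(got$pValue, bruteWilcoxonP(before, after, alt),
                 tolerance = 1e-12, info = paste("seed", s))
  }
})

test_that("tied differences are enumerated exactly too", {
  # |d| all equal: W+ counts midranks; P(W+ <= 0) = 2^-n
  got <- pairedWilcoxonOneSided(before = rep(2, 6), after = rep(1, 6))
  expect_equal(got$pValue, bruteWilcoxonP(rep(2, 6), rep(1, 6)),
               tolerance = 1e-12)
})

test_that("large samples fall back to the corrected normal approximation", {
  set.seed(12)
  before <- rnorm(40, mean = 4)
  after <- before - abs(rnorm(40, 0.5))
  got <- pairedWilcoxonOneSided(before, after)
  ref <- suppressWarnings(stats::wilcox.test(
    after, before, paired = TRUE, alternative = "less", exact = FALSE,
    correct = TRUE))
  expect_equal(got$pValue, unname(ref$p.value), tolerance = 1e-12)
  expect_gt(got$pValue, 0)
  expect_lte(got$pValue, 1)
})

test_that("batch deconvolution records widths and runs the paired test", {
  sim <- simulateBatch(6, twoSigma = 4, noiseModel = "poisson", snr = 20,
                       seed = 0)
  rep <- suppressMessages(runBatchDeconv(sim$stack))
  rows <- reportRows(rep)
  expect_equal(nrow(rows), 6L)
  expect_true(all(is.finite(rows$widthBefore)))
  expect_true(all(is.finite(rows$widthAfter)))
  expect_true(all(rows$widthAfter < rows$widthBefore))
  expect_gt(rep@pValue, 0)
  expect_lt(rep@pValue, 0.05)
  expect_identical(rep@direction, "widthAfter < widthBefore")
  expect_s4_class(attr(rows, "restored"), "IonImageStack")
})

test_that("a batch without usable edges skips the paired test", {
  set.seed(40)
  imgs <- lapply(1:5, function(i)
    IonImage(matrix(runif(64 * 64), 64, 64)))
  stk <- IonImageStack(imgs)
  msgs <- capture_messages(rep <- runBatchDeconv(stk))
  expect_true(any(grepl("skipped", msgs)))
  rows <- reportRows(rep)
  expect_true(all(rows$stopReason %in% c("not_estimable", "subpixel_guard")))
  expect_true(all(rows$iterations == 0L))
  expect_true(is.na(rep@pValue))
})

test_that("before/after FRC batches detect a constructed improvement", {
  n <- 12
  clean <- vector("list", n)
  noisy <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- makePhantom(c(64, 64), "squares", seed = i, pixelSize = 100)
    clean[[i]] <- degradeImage(ph, twoSigma = 0, noiseModel = "poisson",
                               snr = 50, seed = i)
    noisy[[i]] <- degradeImage(ph, twoSigma = 5, noiseModel = "poisson",
                               snr = 8, seed = i)
  }
  ids <- sprintf("img%02d", seq_len(n))
  rep <- runBatchFRC(IonImageStack(noisy, ids), IonImageStack(clean, ids))
  expect_lt(rep@pValue, 0.05)
  expect_identical(rep@direction, "fthreshAfter > fthreshBefore")
  rows <- reportRows(rep)
  expect_gte(sum(rows$fthreshAfter > rows$fthreshBefore), n - 2L)

  expect_error(
    runBatchFRC(IonImageStack(noisy, ids),
                IonImageStack(clean[1:6], ids[1:6])), "misaligned")
})

test_that("identical stacks make the FRC comparison degenerate", {
  imgs <- lapply(1:5, function(i)
    IonImage(pixels(makePhantom(c(64, 64), "squares", seed = i)) +
               i, pixelSize = 100))
  stk <- IonImageStack(imgs)
  expect_error(suppressWarnings(runBatchFRC(stk, stk)), "degenerate")
})

test_that("reports round-trip losslessly through JSON", {
  sim <- simulateBatch(6, twoSigma = 4, seed = 0)
  rep <- suppressMessages(runBatchDeconv(sim$stack))
  f <- withr::local_tempfile(fileext = ".json")
  reportToJSON(rep, f)
  back <- reportFromJSON(f)
  r1 <- reportRows(rep); attr(r1, "restored") <- NULL
  r2 <- reportRows(back)
  expect_equal(r2, r1, tolerance = 1e-12)
  expect_equal(back@wilcoxonStatistic, rep@wilcoxonStatistic)
  expect_equal(back@pValue, rep@pValue)
  expect_identical(back@nPairs, rep@nPairs)
  expect_identical(back@direction, rep@direction)
  # and the round trip is a fixed point: JSON -> object -> JSON identical
  f2 <- withr::local_tempfile(fileext = ".json")
  reportToJSON(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("fthresh distributions export two rows per channel", {
  n <- 6
  before <- vector("list", n); after <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- makePhantom(c(64, 64), "squares", seed = i, pixelSize = 100)
    before[[i]] <- degradeImage(ph, twoSigma = 5, noiseModel = "poisson",
                                snr = 8, seed = i)
    after[[i]] <- degradeImage(ph, twoSigma = 0, noiseModel = "poisson",
                               snr = 50, seed = i)
  }
  ids <- sprintf("c%02d", seq_len(n))
  rep <- runBatchFRC(IonImageStack(before, ids), IonImageStack(after, ids))
  f <- withr::local_tempfile(fileext = ".csv")
  writeFthreshDistribution(rep, f)
  tab <- utils::read.csv(f)
  expect_equal(nrow(tab), 2L * n)
  expect_equal(unname(table(tab$id)), rep(2L, n), ignore_attr = TRUE)
  expect_setequal(unique(tab$group), c("before", "after"))
})
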