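# Batch orchestration: deconvolve or FRC-measure every channel of a
# stack and compare before/after with a one-sided Wilcoxon signed-rank
# test (widths should decrease, cutoff frequencies should increase).

emptyReportRows <- function(n, ids) {
  data.frame(id = ids,
             widthBefore = rep(NA_real_, n), widthAfter = rep(NA_real_, n),
             iterations = rep(NA_integer_, n),
             stopReason = rep(NA_character_, n),
             fthreshBefore = rep(NA_real_, n),
             fthreshAfter = rep(NA_real_, n),
             resolutionBefore = rep(NA_real_, n),
             resolutionAfter = rep(NA_real_, n),
             elapsed = rep(NA_real_, n),
             stringsAsFactors = FALSE)
}

#' Paired one-sided Wilcoxon signed-rank test
#'
#' Tests the alternative that `after` is shifted relative to `before`
#' (`"less"`: after < before, the deblurring direction for widths;
#' `"greater"`: after > before, the direction for FRC cutoffs).
#' Zero differences are dropped (Wilcoxon convention); the exact null
#' distribution is used for up to 25 informative pairs without ties, and
#' the normal approximation with tie and continuity correction otherwise.
#' The statistic is the sum of signed ranks of `after - before` above
#' zero, so perfect improvement under `"less"` gives statistic 0.
#'
#' @param before,after numeric vectors of equal length.
#' @param alternative direction of the alternative for `after` relative
#'   to `before`.
#' @return list with `statistic`, `pValue` and `nPairs` (pairs remaining
#'   after dropping zero differences).
#' @examples
#' pairedWilcoxonOneSided(before = 2:11, after = 1:10)  # statistic 0
#' @export
pairedWilcoxonOneSided <- function(before, after,
                                   alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(before) == length(after))
  ok <- is.finite(before) & is.finite(after)
  before <- before[ok]; after <- after[ok]
  d <- after - before
  d <- d[d != 0]
  if (!length(d))
    stop("degenerate data: all paired differences are zero, no test possible")
  n <- length(d)
  if (n < 5L)
    stop("need at least 5 informative pairs after dropping zero differences")
  r <- rank(abs(d))          # midranks under ties
  wPlus <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null distribution of W+ over all 2^n sign assignments,
    # computed on doubled midranks so tied ranks stay integral
    w2 <- as.integer(round(2 * r))
    counts <- rep(0, sum(w2) + 1L)
    counts[1L] <- 1
    for (k in w2) {
      shifted <- c(rep(0, k), counts[seq_len(length(counts) - k)])
      counts <- counts + shifted
    }
    obs <- as.integer(round(2 * wPlus))
    cum <- cumsum(counts)
    p <- if (alternative == "less") cum[obs + 1L] / 2^n
         else (2^n - if (obs >= 1L) cum[obs] else 0) / 2^n
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      d, mu = 0, alternative = alternative, exact = FALSE, correct = TRUE))
    p <- unname(wt$p.value)
  }
  list(statistic = wPlus, pValue = p, nPairs = n)
}

#' Deconvolve every image of a stack and test the width change
#'
#' Applies [autoDeconvolve()] to every channel, recording the estimated
#' blur width before and after and the per-image run time. Channels whose
#' width could not be estimated, or that were returned untouched by the
#' sub-pixel guard, are kept in the rows but excluded from the paired
#' test. The test is the one-sided Wilcoxon signed-rank with alternative
#' "width after < width before"; it is skipped (with a message) when
#' fewer than 5 informative pairs remain.
#'
#' @param stack a non-empty [IonImageStack-class].
#' @param ... passed to [autoDeconvolve()].
#' @return a [BatchReport-class]; the restored stack is attached in
#'   `reportRows()`'s attribute `"restored"`.
#' @export
runBatchDeconv <- function(stack, ...) {
  stopifnot(is(stack, "IonImageStack"))
  n <- length(stack)
  if (n == 0L) stop("stack must contain at least one image")
  rows <- emptyReportRows(n, channelIds(stack))
  restoredImgs <- vector("list", n)
  for (i in seq_len(n)) {
    t0 <- proc.time()[["elapsed"]]
    res <- autoDeconvolve(stack[[i]], ...)
    rows$elapsed[i] <- proc.time()[["elapsed"]] - t0
    tr <- widthTrajectory(res)
    rows$widthBefore[i] <- if (length(tr)) tr[1L] else NA_real_
    rows$widthAfter[i] <- if (length(tr) > 1L) min(tr[-1L]) else NA_real_
    rows$iterations[i] <- res@iterations
    rows$stopReason[i] <- stopReason(res)
    restoredImgs[[i]] <- restored(res)
    message(sprintf("channel %s: %s after %d iteration(s) in %.2f s",
                    channelIds(stack)[i], stopReason(res),
                    res@iterations, rows$elapsed[i]))
  }
  usable <- !is.na(rows$widthBefore) & !is.na(rows$widthAfter)
  stat <- NA_real_; p <- NA_real_; nPairs <- 0L
  if (sum(usable) >= 5L) {
    test <- tryCatch(
      pairedWilcoxonOneSided(rows$widthBefore[usable],
                             rows$widthAfter[usable],
                             alternative = "less"),
      error = function(e) {
        message("paired test skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(test)) {
      stat <- test$statistic; p <- test$pValue; nPairs <- test$nPairs
    }
  } else {
    message("paired test skipped: fewer than 5 images with estimable widths")
  }
  attr(rows, "restored") <- IonImageStack(restoredImgs, channelIds(stack))
  new("BatchReport", rows = rows, wilcoxonStatistic = stat, pValue = p,
      nPairs = as.integer(nPairs),
      direction = "widthAfter < widthBefore")
}

#' FRC-measure aligned before/after stacks and test the cutoff change
#'
#' Runs [singleImageResolution()] on every aligned channel pair and tests
#' the one-sided alternative "fthresh after > fthresh before" (higher
#' cutoff = better resolution) with the Wilcoxon signed-rank test.
#'
#' @param stackBefore,stackAfter [IonImageStack-class] objects aligned by
#'   channel (same length and channel ids).
#' @param ... passed to [singleImageResolution()].
#' @return a [BatchReport-class].
#' @export
runBatchFRC <- function(stackBefore, stackAfter, ...) {
  stopifnot(is(stackBefore, "IonImageStack"),
            is(stackAfter, "IonImageStack"))
  if (length(stackBefore) != length(stackAfter) ||
      !identical(channelIds(stackBefore), channelIds(stackAfter)))
    stop("stacks are misaligned: channel ids must match pairwise")
  n <- length(stackBefore)
  rows <- emptyReportRows(n, channelIds(stackBefore))
  for (i in seq_len(n)) {
    rb <- suppressWarnings(singleImageResolution(stackBefore[[i]], ...))
    ra <- suppressWarnings(singleImageResolution(stackAfter[[i]], ...))
    rows$fthreshBefore[i] <- cutoffFrequency(rb)
    rows$fthreshAfter[i] <- cutoffFrequency(ra)
    rows$resolutionBefore[i] <- resolutionValue(rb)
    rows$resolutionAfter[i] <- resolutionValue(ra)
  }
  test <- pairedWilcoxonOneSided(rows$fthreshBefore, rows$fthreshAfter,
                                 alternative = "greater")
  new("BatchReport", rows = rows, wilcoxonStatistic = test$statistic,
      pValue = test$pValue, nPairs = as.integer(test$nPairs),
      direction = "fthreshAfter > fthreshBefore")
}

#' Serialize a BatchReport to JSON (and back)
#'
#' The JSON report carries the per-image rows, the test statistic,
#' p-value, pair count and the alternative's direction; `reportFromJSON()`
#' reconstructs an identical [BatchReport-class], so the round trip is
#' lossless.
#'
#' @param report a [BatchReport-class].
#' @param path destination (source) file path.
#' @return `path` invisibly; `reportFromJSON()` returns the
#'   [BatchReport-class].
#' @export
reportToJSON <- function(report, path) {
  stopifnot(is(report, "BatchReport"))
  rows <- report@rows
  attr(rows, "restored") <- NULL
  obj <- list(rows = rows,
              wilcoxonStatistic = report@wilcoxonStatistic,
              pValue = report@pValue,
              nPairs = report@nPairs,
              direction = report@direction)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname reportToJSON
#' @export
reportFromJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- as.data.frame(obj$rows, stringsAsFactors = FALSE)
  proto <- emptyReportRows(nrow(rows), rows$id)
  for (nm in names(proto)) {
    if (is.null(rows[[nm]])) rows[[nm]] <- proto[[nm]]
    storage.mode(rows[[nm]]) <- storage.mode(proto[[nm]])
  }
  rows <- rows[names(proto)]
  new("BatchReport", rows = rows,
      wilcoxonStatistic = nullToNA(obj$wilcoxonStatistic),
      pValue = nullToNA(obj$pValue),
      nPairs = as.integer(obj$nPairs),
      direction = obj$direction)
}

nullToNA <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

#' Export per-channel cutoff frequencies for violin-style plots
#'
#' Writes a long-format CSV with exactly two rows per channel (`group`
#' "before" and "after") carrying `fthresh` and `resolution`; no outlier
#' filtering is applied to the data file.
#'
#' @param report a [BatchReport-class] from [runBatchFRC()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
writeFthreshDistribution <- function(report, path) {
  stopifnot(is(report, "BatchReport"))
  rows <- report@rows
  long <- rbind(
    data.frame(id = rows$id, group = "before",
               fthresh = rows$fthreshBefore,
               resolution = rows$resolutionBefore),
    data.frame(id = rows$id, group = "after",
               fthresh = rows$fthreshAfter,
               resolution = rows$resolutionAfter))
  long <- long[order(long$id, long$group, method = "radix"), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
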