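# Edge-based blur estimation: the width (2*sigma, pixels) of an assumed
# isotropic Gaussian PSF is read off intensity profiles perpendicular to
# automatically detected straight edges. The profile derivative is the
# line spread function (LSF); for a Gaussian-blurred step it is itself a
# Gaussian with the PSF's sigma.

#' Default configuration for the PSF-width estimator
#'
#' @param canny.low_pct,canny.high_pct hysteresis thresholds as percentiles
#'   of the positive gradient magnitudes (defaults 0.5 and 0.9).
#' @param canny.presmooth_sigma Gaussian presmoothing sigma in pixels
#'   before gradient computation (default 1).
#' @param hough.min_length minimum accepted segment length in pixels
#'   (default 10).
#' @param hough.max_gap maximum along-line gap in pixels before a segment
#'   is split (default 2).
#' @param hough.angle_res angular resolution of the Hough accumulator in
#'   degrees (default 1).
#' @param profile.half_length half-length of perpendicular profiles in
#'   pixels (default 8; must exceed the expected blur width).
#' @param profile.spacing spacing of profile anchor points along a segment
#'   in pixels (default 1).
#' @param fit.r2_min minimum goodness of fit R^2 for a profile fit to be
#'   accepted (default 0.5).
#' @param fit.min_fits minimum number of accepted fits for the image to
#'   count as estimable (default 3).
#' @param fit.aggregate `"mean"` (default, unweighted mean of accepted
#'   2*sigma values) or `"median"`.
#' @return a named list of configuration values.
#' @export
psfConfig <- function(canny.low_pct = 0.5, canny.high_pct = 0.9,
                      canny.presmooth_sigma = 1,
                      hough.min_length = 10, hough.max_gap = 2,
                      hough.angle_res = 1,
                      profile.half_length = 8, profile.spacing = 1,
                      fit.r2_min = 0.5, fit.min_fits = 3,
                      fit.aggregate = c("mean", "median")) {
  list(canny.low_pct = canny.low_pct, canny.high_pct = canny.high_pct,
       canny.presmooth_sigma = canny.presmooth_sigma,
       hough.min_length = hough.min_length, hough.max_gap = hough.max_gap,
       hough.angle_res = hough.angle_res,
       profile.half_length = profile.half_length,
       profile.spacing = profile.spacing,
       fit.r2_min = fit.r2_min, fit.min_fits = fit.min_fits,
       fit.aggregate = match.arg(fit.aggregate))
}

# Canny edge map: presmooth, Sobel gradients, non-maximum suppression,
# percentile-based hysteresis thresholds. Returns a logical matrix.
cannyEdges <- function(m, presmoothSigma = 1, lowPct = 0.5, highPct = 0.9) {
  if (presmoothSigma > 0) {
    ksize <- max(3L, 2L * ceiling(3 * presmoothSigma) + 1L)
    g <- kernelWeights(gaussianKernel(2 * presmoothSigma, size = ksize))
    m <- fftConv2(m, g, boundary = "reflect")
  }
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dcol
  sy <- t(sx)                                               # d/drow
  gx <- fftConv2(m, sx, boundary = "reflect", correlate = TRUE)
  gy <- fftConv2(m, sy, boundary = "reflect", correlate = TRUE)
  mag <- sqrt(gx^2 + gy^2)
  # suppress FFT round-off on flat regions (a constant image has no edges)
  mag[mag <= 1e-8 * max(abs(m))] <- 0
  nr <- nrow(m); nc <- ncol(m)

  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(gy, gx)                 # radians, direction of max change
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:col, 1:diag, 2:row, 3:anti-diag
  shiftMat <- function(x, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    out[okr, okc] <- x[rs[okr], cs[okc]]
    out
  }
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  nms <- matrix(FALSE, nr, nc)
  for (s in 0:3) {
    d <- offs[[as.character(s)]]
    fwd <- shiftMat(mag, d[1], d[2])
    bwd <- shiftMat(mag, -d[1], -d[2])
    nms <- nms | (sector == s & mag >= fwd & mag >= bwd)
  }
  cand <- mag * nms

  pos <- mag[mag > 0]
  if (!length(pos)) return(matrix(FALSE, nr, nc))
  lo <- stats::quantile(pos, lowPct, names = FALSE)
  hi <- stats::quantile(pos, highPct, names = FALSE)
  strong <- cand >= hi & cand > 0
  weak <- cand >= lo & cand > 0
  # hysteresis: grow strong edges through connected weak pixels
  edges <- strong
  repeat {
    grown <- edges
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | (weak & shiftMat(edges, dr, dc) > 0)
    }
    if (identical(grown, edges)) break
    edges <- grown
  }
  edges
}

#' Detect straight edge segments in an ion image
#'
#' Runs Canny edge detection (percentile-based hysteresis thresholds) on
#' the median-filled image, then extracts straight segments from the edge
#' map with a Hough line transform: accumulator peaks are taken greedily,
#' the edge pixels within one pixel of each peak line are ordered along
#' the line and split at gaps wider than `hough.max_gap`, and runs shorter
#' than `hough.min_length` are dropped.
#'
#' @param image an [IonImage-class] with at least 16 x 16 pixels.
#' @param config configuration list from [psfConfig()].
#' @return a data.frame of segments with columns `r0`, `c0`, `r1`, `c1`
#'   (endpoint coordinates, rows/cols), `angle` (orientation in degrees in
#'   \[0, 180)), and `length` (pixels). May have zero rows.
#' @export
detectEdgeSegments <- function(image, config = psfConfig()) {
  stopifnot(is(image, "IonImage"))
  m <- fillMissing(pixels(image), imageMask(image))
  if (sum(!imageMask(image)) < 256L)
    stop("image must contain at least 16 x 16 non-missing pixels")
  edges <- cannyEdges(m, config$canny.presmooth_sigma,
                      config$canny.low_pct, config$canny.high_pct)
  houghSegments(edges, minLength = config$hough.min_length,
                maxGap = config$hough.max_gap,
                angleRes = config$hough.angle_res)
}

emptySegments <- function() {
  data.frame(r0 = numeric(0), c0 = numeric(0), r1 = numeric(0),
             c1 = numeric(0), angle = numeric(0), length = numeric(0))
}

# Deterministic Hough line extraction from a logical edge map.
houghSegments <- function(edges, minLength = 10, maxGap = 2,
                          angleRes = 1, maxLines = 50L) {
  pts <- which(edges, arr.ind = TRUE)   # (row, col)
  segs <- emptySegments()
  if (nrow(pts) < minLength) return(segs)
  thetas <- seq(0, 180 - angleRes, by = angleRes) * pi / 180
  ct <- cos(thetas); st <- sin(thetas)
  active <- rep(TRUE, nrow(pts))

  for (iter in seq_len(maxLines)) {
    idx <- which(active)
    if (length(idx) < minLength) break
    P <- pts[idx, , drop = FALSE]
    # rho = col*cos(theta) + row*sin(theta); accumulator over (theta, rho)
    rho <- outer(P[, 2L], ct) + outer(P[, 1L], st)
    rhoBin <- round(rho)
    best <- c(0L, 0L, 0L)   # count, theta index, rho value
    for (t in seq_along(thetas)) {
      tb <- tabulate(rhoBin[, t] - min(rhoBin[, t]) + 1L)
      mx <- max(tb)
      if (mx > best[1L]) {
        best <- c(mx, t, which.max(tb) + min(rhoBin[, t]) - 1L)
      }
    }
    if (best[1L] < minLength) break
    t <- best[2L]; r0 <- best[3L]
    onLine <- abs(rho[, t] - r0) <= 1
    sel <- idx[onLine]
    # order along the line direction (-sin, cos) in (col,row) space
    tt <- -pts[sel, 2L] * st[t] + pts[sel, 1L] * ct[t]
    o <- order(tt)
    sel <- sel[o]; tt <- tt[o]
    gaps <- which(diff(tt) > maxGap)
    starts <- c(1L, gaps + 1L)
    ends <- c(gaps, length(tt))
    for (s in seq_along(starts)) {
      a <- starts[s]; b <- ends[s]
      len <- tt[b] - tt[a]
      if (len >= minLength) {
        p0 <- pts[sel[a], ]; p1 <- pts[sel[b], ]
        ang <- atan2(p1[1L] - p0[1L], p1[2L] - p0[2L]) * 180 / pi
        ang <- ang %% 180
        segs <- rbind(segs, data.frame(
          r0 = p0[1L], c0 = p0[2L], r1 = p1[1L], c1 = p1[2L],
          angle = ang, length = len))
      }
    }
    active[idx[onLine]] <- FALSE
  }
  rownames(segs) <- NULL
  segs
}

#' Extract intensity profiles perpendicular to an edge segment
#'
#' Anchors are placed along the segment at the configured spacing; at each
#' anchor the image is sampled by bilinear interpolation along the
#' perpendicular direction at unit steps, giving a profile of length
#' `2 * halfLength + 1`. Profiles that would leave the image bounds or
#' cross missing pixels are skipped.
#'
#' @param image an [IonImage-class].
#' @param segment one row of the data.frame returned by
#'   [detectEdgeSegments()] (or any list with `r0`, `c0`, `r1`, `c1`).
#' @param halfLength profile half-length in pixels (>= 3).
#' @param spacing anchor spacing along the segment in pixels; a spacing
#'   larger than the segment yields a single profile at the segment start.
#' @return a list of numeric profiles (possibly empty).
#' @export
extractProfiles <- function(image, segment, halfLength = 8, spacing = 1) {
  stopifnot(is(image, "IonImage"), halfLength >= 3)
  m <- pixels(image)
  msk <- imageMask(image)
  nr <- nrow(m); nc <- ncol(m)
  p0 <- c(segment$r0, segment$c0)
  p1 <- c(segment$r1, segment$c1)
  L <- sqrt(sum((p1 - p0)^2))
  u <- if (L > 0) (p1 - p0) / L else c(0, 1)
  v <- c(-u[2L], u[1L])                       # perpendicular
  ts <- if (spacing > L) 0 else seq(0, L, by = spacing)
  offs <- seq(-halfLength, halfLength)
  profiles <- list()
  for (t in ts) {
    anchor <- p0 + t * u
    rs <- anchor[1L] + offs * v[1L]
    cs <- anchor[2L] + offs * v[2L]
    if (any(rs < 1 | rs > nr | cs < 1 | cs > nc)) next
    # reject profiles whose interpolation stencil touches missing pixels
    r0i <- floor(rs); c0i <- floor(cs)
    touch <- msk[cbind(pmin(r0i, nr), pmin(c0i, nc))] |
      msk[cbind(pmin(r0i + 1, nr), pmin(c0i, nc))] |
      msk[cbind(pmin(r0i, nr), pmin(c0i + 1, nc))] |
      msk[cbind(pmin(r0i + 1, nr), pmin(c0i + 1, nc))]
    if (any(touch)) next
    profiles[[length(profiles) + 1L]] <- bilinear(m, rs, cs)
  }
  profiles
}

#' Fit a Gaussian line spread function to one edge profile
#'
#' The profile is differentiated by central differences; the dominant
#' lobe's sign is flipped to positive and a Gaussian
#' `A * exp(-(x - mu)^2 / (2 * sigma^2))` is fitted by nonlinear least
#' squares (Levenberg-Marquardt), initialized from the lobe's moments.
#' The fitted sigma is corrected for the variance added by the
#' central-difference kernel (1/3 px^2) so that a step blurred with
#' Gaussian sigma recovers sigma itself. A fit is accepted when
#' `R^2 > r2Min` and sigma is finite and positive.
#'
#' @param profile numeric vector of length >= 7.
#' @param r2Min acceptance threshold on R^2 (default 0.5).
#' @return one-row data.frame with `amplitude`, `center` (profile
#'   coordinates, pixels), `sigma` (pixels), `rSquared` (`-Inf` when the
#'   fit failed) and `accepted`.
#' @export
fitLSF <- function(profile, r2Min = 0.5) {
  stopifnot(length(profile) >= 7)
  n <- length(profile)
  x <- seq(2L, n - 1L)
  d <- (profile[x + 1L] - profile[x - 1L]) / 2
  rejected <- data.frame(amplitude = NA_real_, center = NA_real_,
                         sigma = NA_real_, rSquared = -Inf,
                         accepted = FALSE)
  if (all(d == 0) || !all(is.finite(d))) return(rejected)
  s <- sign(d[which.max(abs(d))])
  a <- s * d
  w <- pmax(a, 0)
  if (sum(w) <= 0) return(rejected)
  amp0 <- max(a)
  c0 <- sum(x * w) / sum(w)
  sig0 <- sqrt(sum(w * (x - c0)^2) / sum(w))
  if (!is.finite(sig0) || sig0 < 0.5) sig0 <- 0.5
  fit <- tryCatch(
    minpack.lm::nlsLM(
      a ~ A * exp(-(x - mu)^2 / (2 * sg^2)),
      start = list(A = amp0, mu = c0, sg = sig0),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(rejected)
  co <- stats::coef(fit)
  sigFit <- abs(co[["sg"]])
  ssRes <- sum(stats::resid(fit)^2)
  ssTot <- sum((a - mean(a))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else -Inf
  # remove the broadening of the central-difference kernel (variance 1/3)
  sigma <- sqrt(max(sigFit^2 - 1 / 3, 1e-4))
  accepted <- is.finite(r2) && r2 > r2Min && is.finite(sigma) && sigma > 0
  data.frame(amplitude = co[["A"]], center = co[["mu"]], sigma = sigma,
             rSquared = r2, accepted = accepted)
}

#' Estimate the blur width (2*sigma) of an image from its edges
#'
#' Pipeline: [detectEdgeSegments()] on the image, [extractProfiles()]
#' perpendicular to each segment, [fitLSF()] on every profile. The blur
#' width is the unweighted mean of `2 * sigma` over accepted fits
#' (R^2 > 0.5). At least `fit.min_fits` accepted fits are required;
#' otherwise a `notEstimableError` condition is signalled — images without
#' clearly defined edges (or with too low SNR) cannot be deconvolved.
#'
#' @param image an [IonImage-class].
#' @param config configuration list from [psfConfig()].
#' @return a [PSFEstimate-class].
#' @examples
#' ph <- makePhantom(c(64, 64), "squares", seed = 1)
#' blurred <- degradeImage(ph, twoSigma = 4)
#' est <- estimatePSFWidth(blurred)
#' twoSigma(est)
#' @export
estimatePSFWidth <- function(image, config = psfConfig()) {
  segs <- detectEdgeSegments(image, config)
  fits <- emptyFits()
  if (nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      prof <- extractProfiles(image, segs[i, ],
                              halfLength = config$profile.half_length,
                              spacing = config$profile.spacing)
      for (p in prof) fits <- rbind(fits, fitLSF(p, config$fit.r2_min))
    }
  }
  acc <- fits[fits$accepted, , drop = FALSE]
  if (nrow(acc) < config$fit.min_fits) stopNotEstimable()
  agg <- if (config$fit.aggregate == "median") stats::median else mean
  new("PSFEstimate", twoSigma = agg(2 * acc$sigma),
      nAccepted = nrow(acc), nTotal = nrow(fits), fits = fits)
}

emptyFits <- function() {
  data.frame(amplitude = numeric(0), center = numeric(0),
             sigma = numeric(0), rSquared = numeric(0),
             accepted = logical(0))
}

#' Build an isotropic Gaussian PSF kernel from a blur width
#'
#' The kernel's standard deviation is `twoSigma / 2`, sampled on an
#' odd-sized square grid and normalized to sum exactly 1. The default
#' size is the smallest odd integer >= `3 * twoSigma` (at least 3), which
#' captures > 99.7% of the Gaussian mass.
#'
#' @param twoSigma blur width 2*sigma in pixels (> 0).
#' @param size odd kernel side length; computed from `twoSigma` when
#'   missing.
#' @return a [PSFKernel-class].
#' @export
gaussianKernel <- function(twoSigma, size = NULL) {
  if (!is.finite(twoSigma) || twoSigma <= 0)
    stop("twoSigma must be a positive finite blur width")
  sd <- twoSigma / 2
  if (is.null(size)) {
    size <- max(3L, ceiling(3 * twoSigma))
    if (size %% 2L == 0L) size <- size + 1L
  }
  if (size %% 2L == 0L) stop("kernel size must be odd")
  half <- (size - 1L) / 2L
  off <- seq(-half, half)
  g1 <- exp(-off^2 / (2 * sd^2))
  k <- outer(g1, g1)
  PSFKernel(k / sum(k))
}
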