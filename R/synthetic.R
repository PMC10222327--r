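# Ground-truth phantom and degradation generator: piecewise-constant
# objects with known straight edges, blurred with a known Gaussian PSF,
# corrupted with Poisson or Gaussian noise at a target peak SNR, and
# optionally punched with missing pixels. Everything is deterministic
# under a fixed seed, so estimators and restorers can be tested against
# known truth without any external data.

#' Generate a piecewise-constant phantom image
#'
#' Phantoms contain straight-edged shapes (with edges at least 15 px long
#' so the default Hough configuration can find them) at the given
#' intensity levels on a zero background. The ground-truth list of
#' straight edge segments is stored in `metadata(image)$edges` for oracle
#' tests; discs contribute no straight edges.
#'
#' Kinds: `"squares"` places one large and one smaller axis-aligned
#' square; `"discs"` places two filled discs; `"stripes"` draws vertical
#' bars of known period; `"mixed"` combines an axis-aligned square, a
#' 45-degree-rotated square (diamond) and a disc.
#'
#' @param shape integer vector `c(rows, cols)`, both >= 32.
#' @param kind one of `"squares"`, `"discs"`, `"stripes"`, `"mixed"`.
#' @param intensityLevels positive intensity levels cycled over the
#'   shapes (default 100).
#' @param seed integer seed controlling the (small) placement jitter.
#' @param pixelSize optional pixel size in micrometres.
#' @return an [IonImage-class] with ground-truth metadata (`kind`,
#'   `seed`, `edges`, and `period` for stripes).
#' @export
makePhantom <- function(shape = c(64L, 64L),
                        kind = c("squares", "discs", "stripes", "mixed"),
                        intensityLevels = 100, seed = 0L,
                        pixelSize = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(length(shape) == 2L, all(shape >= 32L),
            all(intensityLevels > 0))
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  m <- matrix(0, nr, nc)
  edges <- emptySegments()
  lvl <- function(i) intensityLevels[((i - 1L) %% length(intensityLevels)) + 1L]
  meta <- list(kind = kind, seed = seed)

  withSeed(seed, {
    if (kind %in% c("squares", "mixed")) {
      # one large, roughly centred square; seeded jitter moves it a few
      # pixels so batches are not pixel-identical
      side <- max(15L, min(nr, nc) %/% 2L - if (kind == "mixed") 4L else 0L)
      if (kind == "mixed") {
        # keep the square in the upper-left so the diamond and disc have room
        baseR <- 5L
        baseC <- 5L
      } else {
        baseR <- 1L + (nr - side) %/% 2L
        baseC <- 1L + (nc - side) %/% 2L
      }
      jit <- max(0L, min(4L, min(baseR, baseC) - 2L))
      r0 <- baseR + sample.int(2L * jit + 1L, 1L) - jit - 1L
      c0 <- baseC + sample.int(2L * jit + 1L, 1L) - jit - 1L
      m[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- lvl(1L)
      r1 <- r0 + side - 1L; c1 <- c0 + side - 1L
      edges <- rbind(edges,
        data.frame(r0 = c(r0, r1, r0, r0), c0 = c(c0, c0, c0, c1),
                   r1 = c(r0, r1, r1, r1), c1 = c(c1, c1, c0, c1),
                   angle = c(0, 0, 90, 90),
                   length = rep(side - 1L, 4L)))
    }
    if (kind == "discs") {
      for (i in 1:2) {
        rad <- max(8L, min(nr, nc) %/% 6L)
        ctr <- c(sample.int(nr - 2L * rad, 1L) + rad,
                 sample.int(nc - 2L * rad, 1L) + rad)
        dist2 <- outer((seq_len(nr) - ctr[1L])^2,
                       (seq_len(nc) - ctr[2L])^2, `+`)
        m[dist2 <= rad^2] <- lvl(i)
      }
    }
    if (kind == "stripes") {
      period <- max(16L, 2L * (nc %/% 8L))
      half <- period %/% 2L
      phase <- sample.int(half, 1L) - 1L
      on <- ((seq_len(nc) - 1L + phase) %% period) < half
      m[, on] <- lvl(1L)
      meta$period <- period
      bounds <- which(diff(c(on[1L], on)) != 0)
      if (length(bounds))
        edges <- rbind(edges, data.frame(
          r0 = 1L, c0 = bounds, r1 = nr, c1 = bounds,
          angle = 90, length = nr - 1L))
    }
    if (kind == "mixed") {
      # 45-degree diamond in the emptiest quadrant, plus a small disc
      half <- 10L
      ctr <- c(nr - half - 6L, nc - half - 6L)
      dist1 <- outer(abs(seq_len(nr) - ctr[1L]),
                     abs(seq_len(nc) - ctr[2L]), `+`)
      m[dist1 <= half & m == 0] <- lvl(2L)
      edges <- rbind(edges, data.frame(
        r0 = c(ctr[1L] - half, ctr[1L], ctr[1L] + half, ctr[1L]),
        c0 = c(ctr[2L], ctr[2L] + half, ctr[2L], ctr[2L] - half),
        r1 = c(ctr[1L], ctr[1L] + half, ctr[1L], ctr[1L] - half),
        c1 = c(ctr[2L] + half, ctr[2L], ctr[2L] - half, ctr[2L]),
        angle = c(45, 135, 45, 135),
        length = rep(sqrt(2) * half, 4L)))
      rad <- 6L
      dist2 <- outer((seq_len(nr) - (rad + 5L))^2,
                     (seq_len(nc) - (nc - rad - 5L))^2, `+`)
      m[dist2 <= rad^2 & m == 0] <- lvl(3L)
    }
  })
  meta$edges <- edges
  IonImage(m, pixelSize = pixelSize, metadata = meta)
}

#' Degrade a clean object into a blurred, noisy, gappy observation
#'
#' Applies the linear imaging model `I = O (x) h + N`: convolution with an
#' isotropic Gaussian PSF of width `twoSigma` (skipped when 0), additive
#' or Poisson noise scaled to a target peak SNR, and uniform random
#' dropout of pixels into the missing mask. Peak SNR is defined as the
#' maximum clean (blurred) intensity divided by the noise standard
#' deviation at that intensity; for Poisson noise the counts are scaled so
#' that `sqrt(peak counts) = snr`.
#'
#' @param object a clean [IonImage-class].
#' @param twoSigma true blur width in pixels (>= 0).
#' @param noiseModel `"none"`, `"poisson"` or `"gaussian"`.
#' @param snr target peak signal-to-noise ratio (> 0 when noise is
#'   applied).
#' @param dropoutFraction fraction in \[0, 1) of pixels set missing.
#' @param seed integer seed; the output is fully deterministic given the
#'   seed.
#' @param boundary convolution boundary handling; `"periodic"` conserves
#'   total intensity exactly.
#' @return the degraded [IonImage-class]; ground truth (`trueTwoSigma`,
#'   noise settings) is recorded in its metadata.
#' @export
degradeImage <- function(object, twoSigma = 0,
                         noiseModel = c("none", "poisson", "gaussian"),
                         snr = 20, dropoutFraction = 0, seed = 0L,
                         boundary = c("reflect", "periodic")) {
  stopifnot(is(object, "IonImage"), twoSigma >= 0)
  noiseModel <- match.arg(noiseModel)
  boundary <- match.arg(boundary)
  if (dropoutFraction < 0 || dropoutFraction >= 1)
    stop("dropoutFraction must lie in [0, 1)")
  if (noiseModel != "none" && snr <= 0)
    stop("snr must be positive when noise is applied")
  m <- pixels(object)
  if (twoSigma > 0) {
    k <- kernelWeights(gaussianKernel(twoSigma))
    m <- fftConv2(m, k, boundary = boundary)
    m <- pmax(m, 0)
  }
  peak <- max(m)
  withSeed(seed, {
    if (noiseModel == "poisson" && peak > 0) {
      scale <- snr^2 / peak
      m <- matrix(stats::rpois(length(m), lambda = m * scale) / scale,
                  nrow(m), ncol(m))
    } else if (noiseModel == "gaussian" && peak > 0) {
      m <- m + matrix(stats::rnorm(length(m), sd = peak / snr),
                      nrow(m), ncol(m))
      m <- pmax(m, 0)
    }
    mask <- imageMask(object)
    nDrop <- round(dropoutFraction * length(m))
    if (nDrop > 0) {
      drop <- sample.int(length(m), nDrop)
      mask[drop] <- TRUE
    }
    meta <- object@metadata
    meta$trueTwoSigma <- twoSigma
    meta$noiseModel <- noiseModel
    meta$snr <- if (noiseModel == "none") NA_real_ else snr
    meta$dropoutFraction <- dropoutFraction
    IonImage(m, pixelSize = pixelSize(object), mz = mzValue(object),
             mask = mask, metadata = meta)
  })
}

#' Simulate a batch of degraded phantom images with ground truth
#'
#' Generates `n` independent degraded ion images (per-image seeds derived
#' as `seed + i - 1` for both phantom placement and noise) together with a
#' sidecar table of the true blur per image.
#'
#' @param n number of images (>= 1).
#' @param shape,kind,intensityLevels passed to [makePhantom()].
#' @param twoSigma,noiseModel,snr,dropoutFraction passed to
#'   [degradeImage()].
#' @param seed base seed.
#' @param pixelSize optional pixel size in micrometres.
#' @return a list with `stack` (an [IonImageStack-class] of degraded
#'   images), `clean` (the matching stack of clean phantoms) and `truth`
#'   (data.frame with `id`, `seed`, `trueTwoSigma`).
#' @export
simulateBatch <- function(n, shape = c(64L, 64L), kind = "squares",
                          intensityLevels = 100, twoSigma = 4,
                          noiseModel = "poisson", snr = 20,
                          dropoutFraction = 0, seed = 0L,
                          pixelSize = NA_real_) {
  stopifnot(n >= 1)
  degraded <- vector("list", n)
  clean <- vector("list", n)
  for (i in seq_len(n)) {
    si <- seed + i - 1L
    ph <- makePhantom(shape, kind, intensityLevels, seed = si,
                      pixelSize = pixelSize)
    clean[[i]] <- ph
    degraded[[i]] <- degradeImage(ph, twoSigma = twoSigma,
                                  noiseModel = noiseModel, snr = snr,
                                  dropoutFraction = dropoutFraction,
                                  seed = si)
  }
  ids <- sprintf("sim%03d", seq_len(n))
  list(stack = IonImageStack(degraded, ids),
       clean = IonImageStack(clean, ids),
       truth = data.frame(id = ids, seed = seed + seq_len(n) - 1L,
                          trueTwoSigma = twoSigma))
}
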