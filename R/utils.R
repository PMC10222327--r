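# Internal numerical helpers: FFT convolution with boundary handling,
# interpolation, seeded evaluation, missing-pixel fill.

rot180 <- function(k) k[nrow(k):1, ncol(k):1, drop = FALSE]

# Symmetric (mirror) padding by pr rows / pc cols on each side.
# Requires pad smaller than the matrix extent.
mirrorPad <- function(x, pr, pc) {
  nr <- nrow(x); nc <- ncol(x)
  if (pr >= nr || pc >= nc)
    stop("kernel too large for image: padding exceeds image extent")
  ri <- c(if (pr > 0) pr:1, seq_len(nr), if (pr > 0) nr:(nr - pr + 1))
  ci <- c(if (pc > 0) pc:1, seq_len(nc), if (pc > 0) nc:(nc - pc + 1))
  x[ri, ci, drop = FALSE]
}

# 2-D convolution of image x with small odd-sized kernel k via FFT.
# boundary "reflect" mirror-pads before a circular convolution and crops;
# "periodic" convolves circularly on the original grid.
# correlate = TRUE computes cross-correlation (kernel rotated 180 deg).
fftConv2 <- function(x, k, boundary = c("reflect", "periodic"),
                     correlate = FALSE) {
  boundary <- match.arg(boundary)
  if (correlate) k <- rot180(k)
  kr <- nrow(k); kc <- ncol(k)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  xp <- if (boundary == "reflect") mirrorPad(x, pr, pc) else x
  nr <- nrow(xp); nc <- ncol(xp)
  if (kr > nr || kc > nc)
    stop("kernel larger than image")
  kp <- matrix(0, nr, nc)
  kp[((-pr:pr) %% nr) + 1L, ((-pc:pc) %% nc) + 1L] <- k
  y <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) /
    (nr * nc)
  if (boundary == "reflect")
    y <- y[pr + seq_len(nrow(x)), pc + seq_len(ncol(x)), drop = FALSE]
  y
}

# Cross-correlation patch: C[m] = sum_u a[u] b[u + m] for integer lags
# m in [-pr, pr] x [-pc, pc]; used by the blind PSF update where a is the
# current object estimate and b the RL ratio image.
crossCorrPatch <- function(a, b, pr, pc,
                           boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  if (boundary == "reflect") {
    a <- mirrorPad(a, pr, pc)
    b <- mirrorPad(b, pr, pc)
  }
  nr <- nrow(a); nc <- ncol(a)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b),
                      inverse = TRUE)) / (nr * nc)
  cc[((-pr:pr) %% nr) + 1L, ((-pc:pc) %% nc) + 1L, drop = FALSE]
}

# Vectorized bilinear interpolation of matrix x at fractional (row, col)
# positions. Positions must lie within [1, nrow] x [1, ncol].
bilinear <- function(x, r, c) {
  nr <- nrow(x); nc <- ncol(x)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  x[i00] * (1 - fr) * (1 - fc) + x[i10] * fr * (1 - fc) +
    x[i01] * (1 - fr) * fc + x[i11] * fr * fc
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Replace masked pixels by the median of their non-missing neighbours in a
# growing square window (3x3, then 5x5, ...) so isolated holes and small
# clusters are both filled. Returns a plain matrix.
fillMissing <- function(pixels, mask) {
  if (!any(mask)) return(pixels)
  x <- pixels
  x[mask] <- NA_real_
  nr <- nrow(x); nc <- ncol(x)
  todo <- which(mask, arr.ind = TRUE)
  for (half in 1:max(nr, nc)) {
    if (nrow(todo) == 0L) break
    filled <- rep(NA_real_, nrow(todo))
    for (i in seq_len(nrow(todo))) {
      r <- todo[i, 1L]; cc <- todo[i, 2L]
      rs <- max(1L, r - half):min(nr, r + half)
      cs <- max(1L, cc - half):min(nc, cc + half)
      nb <- x[rs, cs]
      nb <- nb[!is.na(nb)]
      if (length(nb)) filled[i] <- stats::median(nb)
    }
    done <- !is.na(filled)
    if (any(done)) x[todo[done, , drop = FALSE]] <- filled[done]
    todo <- todo[!done, , drop = FALSE]
  }
  x[is.na(x)] <- 0
  x
}

# 1-D Tukey (tapered cosine) window of length n with taper fraction alpha.
tukeyWindow <- function(n, alpha = 0.25) {
  if (n == 1L) return(1)
  if (alpha <= 0) return(rep(1, n))
  k <- seq(0, n - 1)
  w <- rep(1, n)
  edge <- alpha * (n - 1) / 2
  lo <- k < edge
  hi <- k > (n - 1) * (1 - alpha / 2)
  w[lo] <- 0.5 * (1 + cos(pi * (k[lo] / edge - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((k[hi] - (n - 1) * (1 - alpha / 2)) / edge)))
  w
}

stopNotEstimable <- function(msg =
    "image not deconvolvable: insufficient edge evidence") {
  stop(errorCondition(msg,
                      class = c("notEstimableError", "error", "condition")))
}
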