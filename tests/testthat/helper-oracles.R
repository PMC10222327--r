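# Independent oracles used across test files. These deliberately avoid the
# package's FFT code paths: explicit loops, explicit enumeration.

# Brute-force Richardson-Lucy update: loops, no FFT.
# boundary "reflect" mirrors indices at the borders; "periodic" wraps.
bruteRLUpdate <- function(e, k, o, boundary = "reflect") {
  nr <- nrow(e); nc <- ncol(e)
  kr <- nrow(k); kc <- ncol(k)
  pr <- (kr - 1) %/% 2; pc <- (kc - 1) %/% 2
  wrap <- function(i, n) {
    if (boundary == "periodic") return(((i - 1) %% n) + 1)
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  conv <- function(x, kern) {
    out <- matrix(0, nr, nc)
    for (i in 1:nr) for (j in 1:nc) {
      s <- 0
      for (a in -pr:pr) for (b in -pc:pc)
        s <- s + kern[a + pr + 1, b + pc + 1] *
          x[wrap(i - a, nr), wrap(j - b, nc)]
      out[i, j] <- s
    }
    out
  }
  denom <- conv(e, k)
  ratio <- o / pmax(denom, 1e-12)
  krot <- k[kr:1, kc:1, drop = FALSE]
  pmax(e * conv(ratio, krot), 0)
}

# Exhaustive one-sided Wilcoxon signed-rank p-value by enumerating every
# sign assignment (n <= ~15).
bruteWilcoxonP <- function(before, after, alternative = "less") {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1, function(s) sum(r[s]))
  if (alternative == "less") mean(ws <= wObs + 1e-12)
  else mean(ws >= wObs - 1e-12)
}

# Brute-force FRC ring values via explicit DFT loops on a small image pair.
bruteFRC <- function(a, b) {
  nr <- nrow(a); nc <- ncol(a)
  am <- a - mean(a); bm <- b - mean(b)
  dft <- function(x) {
    X <- matrix(complex(real = 0), nr, nc)
    for (u in 0:(nr - 1)) for (v in 0:(nc - 1)) {
      s <- 0 + 0i
      for (i in 0:(nr - 1)) for (j in 0:(nc - 1))
        s <- s + x[i + 1, j + 1] *
          exp(-2i * pi * (u * i / nr + v * j / nc))
      X[u + 1, v + 1] <- s
    }
    X
  }
  FA <- dft(am); FB <- dft(bm)
  nbins <- floor(min(nr, nc) / 2)
  num <- pa <- pb <- cnt <- numeric(nbins)
  for (u in 0:(nr - 1)) for (v in 0:(nc - 1)) {
    fu <- if (u > nr / 2) u - nr else u
    fv <- if (v > nc / 2) v - nc else v
    r <- sqrt((2 * fu / nr)^2 + (2 * fv / nc)^2)
    ring <- round(r * nbins)
    if (ring >= 1 && ring <= nbins) {
      z <- FA[u + 1, v + 1] * Conj(FB[u + 1, v + 1])
      num[ring] <- num[ring] + Re(z)
      pa[ring] <- pa[ring] + Mod(FA[u + 1, v + 1])^2
      pb[ring] <- pb[ring] + Mod(FB[u + 1, v + 1])^2
      cnt[ring] <- cnt[ring] + 1
    }
  }
  keep <- cnt > 0
  list(values = (num / sqrt(pa * pb))[keep], n = cnt[keep],
       freqs = (seq_len(nbins) / nbins)[keep])
}

# A reproducible blurred/noisy observation of the standard square phantom.
makeObservation <- function(twoSigma = 4, snr = 20, seed = 0,
                            shape = c(64L, 64L), noise = "poisson",
                            pixelSize = NA_real_) {
  ph <- makePhantom(shape, "squares", seed = seed, pixelSize = pixelSize)
  degradeImage(ph, twoSigma = twoSigma, noiseModel = noise, snr = snr,
               seed = seed)
}
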