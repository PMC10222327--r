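#' Read an ion image from a CSV/TSV matrix or grayscale TIFF/PNG
#'
#' CSV/TSV files are parsed as headerless numeric matrices; empty cells or
#' `NA` entries become missing pixels (recorded in the mask, never as
#' sentinel intensities). TIFF images are read losslessly at their native
#' integer scale; PNG values are rescaled to the integer range of their
#' bit depth. Negative intensities are clipped to 0 with a warning.
#'
#' @param path path to a `.csv`, `.tsv`/`.txt`, `.tif`/`.tiff` or `.png`
#'   file.
#' @param pixelSize pixel side length in micrometres (optional; required
#'   later for physical-unit resolution).
#' @param mz optional m/z label for the channel.
#' @return an [IonImage-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.table(matrix(1:9, 3, 3), f, sep = ",",
#'             row.names = FALSE, col.names = FALSE)
#' readIonImage(f, pixelSize = 100)
#' @export
readIonImage <- function(path, pixelSize = NA_real_, mz = NA_real_) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: file '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv", "txt")) {
    sep <- if (ext == "csv") "," else "\t"
    m <- readDelimMatrix(path, sep)
  } else if (ext %in% c("tif", "tiff")) {
    m <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e)
                    stop(sprintf("cannot read TIFF '%s': %s", path,
                                 conditionMessage(e))))
    if (length(dim(m)) == 3L) {
      if (dim(m)[3L] == 1L) m <- m[, , 1L]
      else stop(sprintf("'%s' is not a grayscale image", path))
    }
  } else if (ext == "png") {
    m <- tryCatch(png::readPNG(path, info = TRUE),
                  error = function(e)
                    stop(sprintf("cannot read PNG '%s': %s", path,
                                 conditionMessage(e))))
    info <- attr(m, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    if (length(dim(m)) == 3L) {
      if (dim(m)[3L] == 1L) m <- m[, , 1L]
      else stop(sprintf("'%s' is not a grayscale image", path))
    }
    m <- m * (2^depth - 1)
  } else {
    stop(sprintf("unsupported image format '%s' for '%s'", ext, path))
  }
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  neg <- is.finite(m) & m < 0
  if (any(neg)) {
    warning(sprintf("%d negative intensities clipped to 0 in '%s'",
                    sum(neg), path))
    m[neg] <- 0
  }
  IonImage(m, pixelSize = pixelSize, mz = mz)
}

# Strict rectangular delimited-matrix parser: empty fields / NA -> missing,
# ragged rows -> shape error (read.csv's fill= would silently pad).
readDelimMatrix <- function(path, sep) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop(sprintf("cannot read image: '%s' contains no data", path))
  fields <- strsplit(lines, sep, fixed = TRUE)
  nfield <- lengths(fields)
  if (length(unique(nfield)) != 1L)
    stop(sprintf("non-rectangular matrix in '%s': rows have %s fields",
                 path, paste(sort(unique(nfield)), collapse = "/")))
  vals <- suppressWarnings(
    vapply(fields, function(f) {
      f <- trimws(f)
      f[f == ""] <- NA_character_
      as.numeric(f)
    }, numeric(nfield[1L]))
  )
  if (is.matrix(vals)) t(vals) else matrix(vals, nrow = length(fields))
}

#' Write an ion image to CSV or 32-bit float TIFF
#'
#' CSV output is lossless and round-trips exactly (missing pixels are
#' written as empty cells). TIFF output stores 32-bit floats; because the
#' TIFF writer requires values in \[0, 1\], intensities above 1 are scaled
#' by the image maximum with a warning.
#'
#' @param image an [IonImage-class].
#' @param path destination path; format chosen by extension (`.csv`,
#'   `.tsv`, `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
writeIonImage <- function(image, path) {
  stopifnot(is(image, "IonImage"))
  ext <- tolower(tools::file_ext(path))
  m <- pixels(image)
  if (ext %in% c("csv", "tsv")) {
    m[imageMask(image)] <- NA_real_
    utils::write.table(m, path, sep = if (ext == "csv") "," else "\t",
                       row.names = FALSE, col.names = FALSE, na = "")
  } else if (ext %in% c("tif", "tiff")) {
    mx <- max(m)
    if (mx > 1) {
      warning(sprintf(
        "TIFF stores [0,1]; intensities scaled by image maximum %g", mx))
      m <- m / mx
    }
    tiff::writeTIFF(m, path, bits.per.sample = 32L)
  } else {
    stop(sprintf("unsupported output format '%s'", ext))
  }
  invisible(path)
}

#' Select the channels with the highest total intensity
#'
#' Ranks channels of a stack by their summed (non-missing) intensity and
#' keeps the top `n`, in descending order. When an off-tissue background
#' mask is supplied, channels whose on-mask share of total intensity
#' exceeds `backgroundMaxFraction` are excluded before ranking — a simple
#' stand-in for tissue/background discrimination.
#'
#' @param stack an [IonImageStack-class].
#' @param n number of channels to keep (>= 1).
#' @param backgroundMask optional logical matrix (image dimensions) marking
#'   off-tissue pixels.
#' @param backgroundMaxFraction maximum tolerated fraction of a channel's
#'   intensity falling on the background mask (default 0.5).
#' @return an [IonImageStack-class] with at most `n` channels, ordered by
#'   decreasing total intensity.
#' @export
selectTopIonImages <- function(stack, n, backgroundMask = NULL,
                               backgroundMaxFraction = 0.5) {
  stopifnot(is(stack, "IonImageStack"), n >= 1)
  totals <- vapply(images(stack), function(im) {
    sum(pixels(im)[!imageMask(im)])
  }, numeric(1))
  keep <- rep(TRUE, length(totals))
  if (!is.null(backgroundMask)) {
    bg <- vapply(images(stack), function(im) {
      p <- pixels(im); msk <- imageMask(im)
      tot <- sum(p[!msk])
      if (tot <= 0) return(1)
      sum(p[backgroundMask & !msk]) / tot
    }, numeric(1))
    keep <- bg <= backgroundMaxFraction
  }
  idx <- which(keep)
  # stable, order-invariant ranking: ties broken by channel id
  ord <- idx[order(-totals[idx], channelIds(stack)[idx])]
  if (n > length(ord)) {
    warning(sprintf("requested %d channels but only %d available", n,
                    length(ord)))
    n <- length(ord)
  }
  sel <- ord[seq_len(n)]
  new("IonImageStack", images = images(stack)[sel],
      channelIds = channelIds(stack)[sel])
}
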