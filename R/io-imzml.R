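# Minimal imzML 1.1 (+ibd) support: enough to round-trip synthetic MSI
# datasets and to extract per-ion images from continuous- or
# processed-mode files. Binary arrays are addressed through the external
# offset / array length cvParams, which covers both modes uniformly.

IMZML_CV <- c(
  uuid = "IMS:1000080", processed = "IMS:1000031", continuous = "IMS:1000030",
  maxX = "IMS:1000042", maxY = "IMS:1000043",
  pixelX = "IMS:1000046", pixelY = "IMS:1000047",
  posX = "IMS:1000050", posY = "IMS:1000051",
  offset = "IMS:1000102", arrayLength = "IMS:1000103",
  encodedLength = "IMS:1000104", external = "IMS:1000101",
  mzArray = "MS:1000514", intensityArray = "MS:1000515",
  float64 = "MS:1000523", float32 = "MS:1000521",
  noCompression = "MS:1000576"
)

# Parse an imzML file into a plain structure:
# list(nrow, ncol, pixelSize, spectra = list(list(x, y, mz, intensity)))
readImzML <- function(path) {
  if (!file.exists(path))
    stop(sprintf("imzML file '%s' does not exist", path))
  ibdPath <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibdPath, path)) ibdPath <- paste0(path, ".ibd")
  if (!file.exists(ibdPath))
    stop(sprintf("ibd file '%s' does not exist", ibdPath))
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  cvValue <- function(node, accession) {
    n <- xml2::xml_find_first(node, sprintf(
      ".//cvParam[@accession='%s']", accession))
    if (inherits(n, "xml_missing")) NA_character_
    else xml2::xml_attr(n, "value")
  }
  hasCv <- function(node, accession) {
    !inherits(xml2::xml_find_first(node, sprintf(
      ".//cvParam[@accession='%s']", accession)), "xml_missing")
  }

  # referenceable param groups: id -> accession set
  groups <- xml2::xml_find_all(doc, "//referenceableParamGroup")
  groupAcc <- lapply(groups, function(g)
    xml2::xml_attr(xml2::xml_find_all(g, ".//cvParam"), "accession"))
  names(groupAcc) <- xml2::xml_attr(groups, "id")

  maxX <- as.integer(cvValue(doc, IMZML_CV[["maxX"]]))
  maxY <- as.integer(cvValue(doc, IMZML_CV[["maxY"]]))
  px <- as.numeric(cvValue(doc, IMZML_CV[["pixelX"]]))

  spectra <- xml2::xml_find_all(doc, "//run//spectrum")
  if (!length(spectra))
    stop(sprintf("empty dataset: no spectra in '%s'", path))

  ibd <- file(ibdPath, "rb")
  on.exit(close(ibd))

  readArray <- function(arrayNode) {
    acc <- xml2::xml_attr(xml2::xml_find_all(arrayNode, ".//cvParam"),
                          "accession")
    ref <- xml2::xml_find_first(arrayNode, ".//referenceableParamGroupRef")
    if (!inherits(ref, "xml_missing")) {
      gid <- xml2::xml_attr(ref, "ref")
      acc <- c(acc, groupAcc[[gid]])
    }
    kind <- if (IMZML_CV[["mzArray"]] %in% acc) "mz"
            else if (IMZML_CV[["intensityArray"]] %in% acc) "intensity"
            else "other"
    size <- if (IMZML_CV[["float32"]] %in% acc) 4L else 8L
    offset <- as.numeric(cvValue(arrayNode, IMZML_CV[["offset"]]))
    n <- as.integer(cvValue(arrayNode, IMZML_CV[["arrayLength"]]))
    seek(ibd, where = offset, origin = "start")
    list(kind = kind, values = readBin(ibd, "double", n = n, size = size))
  }

  out <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    x <- as.integer(cvValue(sp, IMZML_CV[["posX"]]))
    y <- as.integer(cvValue(sp, IMZML_CV[["posY"]]))
    arrs <- lapply(xml2::xml_find_all(sp, ".//binaryDataArray"), readArray)
    mz <- intensity <- numeric(0)
    for (a in arrs) {
      if (a$kind == "mz") mz <- a$values
      else if (a$kind == "intensity") intensity <- a$values
    }
    out[[i]] <- list(x = x, y = y, mz = mz, intensity = intensity)
  }
  if (is.na(maxX)) maxX <- max(vapply(out, `[[`, integer(1), "x"))
  if (is.na(maxY)) maxY <- max(vapply(out, `[[`, integer(1), "y"))
  list(nrow = maxY, ncol = maxX, pixelSize = px, spectra = out)
}

#' Extract a single ion image from an imzML dataset
#'
#' Sums, for every pixel, the intensities of all peaks whose m/z falls
#' within the requested window, producing one [IonImage-class]. Grid
#' dimensions are taken from the file's maximum x/y pixel counts; pixel
#' coordinates absent from the file are recorded as missing in the mask.
#'
#' @param imzmlPath path to the `.imzML` file (the `.ibd` companion must
#'   sit alongside it).
#' @param mzCenter centre of the m/z window.
#' @param mzTol half-window width; in Da by default, in ppm of `mzCenter`
#'   when `ppm = TRUE`. Must be positive.
#' @param pixelSize pixel side length in micrometres; defaults to the
#'   file's pixel-size metadata when present.
#' @param ppm interpret `mzTol` as parts-per-million instead of Da.
#' @return an [IonImage-class] with `mz = mzCenter`.
#' @export
extractIonImage <- function(imzmlPath, mzCenter, mzTol,
                            pixelSize = NULL, ppm = FALSE) {
  stopifnot(mzTol > 0)
  tol <- if (ppm) mzCenter * mzTol * 1e-6 else mzTol
  dat <- readImzML(imzmlPath)
  if (is.null(pixelSize))
    pixelSize <- if (is.finite(dat$pixelSize)) dat$pixelSize else NA_real_
  m <- matrix(0, dat$nrow, dat$ncol)
  seen <- matrix(FALSE, dat$nrow, dat$ncol)
  anyHit <- FALSE
  for (sp in dat$spectra) {
    if (sp$y < 1L || sp$y > dat$nrow || sp$x < 1L || sp$x > dat$ncol) next
    seen[sp$y, sp$x] <- TRUE
    hit <- abs(sp$mz - mzCenter) <= tol
    if (any(hit)) {
      anyHit <- TRUE
      m[sp$y, sp$x] <- sum(sp$intensity[hit])
    }
  }
  if (!anyHit)
    warning(sprintf("m/z window %g +/- %g matched no peaks; image is all zero",
                    mzCenter, tol))
  IonImage(m, pixelSize = pixelSize, mz = mzCenter, mask = !seen)
}

#' Write an IonImageStack as a synthetic processed-mode imzML/ibd pair
#'
#' Each non-missing pixel becomes one spectrum containing one centroided
#' peak per channel (at the channel's m/z, with that channel's pixel
#' intensity). Pixels missing in every channel are omitted, so they read
#' back as masked. [extractIonImage()] on the output reproduces each
#' channel exactly. Files are labelled synthetic in their metadata.
#'
#' @param stack an [IonImageStack-class].
#' @param mzValues numeric vector of m/z values, one per channel.
#' @param path output path; `.imzML` is appended when absent, and the
#'   `.ibd` companion is written alongside.
#' @return named character vector with the `imzML` and `ibd` paths,
#'   invisibly.
#' @export
writeSyntheticImzML <- function(stack, mzValues, path) {
  stopifnot(is(stack, "IonImageStack"),
            length(mzValues) == length(stack))
  if (!grepl("\\.imzML$", path, ignore.case = TRUE))
    path <- paste0(path, ".imzML")
  ibdPath <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  imgs <- images(stack)
  d <- dim(imgs[[1L]])
  nr <- d[1L]; nc <- d[2L]
  px <- pixelSize(imgs[[1L]])
  mzValues <- as.numeric(mzValues)

  # deterministic synthetic UUID (no RNG draw): derived from the layout
  seedBytes <- as.raw(c(222, 173, 190, 239,
                        nr %% 256, nr %/% 256, nc %% 256, nc %/% 256,
                        length(imgs) %% 256, 0, 0, 0, 0, 0, 0, 1))
  uuidStr <- paste0(
    paste(format(seedBytes[1:4]), collapse = ""), "-",
    paste(format(seedBytes[5:6]), collapse = ""), "-",
    paste(format(seedBytes[7:8]), collapse = ""), "-",
    paste(format(seedBytes[9:10]), collapse = ""), "-",
    paste(format(seedBytes[11:16]), collapse = ""))

  ibd <- file(ibdPath, "wb")
  on.exit(close(ibd), add = TRUE)
  writeBin(seedBytes, ibd)
  offset <- 16

  pixelMat <- lapply(imgs, pixels)
  maskMat <- lapply(imgs, imageMask)

  spectrumXML <- character(0)
  idx <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      present <- !vapply(maskMat, function(m) m[r, cc], logical(1))
      if (!any(present)) next
      mz <- mzValues[present]
      inten <- vapply(pixelMat[present], function(p) p[r, cc], numeric(1))
      o <- order(mz)
      mz <- mz[o]; inten <- inten[o]
      n <- length(mz)
      mzOff <- offset
      writeBin(mz, ibd, size = 8)
      offset <- offset + 8 * n
      intOff <- offset
      writeBin(inten, ibd, size = 8)
      offset <- offset + 8 * n
      spectrumXML <- c(spectrumXML, sprintf(
'      <spectrum id="spectrum=%d" defaultArrayLength="%d" index="%d">
        <scanList count="1">
          <scan>
            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>
          </scan>
        </scanList>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="mzArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
            <binary/>
          </binaryDataArray>
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="intensityArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
            <binary/>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>',
        idx + 1L, n, idx, cc, r, mzOff, n, 8L * n, intOff, n, 8L * n))
      idx <- idx + 1L
    }
  }
  if (idx == 0L)
    stop("cannot write imzML: every pixel is missing in every channel")

  pixelSizeXML <- if (is.finite(px)) sprintf(
'        <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%g"/>
        <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%g"/>', px, px) else ""

  xml <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">
  <cvList count="2">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
    <cv id="IMS" fullName="Imaging MS Ontology" URI="https://ms-imaging.org/wp/wp-content/uploads/2009/08/imagingMS.obo"/>
  </cvList>
  <fileDescription>
    <fileContent>
      <cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>
      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>
      <userParam name="synthetic" value="true"/>
    </fileContent>
  </fileDescription>
  <referenceableParamGroupList count="2">
    <referenceableParamGroup id="mzArray">
      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
    <referenceableParamGroup id="intensityArray">
      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
  </referenceableParamGroupList>
  <scanSettingsList count="1">
    <scanSettings id="scanSettings1">
      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>
%s
    </scanSettings>
  </scanSettingsList>
  <run id="run1">
    <spectrumList count="%d" defaultDataProcessingRef="none">
%s
    </spectrumList>
  </run>
</mzML>', uuidStr, nc, nr, pixelSizeXML, idx,
    paste(spectrumXML, collapse = "\n"))

  writeLines(xml, path)
  invisible(c(imzML = path, ibd = ibdPath))
}
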