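# Processed-mode imzML 1.1 reader/writer. Layout: .imzML XML describing
# per-spectrum external offsets into the .ibd binary (16-byte UUID header,
# then per pixel the m/z array as 64-bit floats and the intensity array as
# 32-bit floats, little-endian). Coordinates are 1-based in the file and
# 0-based in memory.

.IMZML_NS <- "http://psi.hupo.org/ms/mzml"

.uuidFormat <- function(raw16) {
  h <- paste(sprintf("%02x", as.integer(raw16)), collapse = "")
  paste(substr(h, 1, 8), substr(h, 9, 12), substr(h, 13, 16),
        substr(h, 17, 20), substr(h, 21, 32), sep = "-")
}

.md5Raw <- function(path) {
  h <- unname(tools::md5sum(path))
  as.raw(strtoi(substring(h, seq(1, 31, 2), seq(2, 32, 2)), 16L))
}

.imzmlPaths <- function(path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  list(xml = paste0(base, ".imzML"), ibd = paste0(base, ".ibd"))
}

#' Write a SpectrumImage as processed-mode imzML
#'
#' Emits an `.imzML`/`.ibd` pair: m/z arrays stored as 64-bit floats,
#' intensities as 32-bit floats, coordinates 1-based. The ibd UUID is derived
#' from the MD5 of the binary payload, so regenerating identical data yields
#' byte-identical files.
#'
#' @param img A [SpectrumImage-class].
#' @param path Output path (with or without the `.imzML` extension).
#' @return Invisibly, the paths written.
#' @export
writeImzML <- function(img, path) {
  stopifnot(is(img, "SpectrumImage"))
  p <- .imzmlPaths(path)
  np <- nPixels(img)
  n <- diff(img@pointers)

  # binary payload first (UUID prepended afterwards, derived from its MD5)
  body <- tempfile(fileext = ".bin")
  con <- file(body, "wb")
  starts <- img@pointers[-(np + 1L)]
  for (i in seq_len(np)) {
    idx <- seq.int(starts[i], length.out = n[i])
    writeBin(img@mz[idx], con, size = 8L, endian = "little")
    writeBin(as.numeric(img@intensity[idx]), con, size = 4L, endian = "little")
  }
  close(con)
  uuid <- .md5Raw(body)
  con <- file(p$ibd, "wb")
  writeBin(uuid, con)
  writeBin(readBin(body, "raw", file.info(body)$size), con)
  close(con)
  unlink(body)
  md5 <- paste(sprintf("%02x", as.integer(.md5Raw(p$ibd))), collapse = "")

  # external offsets: 16-byte header, then per pixel 8*n (mz) + 4*n (int)
  mzOff <- 16 + c(0, cumsum(12 * n))[seq_len(np)]
  intOff <- mzOff + 8 * n
  md <- img@metadata
  sp <- vapply(seq_len(np), function(i) sprintf(
'      <spectrum id="Spectrum=%d" defaultArrayLength="%d" index="%d">
        <scanList count="1">
          <scan>
            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>
          </scan>
        </scanList>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="mzArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>
            <binary/>
          </binaryDataArray>
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="intensityArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>
            <binary/>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>',
    i, n[i], i - 1L, img@coords[i, 1] + 1L, img@coords[i, 2] + 1L,
    n[i], 8 * n[i], mzOff[i], n[i], 4 * n[i], intOff[i]), "")

  xml <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<mzML xmlns="%s" version="1.1">
  <cvList count="2">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
    <cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>
  </cvList>
  <fileDescription>
    <fileContent>
      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>
      <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>
      <cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>
      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>
      <cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="%s"/>
      <userParam name="msikit:condition" value="%s"/>
      <userParam name="msikit:replicate_id" value="%s"/>
      <userParam name="msikit:solvent" value="%s"/>
      <userParam name="msikit:ice_matrix" value="%s"/>
      <userParam name="msikit:injection_time_ms" value="%s"/>
      <userParam name="msikit:intensity_units" value="%s"/>
      <userParam name="msikit:polarity" value="%s"/>
      <userParam name="msikit:scan_range_low" value="%s"/>
      <userParam name="msikit:scan_range_high" value="%s"/>
    </fileContent>
  </fileDescription>
  <referenceableParamGroupList count="2">
    <referenceableParamGroup id="mzArray">
      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
    <referenceableParamGroup id="intensityArray">
      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>
      <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
  </referenceableParamGroupList>
  <softwareList count="1">
    <software id="msikit" version="0.99"/>
  </softwareList>
  <scanSettingsList count="1">
    <scanSettings id="scanSettings1">
      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%s" unitCvRef="UO" unitAccession="UO:0000017" unitName="micrometer"/>
      <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%s" unitCvRef="UO" unitAccession="UO:0000017" unitName="micrometer"/>
    </scanSettings>
  </scanSettingsList>
  <instrumentConfigurationList count="1">
    <instrumentConfiguration id="IC1">
      <cvParam cvRef="MS" accession="MS:1000031" name="instrument model"/>
    </instrumentConfiguration>
  </instrumentConfigurationList>
  <dataProcessingList count="1">
    <dataProcessing id="dp1">
      <processingMethod order="1" softwareRef="msikit">
        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>
      </processingMethod>
    </dataProcessing>
  </dataProcessingList>
  <run id="run1" defaultInstrumentConfigurationRef="IC1">
    <spectrumList count="%d" defaultDataProcessingRef="dp1">
%s
    </spectrumList>
  </run>
</mzML>
', .IMZML_NS, .uuidFormat(uuid), md5,
    md@condition, md@replicateId, md@solvent, md@iceMatrix,
    format(md@injectionTime), md@intensityUnits, md@polarity,
    format(md@scanRange[1]), format(md@scanRange[2]),
    img@gridShape[1], img@gridShape[2],
    format(md@spatialResolution), format(md@spatialResolution),
    np, paste(sp, collapse = "\n"))
  writeLines(xml, p$xml, sep = "")
  invisible(p)
}

.cvValue <- function(doc, accession, ns) {
  nodes <- xml2::xml_find_all(doc, sprintf("//d1:cvParam[@accession='%s']", accession), ns)
  if (!length(nodes)) return(NULL)
  xml2::xml_attr(nodes, "value")
}

.userValue <- function(doc, name, ns, default) {
  nodes <- xml2::xml_find_all(doc, sprintf("//d1:userParam[@name='%s']", name), ns)
  if (!length(nodes)) return(default)
  xml2::xml_attr(nodes[[1]], "value")
}

#' Read a processed-mode imzML file
#'
#' Loads an `.imzML`/`.ibd` pair, verifying the ibd MD5 checksum when
#' present. Only processed (per-pixel centroid) mode is supported;
#' continuous-mode files raise an error. Study labels written by
#' [writeImzML()] are recovered; absent metadata falls back to the supplied
#' defaults.
#'
#' @param path Path to the `.imzML` file (extension optional).
#' @param metadata Fallback [AcquisitionMetadata-class] for fields the file
#'   does not carry.
#' @param checkHash Verify the ibd MD5 checksum (default TRUE).
#' @return A [SpectrumImage-class].
#' @export
readImzML <- function(path, metadata = acquisitionMetadata(), checkHash = TRUE) {
  p <- .imzmlPaths(path)
  if (!file.exists(p$xml) || !file.exists(p$ibd))
    stop("imzML file pair not found: ", p$xml, " / ", p$ibd)
  doc <- xml2::read_xml(p$xml)
  ns <- xml2::xml_ns(doc)

  mode <- xml2::xml_find_all(doc, "//d1:fileContent/d1:cvParam[@accession='IMS:1000030']", ns)
  if (length(mode)) stop("unsupported mode: continuous imzML (processed required)")
  if (!length(xml2::xml_find_all(doc, "//d1:fileContent/d1:cvParam[@accession='IMS:1000031']", ns)))
    stop("file does not declare processed mode")

  md5 <- .cvValue(doc, "IMS:1000090", ns)
  if (checkHash && !is.null(md5)) {
    have <- paste(sprintf("%02x", as.integer(.md5Raw(p$ibd))), collapse = "")
    if (tolower(md5[1]) != have)
      stop("ibd MD5 checksum mismatch for ", p$ibd)
  }

  xs <- as.integer(.cvValue(doc, "IMS:1000050", ns))
  ys <- as.integer(.cvValue(doc, "IMS:1000051", ns))
  np <- length(xs)
  getArr <- function(ref, acc) {
    nodes <- xml2::xml_find_all(doc, sprintf(
      "//d1:binaryDataArray[d1:referenceableParamGroupRef/@ref='%s']/d1:cvParam[@accession='%s']",
      ref, acc), ns)
    as.numeric(xml2::xml_attr(nodes, "value"))
  }
  mzOff <- getArr("mzArray", "IMS:1000102")
  mzLen <- as.integer(getArr("mzArray", "IMS:1000103"))
  intOff <- getArr("intensityArray", "IMS:1000102")
  intLen <- as.integer(getArr("intensityArray", "IMS:1000103"))
  if (length(mzOff) != np || length(intOff) != np || any(mzLen != intLen))
    stop("I/O error: array descriptors inconsistent with spectrum count")

  con <- file(p$ibd, "rb")
  on.exit(close(con))
  mzs <- vector("list", np); ints <- vector("list", np)
  for (i in seq_len(np)) {
    seek(con, mzOff[i])
    mzs[[i]] <- readBin(con, "double", mzLen[i], size = 8L, endian = "little")
    seek(con, intOff[i])
    ints[[i]] <- readBin(con, "double", intLen[i], size = 4L, endian = "little")
    if (length(mzs[[i]]) != mzLen[i] || length(ints[[i]]) != intLen[i])
      stop("I/O error: ibd truncated at spectrum ", i)
  }

  grid <- c(max(c(xs, 1L)), max(c(ys, 1L)))
  gx <- .cvValue(doc, "IMS:1000042", ns); gy <- .cvValue(doc, "IMS:1000043", ns)
  if (!is.null(gx)) grid[1] <- as.integer(gx[1])
  if (!is.null(gy)) grid[2] <- as.integer(gy[1])

  res <- .cvValue(doc, "IMS:1000046", ns)
  md <- acquisitionMetadata(
    spatialResolution = if (!is.null(res)) as.numeric(res[1]) else metadata@spatialResolution,
    scanRange = c(as.numeric(.userValue(doc, "msikit:scan_range_low", ns, metadata@scanRange[1])),
                  as.numeric(.userValue(doc, "msikit:scan_range_high", ns, metadata@scanRange[2]))),
    polarity = .userValue(doc, "msikit:polarity", ns, metadata@polarity),
    injectionTime = as.numeric(.userValue(doc, "msikit:injection_time_ms", ns, metadata@injectionTime)),
    intensityUnits = .userValue(doc, "msikit:intensity_units", ns, metadata@intensityUnits),
    condition = .userValue(doc, "msikit:condition", ns, metadata@condition),
    replicateId = .userValue(doc, "msikit:replicate_id", ns, metadata@replicateId),
    solvent = .userValue(doc, "msikit:solvent", ns, metadata@solvent),
    iceMatrix = as.logical(.userValue(doc, "msikit:ice_matrix", ns, metadata@iceMatrix)))

  spectrumImage(
    spectra = Map(function(m, it) list(mz = m, intensity = it), mzs, ints),
    coords = cbind(xs - 1L, ys - 1L), gridShape = grid, metadata = md)
}
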