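#' Acquisition metadata for one MSI dataset
#'
#' Instrument-level settings carried alongside the pixel spectra: spatial
#' resolution (µm per pixel), scan range (Th), polarity, fixed injection time
#' (ms), intensity units ("charges per second" on the instruments this models,
#' i.e. total charges divided by injection time), plus study labels:
#' condition, replicate id, electrospray solvent (standard vs NH4F-doped) and
#' whether an ice matrix was applied.
#'
#' @export
setClass("AcquisitionMetadata", representation(
  spatialResolution = "numeric", scanRange = "numeric", polarity = "character",
  injectionTime = "numeric", intensityUnits = "character",
  condition = "character", replicateId = "character", solvent = "character",
  iceMatrix = "logical"))

setValidity("AcquisitionMetadata", function(object) {
  if (object@spatialResolution <= 0) return("spatialResolution must be > 0")
  if (length(object@scanRange) != 2 || object@scanRange[1] >= object@scanRange[2])
    return("scanRange must be (low, high) with low < high")
  if (!object@polarity %in% c("positive", "negative"))
    return("polarity must be 'positive' or 'negative'")
  TRUE
})

#' @param spatialResolution µm per pixel.
#' @param scanRange Numeric (low, high) in Th.
#' @param polarity "positive" or "negative".
#' @param injectionTime ms.
#' @param intensityUnits Intensity unit label.
#' @param condition,replicateId,solvent Study labels.
#' @param iceMatrix Logical.
#' @rdname AcquisitionMetadata-class
#' @export
acquisitionMetadata <- function(spatialResolution = 100,
                                scanRange = c(200, 800),
                                polarity = "positive", injectionTime = 15,
                                intensityUnits = "charges per second",
                                condition = "unknown", replicateId = "R1",
                                solvent = "standard", iceMatrix = TRUE) {
  new("AcquisitionMetadata", spatialResolution = spatialResolution,
      scanRange = as.numeric(scanRange), polarity = polarity,
      injectionTime = injectionTime, intensityUnits = intensityUnits,
      condition = condition, replicateId = replicateId, solvent = solvent,
      iceMatrix = iceMatrix)
}

setMethod("show", "AcquisitionMetadata", function(object) {
  cat("AcquisitionMetadata: ", object@polarity, " mode, m/z ",
      object@scanRange[1], "-", object@scanRange[2], ", ",
      object@spatialResolution, " um, IT ", object@injectionTime, " ms\n",
      "  condition=", object@condition, " replicate=", object@replicateId,
      " solvent=", object@solvent, " ice=", object@iceMatrix, "\n", sep = "")
})

#' Pixel-indexed centroided MSI dataset
#'
#' The in-memory form of one processed-mode imzML file. Spectra are stored
#' in a compressed sparse layout: all peak m/z and intensity values
#' concatenated pixel-by-pixel, with `pointers[i] .. pointers[i+1]-1`
#' delimiting pixel `i`'s peaks (m/z sorted within each pixel). `coords`
#' holds 0-based (x, y) grid coordinates; pixels missing from the grid
#' (holes in degraded sections) are simply absent.
#'
#' @slot mz,intensity Concatenated peak arrays.
#' @slot pointers Integer vector of length nPixels+1 (1-based offsets).
#' @slot coords Integer matrix nPixels x 2 of 0-based (x, y).
#' @slot gridShape Integer (n_cols, n_rows).
#' @slot metadata An [AcquisitionMetadata-class].
#' @seealso [readImzML()], [writeImzML()], [extractIonImage()]
#' @export
setClass("SpectrumImage", representation(
  mz = "numeric", intensity = "numeric", pointers = "integer",
  coords = "matrix", gridShape = "integer", metadata = "AcquisitionMetadata"))

setValidity("SpectrumImage", function(object) {
  np <- nrow(object@coords)
  if (length(object@pointers) != np + 1L) return("pointers length != nPixels+1")
  if (object@pointers[1] != 1L ||
      object@pointers[np + 1L] != length(object@mz) + 1L)
    return("pointer bounds inconsistent with peak arrays")
  if (any(diff(object@pointers) < 0L)) return("pointers must be non-decreasing")
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity lengths differ")
  if (length(object@intensity) && any(object@intensity < 0))
    return("negative intensities")
  if (ncol(object@coords) != 2L) return("coords must have 2 columns")
  if (np) {
    if (min(object@coords) < 0L ||
        any(object@coords[, 1] >= object@gridShape[1]) ||
        any(object@coords[, 2] >= object@gridShape[2]))
      return("coordinates outside gridShape")
    if (anyDuplicated(object@coords[, 1] + object@coords[, 2] * object@gridShape[1]))
      return("more than one spectrum at a coordinate")
  }
  # sortedness within pixels: global diff check skipping pixel boundaries
  if (length(object@mz) > 1L) {
    d <- diff(object@mz)
    boundary <- object@pointers[-c(1L, np + 1L)] - 1L
    d[boundary[boundary >= 1L & boundary < length(object@mz)]] <- 1
    if (any(d <= 0)) return("m/z values must be strictly increasing within a pixel")
  }
  TRUE
})

#' Construct a SpectrumImage from per-pixel peak lists
#'
#' @param spectra List of `list(mz=, intensity=)`, one per pixel, each m/z
#'   vector sorted ascending.
#' @param coords Integer matrix of 0-based (x, y), one row per spectrum.
#' @param gridShape Integer (n_cols, n_rows).
#' @param metadata An [AcquisitionMetadata-class].
#' @return A [SpectrumImage-class].
#' @export
spectrumImage <- function(spectra, coords, gridShape,
                          metadata = acquisitionMetadata()) {
  n <- vapply(spectra, function(s) length(s$mz), 0L)
  new("SpectrumImage",
      mz = unlist(lapply(spectra, `[[`, "mz"), use.names = FALSE),
      intensity = as.numeric(unlist(lapply(spectra, `[[`, "intensity"),
                                    use.names = FALSE)),
      pointers = c(1L, 1L + cumsum(n)),
      coords = matrix(as.integer(coords), ncol = 2,
                      dimnames = list(NULL, c("x", "y"))),
      gridShape = as.integer(gridShape), metadata = metadata)
}

#' @describeIn SpectrumImage-class Number of recorded pixels.
#' @param x,object A SpectrumImage.
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))
#' @rdname SpectrumImage-class
#' @export
setMethod("nPixels", "SpectrumImage", function(x) nrow(x@coords))

#' @describeIn SpectrumImage-class Grid shape (n_cols, n_rows).
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname SpectrumImage-class
#' @export
setMethod("gridShape", "SpectrumImage", function(x) x@gridShape)

#' @describeIn SpectrumImage-class Acquisition metadata.
#' @export
setGeneric("acqMetadata", function(x) standardGeneric("acqMetadata"))
#' @rdname SpectrumImage-class
#' @export
setMethod("acqMetadata", "SpectrumImage", function(x) x@metadata)

#' @describeIn SpectrumImage-class 0-based pixel coordinates.
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))
#' @rdname SpectrumImage-class
#' @export
setMethod("pixelCoords", "SpectrumImage", function(x) x@coords)

#' Spectrum at a grid coordinate
#'
#' @param img A [SpectrumImage-class].
#' @param x,y 0-based grid coordinates.
#' @return data.frame(mz, intensity), or NULL if no spectrum was recorded
#'   at that coordinate.
#' @export
spectrumAt <- function(img, x, y) {
  i <- which(img@coords[, 1] == x & img@coords[, 2] == y)
  if (!length(i)) return(NULL)
  idx <- seq.int(img@pointers[i], length.out = img@pointers[i + 1L] - img@pointers[i])
  data.frame(mz = img@mz[idx], intensity = img@intensity[idx])
}

setMethod("show", "SpectrumImage", function(object) {
  cat("SpectrumImage: ", nPixels(object), " pixels on a ",
      object@gridShape[1], " x ", object@gridShape[2], " grid, ",
      length(object@mz), " peaks total\n", sep = "")
  show(object@metadata)
})

#' Single-ion abundance image
#'
#' A 2-D grid of abundances (values[row, col], i.e. values[y+1, x+1]) for one
#' m/z window or a derived quantity (TIC, adduct sum). `missing` marks grid
#' cells where no spectrum was recorded, distinguishing them from true zero.
#'
#' @slot values Numeric matrix (n_rows x n_cols), >= 0 where not missing.
#' @slot missing Logical matrix, same shape.
#' @slot targetMz Window center in Th (NA for derived images).
#' @slot tolPpm Window half-width in ppm (NA for derived images).
#' @slot label Display label.
#' @export
setClass("IonImage", representation(values = "matrix", missing = "matrix",
                                    targetMz = "numeric", tolPpm = "numeric",
                                    label = "character"))

setValidity("IonImage", function(object) {
  if (!identical(dim(object@values), dim(object@missing)))
    return("values and missing shape mismatch")
  if (any(object@values[!object@missing] < 0, na.rm = TRUE))
    return("negative abundances")
  TRUE
})

.ionImage <- function(values, missing, targetMz = NA_real_, tolPpm = NA_real_,
                      label = "") {
  new("IonImage", values = values, missing = missing,
      targetMz = targetMz, tolPpm = tolPpm, label = label)
}

#' @describeIn IonImage-class Abundance matrix (rows = y, cols = x).
#' @param x An IonImage.
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))
#' @rdname IonImage-class
#' @export
setMethod("imageValues", "IonImage", function(x) x@values)

#' @describeIn IonImage-class Logical matrix of off-grid (missing) pixels.
#' @export
setGeneric("missingPixels", function(x) standardGeneric("missingPixels"))
#' @rdname IonImage-class
#' @export
setMethod("missingPixels", "IonImage", function(x) x@missing)

setMethod("show", "IonImage", function(object) {
  v <- object@values[!object@missing]
  cat("IonImage '", object@label, "' ", ncol(object@values), " x ",
      nrow(object@values), if (!is.na(object@targetMz))
        paste0(", m/z ", round(object@targetMz, 4), " +/- ", object@tolPpm, " ppm"),
      "; mean ", signif(mean(v), 4), ", max ", signif(max(v), 4), "\n", sep = "")
})
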