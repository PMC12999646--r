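# Ion-image extraction and comparison: ppm-windowed abundance maps, adduct
# summing, TIC/tissue masking, colocalization scores, PNG rendering.

.pixelIndexVector <- function(img) {
  rep.int(seq_len(nPixels(img)), diff(img@pointers))
}

.emptyGrid <- function(img) {
  g <- gridShape(img)
  values <- matrix(0, nrow = g[2], ncol = g[1])
  missing <- matrix(TRUE, nrow = g[2], ncol = g[1])
  missing[cbind(img@coords[, 2] + 1L, img@coords[, 1] + 1L)] <- FALSE
  list(values = values, missing = missing)
}

.fillGrid <- function(img, perPixel, targetMz = NA_real_, tolPpm = NA_real_,
                      label = "") {
  g <- .emptyGrid(img)
  g$values[cbind(img@coords[, 2] + 1L, img@coords[, 1] + 1L)] <- perPixel
  .ionImage(g$values, g$missing, targetMz, tolPpm, label)
}

#' ppm window bounds
#'
#' Half-open interval `[target*(1 - tol*1e-6), target*(1 + tol*1e-6))`; the
#' open upper edge makes adjacent windows partition the axis so a peak can
#' never be counted twice.
#'
#' @param targetMz Window center (Th).
#' @param tolPpm Half-width in ppm.
#' @return Numeric (low, high).
#' @export
ppmWindow <- function(targetMz, tolPpm) {
  targetMz * c(1 - tolPpm * 1e-6, 1 + tolPpm * 1e-6)
}

#' Extract a ppm-windowed ion image
#'
#' Per pixel, reduces (sum by default, or max) the intensities of all
#' centroids whose m/z falls in the half-open window around `targetMz` —
#' exactly equivalent to a linear scan over every peak. A target outside the
#' scan range yields a zero image with a warning.
#'
#' @param img A [SpectrumImage-class].
#' @param targetMz Window center (Th).
#' @param tolPpm Window half-width in ppm (default 5: the instrument's
#'   +/- 2.5 ppm mass accuracy doubled for safety).
#' @param reducer "sum" or "max".
#' @return An [IonImage-class].
#' @export
extractIonImage <- function(img, targetMz, tolPpm = 5, reducer = c("sum", "max")) {
  stopifnot(tolPpm > 0)
  reducer <- match.arg(reducer)
  sr <- acqMetadata(img)@scanRange
  label <- sprintf("m/z %.4f", targetMz)
  if (targetMz < sr[1] || targetMz > sr[2]) {
    warning("target m/z ", targetMz, " outside scan range [",
            sr[1], ", ", sr[2], "]; returning zero image")
    return(.fillGrid(img, numeric(nPixels(img)), targetMz, tolPpm, label))
  }
  w <- ppmWindow(targetMz, tolPpm)
  sel <- img@mz >= w[1] & img@mz < w[2]
  per <- numeric(nPixels(img))
  if (any(sel)) {
    pix <- .pixelIndexVector(img)[sel]
    int <- img@intensity[sel]
    if (reducer == "sum") {
      agg <- rowsum(int, pix)
    } else {
      agg <- vapply(split(int, pix), max, 0)
      agg <- matrix(agg, dimnames = list(names(agg), NULL))
    }
    per[as.integer(rownames(agg))] <- agg[, 1]
  }
  .fillGrid(img, per, targetMz, tolPpm, label)
}

#' Sum ion images elementwise
#'
#' Used to combine the adduct images of one species into a single abundance
#' map (the "summed ion images" operation). All images must share a grid.
#'
#' @param images Non-empty list of [IonImage-class] objects.
#' @return An [IonImage-class]; labels are concatenated.
#' @export
summedIonImage <- function(images) {
  if (!length(images)) stop("empty image list")
  dims <- lapply(images, function(i) dim(i@values))
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("grid shapes differ")
  values <- Reduce(`+`, lapply(images, imageValues))
  missing <- Reduce(`&`, lapply(images, missingPixels))
  .ionImage(values, missing, NA_real_, NA_real_,
            paste(vapply(images, function(i) i@label, ""), collapse = " + "))
}

#' Summed-adduct image of one panel species
#'
#' Extracts and sums one ion image per adduct of the species (or the single
#' direct m/z for panel entries defined by observed m/z alone).
#'
#' @param img A [SpectrumImage-class].
#' @param entry One row of a panel data.frame (see [defaultPanel()]).
#' @param tolPpm Window half-width in ppm.
#' @param adductsOnly Optional character vector restricting which adducts are
#'   used (e.g. `"M+H"` for protonated-only quantitation).
#' @return An [IonImage-class].
#' @export
speciesImage <- function(img, entry, tolPpm = 5, adductsOnly = NULL) {
  mzs <- speciesIonMz(entry, adductsOnly)
  im <- summedIonImage(lapply(mzs, extractIonImage, img = img, tolPpm = tolPpm))
  im@label <- entry$name
  im
}

#' Total ion current image
#'
#' Per-pixel sum of all centroid intensities; pixels with no spectrum are 0
#' and flagged missing.
#'
#' @param img A [SpectrumImage-class].
#' @return An [IonImage-class] labelled "TIC".
#' @export
ticImage <- function(img) {
  per <- numeric(nPixels(img))
  pix <- .pixelIndexVector(img)
  if (length(pix)) {
    agg <- rowsum(img@intensity, pix)
    per[as.integer(rownames(agg))] <- agg[, 1]
  }
  .fillGrid(img, per, label = "TIC")
}

#' Segment tissue from a TIC image
#'
#' Thresholds the TIC (Otsu's method, or a fixed fraction of the maximum)
#' and keeps the largest connected component. Missing pixels are never part
#' of the mask.
#'
#' @param tic An [IonImage-class], typically from [ticImage()].
#' @param method "otsu" or "fraction".
#' @param param For "fraction": pixels >= `param * max(TIC)` are kept.
#' @return Logical matrix (TRUE = tissue).
#' @export
tissueMask <- function(tic, method = c("otsu", "fraction"), param = 0.1) {
  method <- match.arg(method)
  v <- imageValues(tic)
  v[missingPixels(tic)] <- 0
  mx <- max(v)
  if (mx <= 0) stop("all-zero TIC image: cannot segment tissue")
  thr <- if (method == "otsu") {
    EBImage::otsu(EBImage::Image(t(v) / mx), range = c(0, 1)) * mx
  } else param * mx
  mask <- v >= thr & !missingPixels(tic)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  labm <- t(EBImage::imageData(lab))
  if (max(labm) >= 1) {
    counts <- tabulate(labm[labm > 0])
    mask <- labm == which.max(counts)
  }
  mask
}

#' Colocalization between two ion images
#'
#' Pearson correlation of abundances over the masked pixels, plus an overlap
#' fraction: each image is thresholded by its own Otsu cut within the mask,
#' and the fraction |above in both| / |above in either| is reported. A
#' zero-variance image gives `pearson_r = NA` with a warning.
#'
#' @param a,b [IonImage-class] objects on the same grid.
#' @param mask Logical matrix of pixels to use (e.g. a tissue mask).
#' @return list(pearson_r, overlap_fraction, n_pixels).
#' @export
colocalizationScore <- function(a, b, mask = NULL) {
  if (!identical(dim(a@values), dim(b@values))) stop("grid shapes differ")
  if (is.null(mask)) mask <- !(missingPixels(a) | missingPixels(b))
  mask <- mask & !(missingPixels(a) | missingPixels(b))
  if (!any(mask)) stop("empty mask")
  va <- imageValues(a)[mask]; vb <- imageValues(b)[mask]
  r <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero-variance image: Pearson r undefined")
    NA_real_
  } else stats::cor(va, vb)
  othr <- function(v) {
    if (max(v) == min(v)) return(Inf)
    EBImage::otsu(EBImage::Image(matrix((v - min(v)) / (max(v) - min(v)), ncol = 1)),
                  range = c(0, 1)) * (max(v) - min(v)) + min(v)
  }
  ha <- va >= othr(va); hb <- vb >= othr(vb)
  denom <- sum(ha | hb)
  list(pearson_r = r,
       overlap_fraction = if (denom) sum(ha & hb) / denom else NA_real_,
       n_pixels = sum(mask))
}

.VIRIDIS_STOPS <- matrix(c(
  0.267, 0.005, 0.329,
  0.283, 0.141, 0.458,
  0.254, 0.265, 0.530,
  0.207, 0.372, 0.553,
  0.164, 0.471, 0.558,
  0.128, 0.567, 0.551,
  0.135, 0.659, 0.518,
  0.267, 0.749, 0.441,
  0.478, 0.821, 0.318,
  0.741, 0.873, 0.150,
  0.993, 0.906, 0.144), ncol = 3, byrow = TRUE)

.applyColormap <- function(x, colormap = "viridis") {
  # x in [0,1]; returns array h x w x 3
  stops <- switch(colormap,
    viridis = .VIRIDIS_STOPS,
    gray = matrix(c(0, 0, 0, 1, 1, 1), ncol = 3, byrow = TRUE),
    stop("unknown colormap: ", colormap))
  n <- nrow(stops)
  at <- seq(0, 1, length.out = n)
  out <- array(0, c(dim(x), 3))
  for (k in 1:3) out[, , k] <- matrix(stats::approx(at, stops[, k], xout = as.vector(x),
                                                    rule = 2)$y, nrow = nrow(x))
  out
}

#' Render an ion image as a PNG heat map
#'
#' Deterministic rasterization: values are scaled linearly to [0, 1] (by the
#' image maximum) and mapped through a fixed colormap; missing pixels render
#' black. Identical input always yields byte-identical PNG output.
#'
#' @param img An [IonImage-class].
#' @param path Output PNG path.
#' @param colormap "viridis" or "gray".
#' @param scaleMax Optional fixed maximum for the linear scale.
#' @return Invisibly, `path`.
#' @export
renderHeatmap <- function(img, path, colormap = "viridis", scaleMax = NULL) {
  v <- imageValues(img)
  mx <- if (is.null(scaleMax)) max(v[!missingPixels(img)], 0) else scaleMax
  x <- if (mx > 0) pmin(v / mx, 1) else v * 0
  rgb <- .applyColormap(x, colormap)
  for (k in 1:3) rgb[, , k][missingPixels(img)] <- 0
  png::writePNG(rgb, path)
  invisible(path)
}

#' Render a multi-channel ion-image overlay as PNG
#'
#' Each channel is normalized to its own maximum, tinted with its assigned
#' color, and the channels are added (so coinciding signal blends: red +
#' green renders yellow). Channel order does not change the result.
#'
#' @param images List of [IonImage-class] on one grid.
#' @param path Output PNG path.
#' @param colors Vector of R color names/hex, one per image.
#' @return Invisibly, `path`.
#' @export
renderOverlay <- function(images, path,
                          colors = c("red", "green", "blue", "magenta")[seq_along(images)]) {
  if (!length(images)) stop("empty image list")
  if (length(colors) < length(images)) stop("need one color per image")
  d <- dim(images[[1]]@values)
  out <- array(0, c(d, 3))
  for (i in seq_along(images)) {
    v <- imageValues(images[[i]])
    mx <- max(v[!missingPixels(images[[i]])], 0)
    x <- if (mx > 0) v / mx else v * 0
    tint <- grDevices::col2rgb(colors[i])[, 1] / 255
    for (k in 1:3) out[, , k] <- out[, , k] + x * tint[k]
  }
  out <- pmin(out, 1)
  png::writePNG(out, path)
  invisible(path)
}
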