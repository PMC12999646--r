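# Parallel reaction monitoring: breakdown curves over a collision-energy
# ramp, optimal-NCE selection, ion abundance ratios, isotope-envelope
# matching and fragment-image colocalization.

#' PRM acquisition settings
#'
#' @slot precursorMz Isolated precursor m/z (default: protonated psychosine,
#'   computed from C24H47NO7).
#' @slot isolationWidth Quadrupole isolation width in Th (default 5).
#' @slot scanRange MS2 scan range in Th (default 40-500).
#' @slot fragments data.frame(label, mz, quantitative).
#' @slot tolPpm Extraction window half-width in ppm.
#' @export
setClass("PrmSettings", representation(
  precursorMz = "numeric", isolationWidth = "numeric", scanRange = "numeric",
  fragments = "data.frame", tolPpm = "numeric"))

setValidity("PrmSettings", function(object) {
  if (object@isolationWidth <= 0) return("isolationWidth must be > 0")
  if (any(object@fragments$mz < object@scanRange[1] |
          object@fragments$mz > object@scanRange[2]))
    return("fragment m/z outside scan range")
  TRUE
})

#' @param precursorMz,isolationWidth,scanRange,fragments,tolPpm See slots.
#' @rdname PrmSettings-class
#' @export
prmSettings <- function(precursorMz = NULL, isolationWidth = 5,
                        scanRange = c(40, 500), fragments = NULL, tolPpm = 5) {
  ions <- prmIonMz()
  if (is.null(precursorMz)) precursorMz <- unname(ions["precursor"])
  if (is.null(fragments))
    fragments <- data.frame(label = c("frag282", "frag264"),
                            mz = unname(ions[c("frag282", "frag264")]),
                            quantitative = TRUE)
  new("PrmSettings", precursorMz = precursorMz,
      isolationWidth = isolationWidth, scanRange = as.numeric(scanRange),
      fragments = fragments, tolPpm = tolPpm)
}

setMethod("show", "PrmSettings", function(object) {
  cat("PrmSettings: precursor m/z ", round(object@precursorMz, 4),
      ", isolation ", object@isolationWidth, " Th, scan ",
      object@scanRange[1], "-", object@scanRange[2], " Th\n", sep = "")
  print(object@fragments)
})

#' Breakdown curve over a collision-energy ramp
#'
#' Per-NCE mean abundances of the precursor and each configured fragment.
#'
#' @slot nce Sorted NCE grid (%).
#' @slot abundance Matrix (length(nce) x ions), columns named precursor and
#'   fragment labels.
#' @export
setClass("BreakdownCurve", representation(nce = "numeric",
                                          abundance = "matrix"))

setValidity("BreakdownCurve", function(object) {
  if (is.unsorted(object@nce, strictly = TRUE)) return("nce grid must be sorted")
  if (nrow(object@abundance) != length(object@nce)) return("shape mismatch")
  if (any(object@abundance < 0)) return("negative abundances")
  TRUE
})

setMethod("show", "BreakdownCurve", function(object) {
  cat("BreakdownCurve over", length(object@nce), "NCE points (",
      min(object@nce), "-", max(object@nce), "% )\n")
  utils::head(data.frame(nce = object@nce, object@abundance))
})

#' Ion fractions of a breakdown curve
#'
#' @param curve A [BreakdownCurve-class].
#' @return Matrix of per-NCE fractions (rows sum to 1 where total > 0).
#' @export
breakdownFractions <- function(curve) {
  tot <- rowSums(curve@abundance)
  sweep(curve@abundance, 1, ifelse(tot > 0, tot, 1), "/")
}

#' Build a breakdown curve from NCE-ramp spectra
#'
#' For each NCE and ion, each scan's abundance is the ppm-window sum around
#' the ion's theoretical m/z (the same half-open window convention as ion
#' images), averaged over scans.
#'
#' @param ramp data.frame(nce, scan, mz, intensity) as from
#'   [generateBreakdownData()] or a delimited instrument export.
#' @param settings A [PrmSettings-class].
#' @return A [BreakdownCurve-class].
#' @export
buildBreakdownCurve <- function(ramp, settings = prmSettings()) {
  grid <- sort(unique(ramp$nce))
  if (length(grid) < 3) stop("need >= 3 NCE points")
  targets <- c(precursor = settings@precursorMz,
               stats::setNames(settings@fragments$mz, settings@fragments$label))
  nceF <- factor(ramp$nce, levels = grid)
  ab <- vapply(targets, function(tmz) {
    w <- ppmWindow(tmz, settings@tolPpm)
    sel <- ramp$mz >= w[1] & ramp$mz < w[2]
    # a scan with no in-window peak contributes 0 to the mean
    sums <- tapply(ramp$intensity * sel, list(nceF, ramp$scan), sum)
    rowMeans(sums, na.rm = TRUE)
  }, numeric(length(grid)))
  new("BreakdownCurve", nce = grid,
      abundance = matrix(ab, nrow = length(grid),
                         dimnames = list(NULL, names(targets))))
}

#' Optimal collision energy from a breakdown curve
#'
#' The grid point where the two quantitative fragments are closest to equal
#' (minimal |fraction difference|), subject to a minimum total fragment
#' yield; ties resolve to the lower NCE. This formalizes "fragments
#' approximately equivalent in abundance at the optimized energy".
#'
#' @param curve A [BreakdownCurve-class].
#' @param settings A [PrmSettings-class] (names the quantitative fragments).
#' @param minFragmentFraction Minimum summed fragment fraction (default
#'   0.25) for a grid point to qualify.
#' @return Optimal NCE (%).
#' @export
optimalNce <- function(curve, settings = prmSettings(),
                       minFragmentFraction = 0.25) {
  quant <- settings@fragments$label[settings@fragments$quantitative]
  if (length(quant) != 2) stop("need exactly 2 quantitative fragments")
  fr <- breakdownFractions(curve)
  fragTotal <- rowSums(fr[, quant, drop = FALSE])
  ok <- fragTotal >= minFragmentFraction
  if (!any(ok))
    stop("no NCE reaches fragment fraction ", minFragmentFraction,
         "; best candidate NCE ", curve@nce[which.max(fragTotal)],
         " at ", round(max(fragTotal), 3))
  dif <- abs(fr[, quant[1]] - fr[, quant[2]])
  dif[!ok] <- Inf
  curve@nce[which.min(dif)]  # which.min takes the first (lowest NCE) tie
}

#' Ion abundance ratio analysis
#'
#' Summed abundances of the precursor and quantitative fragments (over all
#' on-tissue pixels of a PRM image, or over one spectrum), their fractions
#' of the total, and the equality ratio min/max of the two quantitative
#' fragments (1 = perfectly equal).
#'
#' @param x A [SpectrumImage-class] or data.frame(mz, intensity).
#' @param settings A [PrmSettings-class].
#' @param mask Optional logical tissue mask for image input.
#' @return list(abundance, fraction, equality_ratio).
#' @export
ionRatioAnalysis <- function(x, settings = prmSettings(), mask = NULL) {
  targets <- c(precursor = settings@precursorMz,
               stats::setNames(settings@fragments$mz, settings@fragments$label))
  windows <- lapply(targets, ppmWindow, tolPpm = settings@tolPpm)
  sorted <- windows[order(targets)]
  for (i in seq_along(sorted)[-1])
    if (sorted[[i]][1] < sorted[[i - 1]][2])
      stop("extraction windows overlap")
  ab <- if (is(x, "SpectrumImage")) {
    vapply(targets, function(tmz) {
      im <- extractIonImage(x, tmz, settings@tolPpm)
      use <- !missingPixels(im)
      if (!is.null(mask)) use <- use & mask
      sum(imageValues(im)[use])
    }, 0)
  } else {
    vapply(windows, function(w)
      sum(x$intensity[x$mz >= w[1] & x$mz < w[2]]), 0)
  }
  quant <- settings@fragments$label[settings@fragments$quantitative]
  fq <- ab[quant]
  list(abundance = ab, fraction = ab / sum(ab),
       equality_ratio = if (max(fq) > 0) min(fq) / max(fq) else NA_real_)
}

#' Cosine match between an observed and theoretical isotope envelope
#'
#' Observed peaks are assigned to theoretical envelope entries by nearest
#' m/z within the tolerance; unmatched theoretical entries contribute 0.
#' Returns the cosine similarity of the two abundance vectors (1 = perfect
#' shape agreement).
#'
#' @param observed data.frame(mz, intensity) of peaks near the precursor
#'   (>= 2 rows).
#' @param pattern An [IsotopePattern-class].
#' @param tolPpm Matching tolerance in ppm.
#' @return Cosine similarity in [0, 1].
#' @export
isotopeMatchScore <- function(observed, pattern, tolPpm = 5) {
  if (nrow(observed) < 2) stop("need >= 2 observed isotopologue peaks")
  obs <- numeric(length(pattern@mz))
  for (k in seq_along(pattern@mz)) {
    dppm <- abs(ppmError(observed$mz, pattern@mz[k]))
    i <- which.min(dppm)
    if (dppm[i] <= tolPpm) obs[k] <- obs[k] + observed$intensity[i]
  }
  if (sum(obs) == 0) return(0)
  sum(obs * pattern@abundance) /
    sqrt(sum(obs^2) * sum(pattern@abundance^2))
}

#' Colocalization among precursor and fragment images
#'
#' Extracts the precursor and each fragment image from PRM imaging data and
#' scores all pairs with [colocalizationScore()]; matching spatial
#' distributions support the fragments' assignment to the precursor.
#'
#' @param img A PRM [SpectrumImage-class].
#' @param settings A [PrmSettings-class].
#' @param mask Optional logical tissue mask.
#' @return list(r = pairwise Pearson matrix, images = the extracted
#'   [IonImage-class] objects).
#' @export
fragmentColoc <- function(img, settings = prmSettings(), mask = NULL) {
  targets <- c(precursor = settings@precursorMz,
               stats::setNames(settings@fragments$mz, settings@fragments$label))
  images <- lapply(targets, function(tmz)
    extractIonImage(img, tmz, settings@tolPpm))
  n <- length(images)
  r <- matrix(1, n, n, dimnames = list(names(targets), names(targets)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r[i, j] <- r[j, i] <-
      colocalizationScore(images[[i]], images[[j]], mask)$pearson_r
  }
  list(r = r, images = images)
}

#' Render a breakdown curve as PNG
#'
#' @param curve A [BreakdownCurve-class].
#' @param path Output PNG path.
#' @param normalized Plot fractions instead of raw abundances.
#' @return Invisibly, `path`.
#' @export
plotBreakdownCurve <- function(curve, path, normalized = TRUE) {
  y <- if (normalized) breakdownFractions(curve) else curve@abundance
  grDevices::png(path, width = 700, height = 500)
  on.exit(grDevices::dev.off())
  cols <- c("black", "steelblue", "firebrick", "darkgreen")
  graphics::matplot(curve@nce, y, type = "b", pch = 19, lty = 1,
                    col = cols[seq_len(ncol(y))], xlab = "NCE (%)",
                    ylab = if (normalized) "fraction of total" else "abundance")
  graphics::legend("right", legend = colnames(y), col = cols[seq_len(ncol(y))],
                   lty = 1, pch = 19)
  invisible(path)
}
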