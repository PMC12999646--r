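# Quadrant ROI statistics: square ROI placement, per-ROI abundance
# extraction, and the three z-score normalization schemes used to diagnose
# replicate-level systematic offsets.

#' Square regions of interest within quadrants
#'
#' A set of square pixel blocks, each assigned to one anatomical region,
#' pairwise disjoint and fully inside both the tissue mask and its region.
#'
#' @slot rois data.frame(region, x, y, side) with 0-based top-left corners.
#' @export
setClass("RoiSet", representation(rois = "data.frame"))

setValidity("RoiSet", function(object) {
  r <- object@rois
  if (!all(c("region", "x", "y", "side") %in% names(r)))
    return("rois needs columns region, x, y, side")
  TRUE
})

setMethod("show", "RoiSet", function(object) {
  cat("RoiSet:", nrow(object@rois), "ROIs of side",
      unique(object@rois$side), "\n")
  print(table(object@rois$region))
})

#' @describeIn RoiSet-class ROI table (region, x, y, side).
#' @param x A RoiSet.
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))
#' @rdname RoiSet-class
#' @export
setMethod("roiTable", "RoiSet", function(x) x@rois)

#' Place square ROIs in each quadrant
#'
#' Uniform-random rejection sampling of non-overlapping `side` x `side`
#' squares whose every pixel lies in the target region (and tissue mask),
#' deterministic for a fixed seed. The study default is 10 ROIs per region,
#' 40 in total.
#'
#' @param regionMap Integer matrix (0 = background) with a `levels`
#'   attribute naming the regions, as from [brainRegionMap()].
#' @param mask Optional logical tissue mask (defaults to regionMap > 0).
#' @param nPerRegion ROIs per region (default 10).
#' @param side ROI side length in pixels (default 3).
#' @param seed Integer seed.
#' @return A [RoiSet-class].
#' @export
placeRois <- function(regionMap, mask = NULL, nPerRegion = 10, side = 3,
                      seed = 1) {
  set.seed(seed)
  regions <- attr(regionMap, "levels")
  if (is.null(regions)) regions <- as.character(sort(unique(regionMap[regionMap > 0])))
  if (is.null(mask)) mask <- regionMap > 0
  ny <- nrow(regionMap); nx <- ncol(regionMap)
  occupied <- matrix(FALSE, ny, nx)
  out <- list()
  for (ri in seq_along(regions)) {
    ok <- regionMap == ri & mask
    # valid top-left corners: the whole block must fit in-region
    valid <- matrix(FALSE, ny, nx)
    if (ny >= side && nx >= side) {
      core <- ok
      for (dy in 0:(side - 1)) for (dx in 0:(side - 1)) {
        if (dx == 0 && dy == 0) next
        shifted <- matrix(FALSE, ny, nx)
        shifted[seq_len(ny - dy), seq_len(nx - dx)] <-
          ok[(1 + dy):ny, (1 + dx):nx]
        core <- core & shifted
      }
      valid[seq_len(ny - side + 1), seq_len(nx - side + 1)] <-
        core[seq_len(ny - side + 1), seq_len(nx - side + 1)]
    }
    cand <- which(valid)
    if (length(cand) < nPerRegion)
      stop("region '", regions[ri], "' cannot fit ", nPerRegion,
           " ROIs of side ", side)
    candY <- (cand - 1) %% ny + 1
    candX <- (cand - 1) %/% ny + 1
    alive <- rep(TRUE, length(cand))
    placed <- 0
    while (placed < nPerRegion) {
      if (!any(alive))
        stop("ROI placement infeasible in region '", regions[ri],
             "': only ", placed, " of ", nPerRegion, " disjoint ROIs fit")
      k <- which(alive)[sample.int(sum(alive), 1)]
      py <- candY[k]; px <- candX[k]
      occupied[py:(py + side - 1), px:(px + side - 1)] <- TRUE
      placed <- placed + 1
      out[[length(out) + 1]] <- data.frame(region = regions[ri],
                                           x = px - 1L, y = py - 1L,
                                           side = as.integer(side))
      # drop every candidate whose square would overlap the one just placed
      alive <- alive & (abs(candY - py) >= side | abs(candX - px) >= side)
    }
  }
  new("RoiSet", rois = do.call(rbind, out))
}

#' Extract per-ROI species abundances
#'
#' For each ROI and species image, the mean abundance over the ROI's pixels
#' (missing pixels excluded), and its log10 with an additive floor so empty
#' ROIs stay finite.
#'
#' @param images Named list of per-species [IonImage-class] (summed-adduct
#'   images by default upstream).
#' @param rois A [RoiSet-class].
#' @param condition,replicateId Labels copied into the table.
#' @param floor Additive offset before log10 (default 10, the detection
#'   floor).
#' @param categories Optional named character vector species -> LMSD
#'   category.
#' @return Long data.frame: condition, replicate_id, region, roi_index,
#'   species, category, mean_abundance, log_abundance.
#' @export
extractRoiAbundances <- function(images, rois, condition = "unknown",
                                 replicateId = "R1", floor = 10,
                                 categories = NULL) {
  r <- roiTable(rois)
  rows <- lapply(seq_len(nrow(r)), function(i) {
    ys <- (r$y[i] + 1):(r$y[i] + r$side[i])
    xs <- (r$x[i] + 1):(r$x[i] + r$side[i])
    vapply(images, function(im) {
      v <- imageValues(im)[ys, xs]
      m <- missingPixels(im)[ys, xs]
      if (all(m)) return(NA_real_)
      mean(v[!m])
    }, 0)
  })
  species <- names(images)
  roiIdx <- stats::ave(seq_len(nrow(r)), r$region, FUN = seq_along)
  out <- data.frame(
    condition = condition, replicate_id = replicateId,
    region = rep(r$region, each = length(species)),
    roi_index = rep(roiIdx, each = length(species)),
    species = rep(species, nrow(r)),
    mean_abundance = unlist(rows, use.names = FALSE))
  out$category <- if (is.null(categories)) NA_character_ else
    unname(categories[out$species])
  out$log_abundance <- log10(out$mean_abundance + floor)
  out
}

#' ROI table for a whole cohort
#'
#' Convenience wrapper: for every replicate, builds summed-adduct species
#' images, places its own seeded ROI set, and extracts abundances.
#'
#' @param cohort A [PhantomCohort-class].
#' @param panel Panel data.frame (default [defaultPanel()]); subset it to
#'   restrict species.
#' @param nPerRegion,side,seed ROI placement parameters.
#' @param tolPpm Extraction window half-width (ppm).
#' @param adductsOnly Optional adduct restriction (e.g. "M+H").
#' @param floor Additive floor before log10.
#' @return Long RoiTable data.frame (see [extractRoiAbundances()]).
#' @export
cohortRoiTable <- function(cohort, panel = defaultPanel(), nPerRegion = 10,
                           side = 3, seed = 1, tolPpm = 5,
                           adductsOnly = NULL, floor = 10) {
  info <- cohortInfo(cohort)
  rm <- cohortTruth(cohort)$regionMap
  categories <- stats::setNames(panel$category, panel$name)
  tabs <- lapply(seq_len(nrow(info)), function(i) {
    img <- cohortImages(cohort)[[i]]
    rois <- placeRois(rm, nPerRegion = nPerRegion, side = side,
                      seed = .childSeed(seed, info$replicate_id[i]))
    images <- stats::setNames(lapply(seq_len(nrow(panel)), function(k)
      speciesImage(img, panel[k, ], tolPpm = tolPpm,
                   adductsOnly = adductsOnly)), panel$name)
    extractRoiAbundances(images, rois, condition = info$condition[i],
                         replicateId = info$replicate_id[i], floor = floor,
                         categories = categories)
  })
  do.call(rbind, tabs)
}

.zScheme <- function(scheme) {
  switch(scheme,
         replicate = c("replicate_id", "species"),
         global = c("condition", "species"),
         region_global = c("condition", "region", "species"),
         stop("unknown scheme: ", scheme))
}

#' z-score normalization of ROI abundances
#'
#' Standardizes log abundances within the scheme's stratum:
#' \describe{
#'   \item{replicate}{rows of the same (replicate, species) — each analyte
#'     relative to that replicate's own average.}
#'   \item{global}{rows of the same (condition, species) — relative to the
#'     analyte's average across all replicates of that condition.}
#'   \item{region_global}{rows of the same (condition, region, species) —
#'     relative to the analyte's average in that region across replicates.}
#' }
#' Conditions are always normalized separately. A zero-SD stratum yields
#' z = 0 with a warning; a stratum with fewer than 2 rows is an error.
#'
#' @param table RoiTable data.frame with `log_abundance`.
#' @param scheme "replicate", "global" or "region_global".
#' @return The table with an added column `z_<scheme>`.
#' @export
zNormalize <- function(table, scheme = c("replicate", "global", "region_global")) {
  scheme <- match.arg(scheme)
  keys <- .zScheme(scheme)
  stratum <- interaction(table[keys], drop = TRUE, sep = "/")
  n <- table(stratum)
  if (any(n < 2))
    stop("stratum with < 2 rows under scheme '", scheme, "': ",
         names(n)[which(n < 2)[1]])
  mu <- stats::ave(table$log_abundance, stratum, FUN = mean)
  sdv <- stats::ave(table$log_abundance, stratum, FUN = stats::sd)
  z <- (table$log_abundance - mu) / sdv
  if (any(sdv == 0)) {
    warning("zero-SD stratum under scheme '", scheme, "'; z set to 0")
    z[sdv == 0] <- 0
  }
  table[[paste0("z_", scheme)]] <- z
  table
}

#' Region-level boxplot statistics of z-scores
#'
#' Tukey boxplot summaries (mean, quartiles, whiskers at 1.5 IQR) of the
#' chosen z column per condition x replicate x region — the display used to
#' spot replicate-wide systematic offsets.
#'
#' @param table RoiTable with the scheme's z column (see [zNormalize()]).
#' @param scheme Which z column to summarize.
#' @return data.frame(condition, replicate_id, region, n, mean, q1, median,
#'   q3, whisker_low, whisker_high).
#' @export
summarizeRegionBoxplots <- function(table,
                                    scheme = c("replicate", "global", "region_global")) {
  scheme <- match.arg(scheme)
  zcol <- paste0("z_", scheme)
  if (!zcol %in% names(table)) stop("run zNormalize(..., '", scheme, "') first")
  f <- interaction(table$condition, table$replicate_id, table$region,
                   drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(table, f), function(d) {
    z <- d[[zcol]]
    s <- grDevices::boxplot.stats(z, do.conf = FALSE, do.out = FALSE)$stats
    data.frame(condition = d$condition[1], replicate_id = d$replicate_id[1],
               region = d$region[1], n = length(z), mean = mean(z),
               q1 = s[2], median = s[3], q3 = s[4],
               whisker_low = s[1], whisker_high = s[5])
  }))
  rownames(out) <- NULL
  out
}
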