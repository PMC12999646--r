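# Differential abundance: whole-tissue and per-region volcano analysis
# between conditions, and descriptive two-solvent comparison statistics.

#' Whole-tissue abundances per replicate
#'
#' For every replicate, segments the tissue from its TIC and reports each
#' panel species' mean summed-adduct abundance over the mask.
#'
#' @param cohort A [PhantomCohort-class] (or list with the same accessors).
#' @param panel Panel data.frame.
#' @param maskMethod,maskParam Passed to [tissueMask()].
#' @param tolPpm Extraction window half-width (ppm).
#' @param adductsOnly Optional adduct restriction.
#' @return Long data.frame: species, category, replicate_id, condition,
#'   abundance.
#' @export
wholeTissueAbundances <- function(cohort, panel = defaultPanel(),
                                  maskMethod = "fraction", maskParam = 0.1,
                                  tolPpm = 5, adductsOnly = NULL) {
  info <- cohortInfo(cohort)
  if (length(unique(info$condition)) > 1 && any(table(info$condition) < 2))
    stop("need >= 2 replicates per condition")
  rows <- lapply(seq_len(nrow(info)), function(i) {
    img <- cohortImages(cohort)[[i]]
    mask <- tissueMask(ticImage(img), method = maskMethod, param = maskParam)
    ab <- vapply(seq_len(nrow(panel)), function(k) {
      im <- speciesImage(img, panel[k, ], tolPpm = tolPpm,
                         adductsOnly = adductsOnly)
      use <- mask & !missingPixels(im)
      mean(imageValues(im)[use])
    }, 0)
    data.frame(species = panel$name, category = panel$category,
               replicate_id = info$replicate_id[i],
               condition = info$condition[i], abundance = ab)
  })
  do.call(rbind, rows)
}

.effectClass <- function(lfc) {
  a <- abs(lfc)
  ifelse(a > 2, "large",
         ifelse(a > 1.5, "intermediate",
                ifelse(a > 0.6, "small_moderate", "none")))
}

#' Volcano analysis between two conditions
#'
#' Per species: log2 fold change as the difference of mean log2 replicate
#' abundances (group A minus group B), a Welch two-sample t-test (or
#' Mann-Whitney) on the log2 values, Benjamini-Hochberg adjustment across
#' all species, and significance at |log2fc| > `lfcThreshold` and adjusted
#' p < `alpha`. Non-positive abundances are excluded with a warning before
#' the log. Effect sizes are additionally labelled none / small_moderate
#' (0.6, 1.5] / intermediate (1.5, 2] / large (> 2).
#'
#' @param abundances Long data.frame from [wholeTissueAbundances()] (or any
#'   table with species, category, condition, replicate_id, abundance).
#' @param groupA,groupB Condition labels; fold changes are A vs B.
#' @param lfcThreshold,alpha Significance thresholds (defaults 0.6, 0.05).
#' @param test "welch" or "wilcoxon".
#' @return data.frame: species, category, n_a, n_b, log2fc, p_value,
#'   p_adjusted, significant, effect_class.
#' @export
volcano <- function(abundances, groupA = "diseased", groupB = "healthy",
                    lfcThreshold = 0.6, alpha = 0.05,
                    test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  ab <- abundances[abundances$condition %in% c(groupA, groupB), ]
  for (grp in c(groupA, groupB)) {
    n <- table(ab$species[ab$condition == grp])
    if (!length(n) || any(n < 2))
      stop("group '", grp, "': each group needs >= 2 replicates per species")
  }
  if (any(ab$abundance <= 0)) {
    warning("excluding ", sum(ab$abundance <= 0),
            " non-positive abundances before log transform")
    ab <- ab[ab$abundance > 0, ]
  }
  out <- do.call(rbind, lapply(split(ab, ab$species), function(d) {
    la <- log2(d$abundance[d$condition == groupA])
    lb <- log2(d$abundance[d$condition == groupB])
    if (length(la) < 2 || length(lb) < 2) {
      warning("species '", d$species[1],
              "': fewer than 2 positive replicates in a group; reported as NA")
      return(data.frame(species = d$species[1], category = d$category[1],
                        n_a = length(la), n_b = length(lb),
                        log2fc = NA_real_, p_value = NA_real_))
    }
    p <- if (test == "welch") {
      tryCatch(stats::t.test(la, lb, var.equal = FALSE)$p.value,
               error = function(e) 1)
    } else stats::wilcox.test(la, lb, exact = FALSE)$p.value
    data.frame(species = d$species[1], category = d$category[1],
               n_a = length(la), n_b = length(lb),
               log2fc = mean(la) - mean(lb), p_value = p)
  }))
  rownames(out) <- NULL
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_adjusted) &
    abs(out$log2fc) > lfcThreshold & out$p_adjusted < alpha
  out$effect_class <- .effectClass(out$log2fc)
  out
}

#' Per-region volcano analysis from ROI data
#'
#' Collapses each replicate's ROIs within the region to a replicate-level
#' regional mean abundance per species, then runs the same two-condition
#' test as [volcano()]. Because regional means of scarce analytes sit at or
#' below the detection floor (exact zeros in a censored acquisition), the
#' same additive floor used for the ROI log transform is applied before the
#' log so the comparison stays defined; fold changes of floor-level species
#' are therefore conservative.
#'
#' @param roiTab RoiTable data.frame (see [cohortRoiTable()]).
#' @param region Region label to analyze.
#' @param floor Additive offset (charges/s) applied to regional means before
#'   the log (default 10, the detection floor; 0 restores plain log ratios).
#' @param ... Passed to [volcano()].
#' @return A volcano table (see [volcano()]).
#' @export
regionalVolcano <- function(roiTab, region, floor = 10, ...) {
  d <- roiTab[roiTab$region == region, ]
  if (!nrow(d)) stop("no ROIs in region '", region, "'")
  f <- interaction(d$species, d$replicate_id, drop = TRUE)
  agg <- do.call(rbind, lapply(split(d, f), function(g)
    data.frame(species = g$species[1], category = g$category[1],
               replicate_id = g$replicate_id[1], condition = g$condition[1],
               abundance = mean(g$mean_abundance, na.rm = TRUE) + floor)))
  volcano(agg, ...)
}

#' Default mass-range comparison groups
#'
#' The three ion groups used to compare solvent compositions across the
#' lower (300-325 Th), central (545-570 Th) and upper (745-770 Th) mass
#' ranges, with their 14 member ions (observed m/z with LMSD labels).
#'
#' @return List of list(name, range, members) with named member m/z vectors.
#' @export
defaultMassRangeGroups <- function() {
  list(
    list(name = "low", range = c(300, 325),
         members = c("PR01 305.2475" = 305.2475, "FA01 313.2737" = 313.2737,
                     "FA01 315.2530" = 315.2530)),
    list(name = "central", range = c(545, 570),
         members = c("FA07 548.5401" = 548.5401, "SP01 566.5506" = 566.5506)),
    list(name = "upper", range = c(745, 770),
         members = c("GP01 758.5694" = 758.5694, "GP01 760.5851" = 760.5851,
                     "SP01 761.5886" = 761.5886,
                     "GP01/GP10 762.6007" = 762.6007,
                     "GP01/GP10 764.5225" = 764.5225,
                     "GP01/GP10 766.5381" = 766.5381,
                     "GP01 768.5514" = 768.5514, "GP01 768.5538" = 768.5538,
                     "GP01 772.5851" = 772.5851)))
}

#' Compare standard vs doped electrospray solvent
#'
#' Descriptive comparison of two acquisitions of the same tissue: per
#' species, log2(doped/standard) of the on-tissue mean summed-adduct
#' abundance; per LMSD category, box statistics of those ratios; per
#' mass-range group, the summed member-ion abundances under each solvent
#' and the standard/doped fold ratio; and the fraction of evaluated group
#' ions that prefer (are more abundant under) the standard solvent. Species
#' missing in either condition are flagged and excluded from ratios.
#'
#' @param imgStandard,imgDoped [SpectrumImage-class] acquisitions.
#' @param panel Panel data.frame.
#' @param groups Mass-range groups (default [defaultMassRangeGroups()]).
#' @param tolPpm Extraction window half-width (ppm).
#' @param maskMethod,maskParam Passed to [tissueMask()].
#' @return list(species, categories, groups, ion_preferences,
#'   preference_fraction).
#' @export
solventCompare <- function(imgStandard, imgDoped, panel = defaultPanel(),
                           groups = defaultMassRangeGroups(), tolPpm = 5,
                           maskMethod = "fraction", maskParam = 0.1) {
  meanAb <- function(img, mzs) {
    mask <- tissueMask(ticImage(img), method = maskMethod, param = maskParam)
    vapply(mzs, function(mz) {
      im <- extractIonImage(img, mz, tolPpm)
      use <- mask & !missingPixels(im)
      mean(imageValues(im)[use])
    }, 0)
  }
  speciesMean <- function(img) {
    mask <- tissueMask(ticImage(img), method = maskMethod, param = maskParam)
    vapply(seq_len(nrow(panel)), function(k) {
      im <- speciesImage(img, panel[k, ], tolPpm = tolPpm)
      use <- mask & !missingPixels(im)
      mean(imageValues(im)[use])
    }, 0)
  }
  s <- speciesMean(imgStandard)
  d <- speciesMean(imgDoped)
  defined <- s > 0 & d > 0
  species <- data.frame(species = panel$name, category = panel$category,
                        standard = s, doped = d, defined = defined,
                        log2_ratio = ifelse(defined, log2(d / s), NA_real_))
  if (any(!defined))
    warning(sum(!defined), " species absent in one condition; excluded from ratios")
  categories <- do.call(rbind, lapply(split(species[defined, ],
                                            species$category[defined]), function(g) {
    q <- stats::quantile(g$log2_ratio, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(category = g$category[1], n = nrow(g), mean = mean(g$log2_ratio),
               q1 = q[1], median = q[2], q3 = q[3])
  }))
  rownames(categories) <- NULL
  prefs <- list(); grows <- list()
  for (g in groups) {
    sa <- meanAb(imgStandard, g$members)
    da <- meanAb(imgDoped, g$members)
    grows[[g$name]] <- data.frame(group = g$name, range_low = g$range[1],
                                  range_high = g$range[2],
                                  n_members = length(g$members),
                                  standard_sum = sum(sa), doped_sum = sum(da),
                                  fold_standard_over_doped = sum(sa) / sum(da))
    prefs[[g$name]] <- data.frame(group = g$name, ion = names(g$members),
                                  mz = unname(g$members), standard = sa,
                                  doped = da, prefers_standard = sa > da)
  }
  ionPrefs <- do.call(rbind, prefs)
  rownames(ionPrefs) <- NULL
  list(species = species, categories = categories,
       groups = do.call(rbind, grows), ion_preferences = ionPrefs,
       preference_fraction = mean(ionPrefs$prefers_standard))
}

#' Paired binned mean spectra for a reflection plot
#'
#' Averages the on-tissue spectrum of each acquisition (total intensity per
#' m/z bin divided by the number of tissue pixels) over a common binning of
#' the overlapping scan range. Plotting mirrors condition B downward.
#'
#' @param imgA,imgB [SpectrumImage-class] acquisitions.
#' @param binWidth Bin width in Th (default 1).
#' @param maskMethod,maskParam Passed to [tissueMask()].
#' @return data.frame(bin_mz [bin center], mean_a, mean_b).
#' @export
reflectionData <- function(imgA, imgB, binWidth = 1,
                           maskMethod = "fraction", maskParam = 0.1) {
  lo <- max(acqMetadata(imgA)@scanRange[1], acqMetadata(imgB)@scanRange[1])
  hi <- min(acqMetadata(imgA)@scanRange[2], acqMetadata(imgB)@scanRange[2])
  if (lo >= hi) stop("scan ranges do not overlap")
  nbin <- ceiling((hi - lo) / binWidth)
  binned <- function(img) {
    mask <- tissueMask(ticImage(img), method = maskMethod, param = maskParam)
    maskVec <- mask[cbind(img@coords[, 2] + 1L, img@coords[, 1] + 1L)]
    onPeak <- maskVec[.pixelIndexVector(img)]
    mz <- img@mz[onPeak]; int <- img@intensity[onPeak]
    inb <- mz >= lo & mz < hi
    idx <- pmin(floor((mz[inb] - lo) / binWidth) + 1, nbin)
    v <- numeric(nbin)
    agg <- rowsum(int[inb], idx)
    v[as.integer(rownames(agg))] <- agg[, 1]
    v / sum(maskVec)
  }
  data.frame(bin_mz = lo + (seq_len(nbin) - 0.5) * binWidth,
             mean_a = binned(imgA), mean_b = binned(imgB))
}

#' Render a mirrored reflection plot as PNG
#'
#' @param rd data.frame from [reflectionData()].
#' @param path Output PNG path.
#' @param labels Condition labels for the upper/lower traces.
#' @return Invisibly, `path`.
#' @export
plotReflection <- function(rd, path, labels = c("standard", "doped")) {
  grDevices::png(path, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  ylim <- max(rd$mean_a, rd$mean_b)
  plot(NA, xlim = range(rd$bin_mz), ylim = c(-ylim, ylim),
       xlab = "m/z", ylab = "mean abundance (charges/s)", main = "")
  graphics::segments(rd$bin_mz, 0, rd$bin_mz, rd$mean_a, col = "steelblue")
  graphics::segments(rd$bin_mz, 0, rd$bin_mz, -rd$mean_b, col = "firebrick")
  graphics::abline(h = 0)
  graphics::legend("topright", legend = labels, fill = c("steelblue", "firebrick"))
  invisible(path)
}
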