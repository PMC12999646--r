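# ROI placement, abundance extraction and the three z-score schemes.

.constantImage <- function(value, nx = 20, ny = 16) {
  new("IonImage", values = matrix(value, ny, nx),
      missing = matrix(FALSE, ny, nx), targetMz = NA_real_,
      tolPpm = NA_real_, label = "const")
}

test_that("ROI placement yields 40 disjoint in-region squares, reproducibly", {
  rm <- brainRegionMap(c(120L, 80L))
  rois <- placeRois(rm$region, seed = 5)
  r <- roiTable(rois)
  expect_identical(nrow(r), 40L)
  expect_identical(as.integer(table(r$region)), rep(10L, 4))
  occupied <- matrix(0L, 80, 120)
  for (i in seq_len(nrow(r))) {
    ys <- (r$y[i] + 1):(r$y[i] + r$side[i])
    xs <- (r$x[i] + 1):(r$x[i] + r$side[i])
    occupied[ys, xs] <- occupied[ys, xs] + 1L
    # every pixel of the square lies in the labelled region
    expect_true(all(rm$region[ys, xs] == match(r$region[i], attr(rm$region, "levels"))))
  }
  expect_lte(max(occupied), 1L)          # pairwise disjoint
  again <- placeRois(rm$region, seed = 5)
  expect_identical(roiTable(again), r)
  expect_false(identical(roiTable(placeRois(rm$region, seed = 6)), r))
})

test_that("oversized ROIs are rejected with the offending region named", {
  rm <- brainRegionMap(c(40L, 28L))
  expect_error(placeRois(rm$region, side = 30), "cannot fit")
})

test_that("ROI means are exact on constant images and skip missing pixels", {
  rois <- new("RoiSet", rois = data.frame(region = "cerebrum", x = 2L, y = 3L,
                                          side = 3L))
  tab <- extractRoiAbundances(list(sp = .constantImage(7)), rois,
                              floor = 10)
  expect_identical(tab$mean_abundance, 7)
  expect_identical(tab$log_abundance, log10(17))
  holed <- .constantImage(7)
  holed@values[4, 3] <- 99
  holed@missing[4, 3] <- TRUE            # inflated value must be ignored
  tab2 <- extractRoiAbundances(list(sp = holed), rois)
  expect_identical(tab2$mean_abundance, 7)
})

test_that("each z scheme standardizes its stratum exactly", {
  cfg <- tinyConfig()
  cohort <- generateCohort(cfg, seed = 41)
  panel <- cfg@panel[cfg@panel$name %in%
                       c("cholesterol", "GalCer(d18:1/18:0)", "SM(d18:1/16:0)"), ]
  tab <- cohortRoiTable(cohort, panel, nPerRegion = 4, side = 2, seed = 41)
  for (scheme in c("replicate", "global", "region_global")) {
    tab <- zNormalize(tab, scheme)
    z <- tab[[paste0("z_", scheme)]]
    strata <- interaction(tab[msikit:::.zScheme(scheme)], drop = TRUE)
    mus <- as.numeric(tapply(z, strata, mean))
    sds <- as.numeric(tapply(z, strata, sd))
    expect_equal(mus, rep(0, length(mus)), tolerance = 1e-12)
    expect_equal(sds, rep(1, length(sds)), tolerance = 1e-12)
  }
})

test_that("a replicate offset shows in global but not replicate z-scores", {
  cfg <- phantomConfig(gridShape = c(60L, 40L),
                       panel = nullPanel()[2:7, ],  # psychosine is floor-censored here
                       anticorrelate = character(0))
  noise <- noiseModel(replicateOffsetSd = 0)
  offsets <- c(0, 0, 0, 1)               # last diseased replicate shifted +1 log2
  ids <- c("TW1", "TW2", "TW3", "TW4")
  images <- lapply(1:4, function(i)
    generatePhantom(cfg, noise, "diseased", ids[i], seed = 300 + i,
                    replicateOffsetLog2 = offsets[i]))
  cohort <- new("PhantomCohort", images = images,
                info = data.frame(replicate_id = ids, condition = "diseased",
                                  seed = 300 + (1:4), offset_log2 = offsets),
                truth = list(regionMap = brainRegionMap(cfg@gridShape)$region))
  tab <- cohortRoiTable(cohort, cfg@panel, nPerRegion = 8, side = 2, seed = 1)
  tab <- zNormalize(zNormalize(tab, "replicate"), "global")
  perRegion <- function(col, rep)
    tapply(tab[[col]][tab$replicate_id == rep],
           tab$region[tab$replicate_id == rep], mean)
  expect_true(all(perRegion("z_global", "TW4") > 0.2))
  # replicate normalization absorbs the offset: region means are only
  # sampling noise (SD ~ 1/sqrt(n) for an 8-ROI x 6-species region mean)
  expect_true(all(abs(perRegion("z_replicate", "TW4")) < 0.35))
  expect_gt(min(perRegion("z_global", "TW4")),
            max(abs(perRegion("z_replicate", "TW4"))))
  # recovered replicate means track injected offsets only before
  # replicate normalization
  repMeansGlobal <- tapply(tab$z_global, tab$replicate_id, mean)
  expect_gt(cor(repMeansGlobal, offsets), 0.9)
})

test_that("region-global z ignores region-wide scale factors", {
  cfg <- tinyConfig()
  cohort <- generateCohort(cfg, seed = 51)
  panel <- cfg@panel[cfg@panel$name == "cholesterol", ]
  tab <- cohortRoiTable(cohort, panel, nPerRegion = 4, side = 2, seed = 51)
  scaled <- tab
  cere <- scaled$region == "cerebellum"
  scaled$mean_abundance[cere] <- scaled$mean_abundance[cere] * 10
  scaled$log_abundance[cere] <- log10(scaled$mean_abundance[cere] + 10)
  z1 <- zNormalize(tab, "region_global")$z_region_global
  z2 <- zNormalize(scaled, "region_global")$z_region_global
  expect_equal(z1[!cere], z2[!cere], tolerance = 1e-12)
  # multiplying one region across all replicates is absorbed by the
  # stratum mean up to the additive log floor
  expect_equal(z1[cere], z2[cere], tolerance = 0.05)
})

test_that("boxplot summaries have one row per condition-replicate-region", {
  cfg <- tinyConfig()
  cohort <- generateCohort(cfg, seed = 61)
  panel <- cfg@panel[2:5, ]
  tab <- zNormalize(cohortRoiTable(cohort, panel, nPerRegion = 3, side = 2,
                                   seed = 61), "replicate")
  box <- summarizeRegionBoxplots(tab, "replicate")
  expect_identical(nrow(box), 7L * 4L)
  expect_true(all(box$whisker_low <= box$q1 & box$q3 <= box$whisker_high))
  # symmetric synthetic z: median tracks mean
  sym <- tab
  sym$z_replicate <- rep(c(-2, -1, 0, 1, 2), length.out = nrow(sym))
  boxSym <- summarizeRegionBoxplots(sym, "replicate")
  expect_equal(boxSym$median, boxSym$mean, tolerance = 0.35)
})

test_that("degenerate strata are reported", {
  tab <- data.frame(condition = "diseased", replicate_id = "R1",
                    region = "cerebrum", roi_index = 1, species = "x",
                    mean_abundance = 5, log_abundance = log10(15))
  expect_error(zNormalize(tab, "replicate"), "stratum")
  two <- rbind(tab, tab)
  expect_warning(z <- zNormalize(two, "replicate"), "zero-SD")
  expect_identical(z$z_replicate, c(0, 0))
})
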