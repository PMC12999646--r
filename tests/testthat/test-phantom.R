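# Ground-truth contracts of the synthetic brain phantom and the
# fragmentation-ramp generator.

test_that("fixed seeds regenerate byte-identical imzML", {
  cfg <- tinyConfig()
  a <- generatePhantom(cfg, condition = "diseased", seed = 99)
  b <- generatePhantom(cfg, condition = "diseased", seed = 99)
  expect_identical(a@mz, b@mz)
  expect_identical(a@intensity, b@intensity)
  pa <- writeImzML(a, file.path(tempdir(), "seedA"))
  pb <- writeImzML(b, file.path(tempdir(), "seedB"))
  expect_identical(unname(tools::md5sum(pa$ibd)), unname(tools::md5sum(pb$ibd)))
  c2 <- generatePhantom(cfg, condition = "diseased", seed = 100)
  expect_false(identical(a@mz, c2@mz))
})

test_that("region map paints four disjoint quadrants covering the tissue", {
  rm <- brainRegionMap(c(120L, 80L))
  expect_identical(attr(rm$region, "levels"),
                   c("cerebrum", "cerebellum", "brain_stem", "midbrain"))
  expect_identical(unname(rm$mask), unname(rm$region > 0))
  counts <- tabulate(rm$region[rm$region > 0], 4)
  expect_true(all(counts > 100))          # each quadrant fits 10 3x3 ROIs
  expect_true(all(rm$region[rm$hotspot] == 1))  # hotspot inside cerebrum
})

test_that("injected fold changes are recovered as generator mean ratios", {
  # noise-free-floor config so truncation cannot bias region means
  noise <- noiseModel(detectionFloor = 0, decoyDensity = 0)
  cfg <- phantomConfig(gridShape = c(80L, 56L), anticorrelate = character(0))
  d <- generatePhantom(cfg, noise, "diseased", seed = 21, replicateOffsetLog2 = 0)
  h <- generatePhantom(cfg, noise, "healthy", seed = 22, replicateOffsetLog2 = 0)
  rm <- brainRegionMap(cfg@gridShape)
  psy <- function(img) speciesImage(img, cfg@panel[cfg@panel$name == "psychosine", ])
  ratio <- mean(imageValues(psy(d))[rm$region == 2]) /
    mean(imageValues(psy(h))[rm$region == 2])
  expect_equal(ratio, 2^2.5, tolerance = 0.1)
})

test_that("healthy psychosine stays near the detection floor everywhere", {
  cfg <- tinyConfig()
  noise <- noiseModel()
  img <- generatePhantom(cfg, noise, "healthy", seed = 5, replicateOffsetLog2 = 0)
  rm <- brainRegionMap(gridShape(img))
  psy <- speciesImage(img, cfg@panel[cfg@panel$name == "psychosine", ])
  for (r in 1:4)
    expect_lt(mean(imageValues(psy)[rm$region == r]), 3 * noise@detectionFloor)
})

test_that("sample means converge to configured expectations (law of large numbers)", {
  panel <- panelEntry("probe", "C27H46O", "ST",
                      adducts = c("M+H" = 1), baseline = 100)
  cfg <- phantomConfig(gridShape = c(180L, 120L), panel = panel,
                       anticorrelate = character(0))
  noise <- noiseModel(lognormalSigma = 0.4, ppmJitterSd = 0,
                      detectionFloor = 0, decoyDensity = 0)
  img <- generatePhantom(cfg, noise, "healthy", seed = 8, replicateOffsetLog2 = 0)
  rm <- brainRegionMap(cfg@gridShape)
  v <- imageValues(speciesImage(img, panel))[rm$mask]
  expect_gt(length(v), 10000)
  expected <- 100 * exp(0.4^2 / 2)       # log-normal mean
  se <- stats::sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - expected), 3 * se)
})

test_that("empirical mass-jitter SD matches the noise model within 10%", {
  panel <- panelEntry("probe", "C24H47NO7", "SP", adducts = c("M+H" = 1),
                      baseline = 500)
  cfg <- phantomConfig(gridShape = c(120L, 80L), panel = panel,
                       anticorrelate = character(0))
  noise <- noiseModel(ppmJitterSd = 0.8, detectionFloor = 0, decoyDensity = 0)
  img <- generatePhantom(cfg, noise, "healthy", seed = 12, replicateOffsetLog2 = 0)
  target <- adductMz("C24H47NO7", "M+H")
  errs <- ppmError(img@mz[abs(img@mz - target) < 0.01], target)
  expect_gt(length(errs), 3000)
  expect_equal(sd(errs), 0.8, tolerance = 0.1)
  expect_lt(max(abs(errs)), 5)
})

test_that("cohorts carry matching grids and echo the configured truth", {
  cfg <- tinyConfig()
  cohort <- generateCohort(cfg, seed = 31)
  expect_length(cohortImages(cohort), 7)
  shapes <- vapply(cohortImages(cohort), gridShape, integer(2))
  expect_true(all(shapes == shapes[, 1]))
  info <- cohortInfo(cohort)
  expect_identical(table(info$condition)[["healthy"]], 3L)
  expect_identical(table(info$condition)[["diseased"]], 4L)
  truth <- cohortTruth(cohort)$log2fc
  expect_equal(truth$log2fc[truth$species == "psychosine" &
                              truth$region == "cerebellum"], 2.5)
  # same root seed regenerates the identical cohort
  again <- generateCohort(cfg, seed = 31)
  expect_identical(cohortImages(cohort)[[5]]@mz, cohortImages(again)[[5]]@mz)
})

test_that("breakdown model fractions behave across the NCE axis", {
  fm <- fragmentationModel()
  fr0 <- fragmentationFractions(fm, 0)
  expect_gt(fr0$precursor, 0.9)          # no fragmentation without energy
  frx <- fragmentationFractions(fm, fm@crossoverNce)
  expect_equal(frx$frag282, frx$frag264) # exact equality at the crossover
  frh <- fragmentationFractions(fm, 45)
  expect_gt(frh$frag264, frh$frag282)    # small fragment wins at high NCE
  nce <- 35:50
  fr <- fragmentationFractions(fm, nce)
  expect_true(all(diff(fr$frag282) <= 0))
  expect_true(all(diff(fr$frag264) >= 0))
  expect_equal(rowSums(fr[, c("precursor", "frag282", "frag264")]),
               rep(1, length(nce)))
})

test_that("noiseless ramp data reproduce the model expectations exactly", {
  fm <- fragmentationModel()
  ramp <- generateBreakdownData(fm, nceGrid = c(10, 16, 22), nScans = 2,
                                seed = 1, totalAbundance = 1000,
                                scanNoiseSigma = 0, ppmJitterSd = 0)
  at16 <- ramp[ramp$nce == 16, ]
  fr <- fragmentationFractions(fm, 16)
  expect_equal(at16$intensity[at16$ion == "frag282" & at16$scan == 1],
               1000 * fr$frag282)
  expect_equal(at16$intensity[at16$ion == "frag264" & at16$scan == 1],
               1000 * fr$frag264)
  expect_error(generateBreakdownData(fm, nceGrid = numeric(0)), "non-empty")
})

test_that("section holes drop pixels but leave the grid consistent", {
  cfg <- tinyConfig(holeFraction = 0.1)
  img <- generatePhantom(cfg, condition = "diseased", seed = 17)
  full <- tinyConfig()
  ref <- generatePhantom(full, condition = "diseased", seed = 17)
  expect_lt(nPixels(img), nPixels(ref))
  expect_true(validObject(img))
})
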