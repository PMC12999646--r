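# ppm-window extraction, adduct summing, colocalization and rendering.

test_that("extraction keeps only in-window centroids", {
  img <- spectrumImage(
    list(list(mz = c(462.3425, 462.40), intensity = c(50, 99))),
    coords = matrix(c(0L, 0L), 1), gridShape = c(1L, 1L))
  im <- extractIonImage(img, 462.3425, 5)
  expect_identical(imageValues(im)[1, 1], 50)  # second peak is ~124 ppm away
})

test_that("extraction equals the linear-scan oracle on random spectra", {
  set.seed(202)
  total <- 0
  for (trial in 1:40) {
    img <- randomSpectrumImage(5, 5, maxPeaks = 30)
    total <- total + nPixels(img)
    for (target in runif(2, 250, 750)) {
      tol <- sample(c(5, 50, 5000), 1)  # include wide windows that catch peaks
      fast <- extractIonImage(img, target, tol)
      expect_identical(imageValues(fast), linearScanImage(img, target, tol))
      fastMax <- extractIonImage(img, target, tol, reducer = "max")
      expect_identical(imageValues(fastMax),
                       linearScanImage(img, target, tol, "max"))
    }
  }
  expect_gte(total, 1000)
})

test_that("targets outside the scan range warn and return zeros", {
  set.seed(9)
  img <- randomSpectrumImage(3, 3)
  expect_warning(im <- extractIonImage(img, 1500, 5), "outside scan range")
  expect_true(all(imageValues(im) == 0))
})

test_that("summing adduct images is linear and label-preserving", {
  set.seed(33)
  img <- randomSpectrumImage(4, 4)
  a <- extractIonImage(img, 400, 5000)
  s <- summedIonImage(list(a, a))
  expect_identical(imageValues(s), 2 * imageValues(a))
  expect_error(summedIonImage(list()), "empty")
  # disjoint windows partition the axis: sum of extracts = union extract
  lo <- extractIonImage(img, 400 * (1 - 25e-6), 25)
  hi <- extractIonImage(img, 400 * (1 + 25e-6), 25)
  both <- extractIonImage(img, 400, 50)
  expect_equal(imageValues(lo) + imageValues(hi), imageValues(both))
})

test_that("summed adduct images recover total species abundance", {
  panel <- panelEntry("psychosine", "C24H47NO7", "SP",
                      adducts = c("M+H" = 0.7, "M+H-H2O" = 0.1,
                                  "M+NH4" = 0.1, "M+Na" = 0.1),
                      baseline = 200)
  cfg <- phantomConfig(gridShape = c(60L, 40L), panel = panel,
                       anticorrelate = character(0))
  noise <- noiseModel(lognormalSigma = 0.3, detectionFloor = 0, decoyDensity = 0)
  img <- generatePhantom(cfg, noise, "healthy", seed = 2, replicateOffsetLog2 = 0)
  rm <- brainRegionMap(cfg@gridShape)
  total <- speciesImage(img, panel)
  mh <- speciesImage(img, panel, adductsOnly = "M+H")
  expect_equal(mean(imageValues(total)[rm$mask]), 200 * exp(0.3^2 / 2),
               tolerance = 0.03)
  expect_equal(mean(imageValues(mh)[rm$mask]) / mean(imageValues(total)[rm$mask]),
               0.7, tolerance = 0.02)
})

test_that("diseased psychosine concentrates in the posterior quadrants", {
  cfg <- phantomConfig(gridShape = c(80L, 56L))
  img <- generatePhantom(cfg, condition = "diseased", seed = 14,
                         replicateOffsetLog2 = 0)
  rm <- brainRegionMap(cfg@gridShape)
  psy <- extractIonImage(img, adductMz("C24H47NO7", "M+H"), 5)
  posterior <- rm$region %in% c(2, 3)
  anterior <- rm$region == 1 & !rm$hotspot
  expect_gt(mean(imageValues(psy)[posterior]),
            4 * mean(imageValues(psy)[anterior]))
})

test_that("colocalization is exact on self-comparison and flags degenerate input", {
  set.seed(61)
  img <- randomSpectrumImage(6, 6)
  a <- extractIonImage(img, 500, 5e5)
  sc <- colocalizationScore(a, a)
  expect_equal(sc$pearson_r, 1)
  expect_equal(sc$overlap_fraction, 1)
  flat <- a; flat@values[] <- 3
  expect_warning(sc2 <- colocalizationScore(flat, a), "zero-variance")
  expect_true(is.na(sc2$pearson_r))
})

test_that("the injected anti-correlation shows up in the diseased cerebellum", {
  cfg <- phantomConfig(gridShape = c(100L, 68L))
  img <- generatePhantom(cfg, condition = "diseased", seed = 4,
                         replicateOffsetLog2 = 0)
  rm <- brainRegionMap(cfg@gridShape)
  psy <- speciesImage(img, cfg@panel[cfg@panel$name == "psychosine", ])
  chol <- speciesImage(img, cfg@panel[cfg@panel$name == "cholesterol", ])
  sc <- colocalizationScore(psy, chol, rm$region == 2)
  expect_lt(sc$pearson_r, 0)
})

test_that("independent noise images decorrelate at large pixel counts", {
  set.seed(7)
  hits <- 0
  for (i in 1:10) {
    v1 <- matrix(rexp(10000), 100, 100)
    v2 <- matrix(rexp(10000), 100, 100)
    miss <- matrix(FALSE, 100, 100)
    a <- new("IonImage", values = v1, missing = miss, targetMz = NA_real_,
             tolPpm = NA_real_, label = "a")
    b <- new("IonImage", values = v2, missing = miss, targetMz = NA_real_,
             tolPpm = NA_real_, label = "b")
    if (abs(colocalizationScore(a, b)$pearson_r) < 0.1) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("heat map rendering is deterministic and blends overlays additively", {
  set.seed(88)
  img <- randomSpectrumImage(5, 4)
  tic <- ticImage(img)
  p1 <- file.path(tempdir(), "h1.png"); p2 <- file.path(tempdir(), "h2.png")
  renderHeatmap(tic, p1); renderHeatmap(tic, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # all-zero image renders a uniform background
  zero <- tic; zero@values[] <- 0; zero@missing[] <- FALSE
  pz <- file.path(tempdir(), "zero.png")
  renderHeatmap(zero, pz)
  px <- png::readPNG(pz)
  expect_identical(length(unique(as.vector(px[, , 1]))), 1L)
  # identical channels in red + green blend to yellow (R = G >> B)
  po <- file.path(tempdir(), "ov.png")
  renderOverlay(list(tic, tic), po, colors = c("red", "green"))
  ov <- png::readPNG(po)
  expect_identical(ov[, , 1], ov[, , 2])
  expect_true(all(ov[, , 3] == 0))
  # channel order does not change the blend
  po2 <- file.path(tempdir(), "ov2.png")
  renderOverlay(list(tic, tic), po2, colors = c("green", "red"))
  expect_identical(unname(tools::md5sum(po)), unname(tools::md5sum(po2)))
})
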