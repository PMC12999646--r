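# imzML round trips, coordinate conventions, checksums and the pixel-indexed
# spectrum model.

test_that("imzML round trip preserves peaks exactly and metadata labels", {
  set.seed(101)
  img <- randomSpectrumImage(6, 5)
  img@metadata <- acquisitionMetadata(spatialResolution = 150,
                                      scanRange = c(200, 800),
                                      condition = "diseased",
                                      replicateId = "TW2", solvent = "doped",
                                      iceMatrix = FALSE)
  base <- file.path(tempdir(), "roundtrip")
  writeImzML(img, base)
  back <- readImzML(base)
  expect_identical(nPixels(back), nPixels(img))
  expect_identical(diff(back@pointers), diff(img@pointers))  # peak counts
  expect_identical(back@coords, img@coords)
  expect_identical(back@mz, img@mz)                          # float64 exact
  expect_equal(back@intensity, img@intensity,
               tolerance = 2^-23)                            # float32 storage
  md <- acqMetadata(back)
  expect_identical(md@condition, "diseased")
  expect_identical(md@replicateId, "TW2")
  expect_identical(md@solvent, "doped")
  expect_false(md@iceMatrix)
  expect_identical(md@spatialResolution, 150)
})

test_that("a one-pixel one-peak file survives the round trip", {
  img <- spectrumImage(list(list(mz = 462.3425, intensity = 100)),
                       coords = matrix(c(0L, 0L), 1), gridShape = c(1L, 1L))
  base <- file.path(tempdir(), "onepixel")
  writeImzML(img, base)
  back <- readImzML(base)
  s <- spectrumAt(back, 0, 0)
  expect_identical(s$mz, 462.3425)
  expect_equal(s$intensity, 100, tolerance = 1e-6)
})

test_that("coordinates are 1-based on disk and 0-based in memory", {
  img <- spectrumImage(list(list(mz = 300, intensity = 5),
                            list(mz = 400, intensity = 6)),
                       coords = matrix(c(0L, 0L, 2L, 1L), 2, byrow = TRUE),
                       gridShape = c(3L, 2L))
  base <- file.path(tempdir(), "coords")
  writeImzML(img, base)
  xml <- readLines(paste0(base, ".imzML"))
  xs <- regmatches(xml, regexpr('IMS:1000050" name="position x" value="[0-9]+', xml))
  expect_identical(sub('.*value="', "", xs), c("1", "3"))
  back <- readImzML(base)
  expect_identical(back@coords[, "x"], c(0L, 2L))
  expect_identical(back@coords[, "y"], c(0L, 1L))
})

test_that("continuous-mode files and corrupted binaries are rejected", {
  set.seed(5)
  img <- randomSpectrumImage(3, 3)
  base <- file.path(tempdir(), "modes")
  writeImzML(img, base)
  xml <- readLines(paste0(base, ".imzML"))
  cont <- gsub('IMS:1000031" name="processed"', 'IMS:1000030" name="continuous"',
               xml, fixed = TRUE)
  writeLines(cont, paste0(base, ".imzML"))
  expect_error(readImzML(base), "continuous")
  writeImzML(img, base)  # restore, then corrupt the binary payload
  con <- file(paste0(base, ".ibd"), "r+b")
  seek(con, 40, rw = "write")
  writeBin(as.raw(255), con)
  close(con)
  expect_error(readImzML(base), "checksum")
  expect_silent(readImzML(base, checkHash = FALSE))
  expect_error(readImzML(file.path(tempdir(), "no_such_file")), "not found")
})

test_that("writing the same data twice is byte-identical", {
  set.seed(77)
  img <- randomSpectrumImage(4, 4)
  b1 <- file.path(tempdir(), "det1"); b2 <- file.path(tempdir(), "det2")
  writeImzML(img, b1); writeImzML(img, b2)
  expect_identical(unname(tools::md5sum(paste0(b1, ".ibd"))),
                   unname(tools::md5sum(paste0(b2, ".ibd"))))
  expect_identical(readLines(paste0(b1, ".imzML")),
                   readLines(paste0(b2, ".imzML")))
})

test_that("an independent imzML reader agrees with what we wrote", {
  set.seed(42)
  img <- randomSpectrumImage(4, 3)
  base <- file.path(tempdir(), "pycheck")
  writeImzML(img, base)
  script <- sprintf("
from pyimzml.ImzMLParser import ImzMLParser
p = ImzMLParser(r'%s.imzML')
n = 0; tot = 0.0
for i, c in enumerate(p.coordinates):
    mz, ints = p.getspectrum(i)
    n += len(mz); tot += float(sum(ints))
print(len(p.coordinates), n, round(tot, 1))
", base)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2("python", sf, stdout = TRUE, stderr = TRUE)
  vals <- strsplit(tail(out, 1), " ")[[1]]
  expect_identical(as.integer(vals[1]), nPixels(img))
  expect_identical(as.integer(vals[2]), length(img@mz))
  expect_equal(as.numeric(vals[3]), sum(img@intensity), tolerance = 1e-4)
})

test_that("TIC sums every centroid and distinguishes missing pixels", {
  img <- spectrumImage(
    list(list(mz = numeric(0), intensity = numeric(0)),
         list(mz = c(300, 400, 500), intensity = c(2, 3, 5))),
    coords = matrix(c(0L, 0L, 1L, 0L), 2, byrow = TRUE),
    gridShape = c(3L, 1L))
  tic <- ticImage(img)
  expect_identical(imageValues(tic)[1, 1], 0)
  expect_identical(imageValues(tic)[1, 2], 10)
  expect_false(missingPixels(tic)[1, 1])  # empty spectrum is a real zero
  expect_true(missingPixels(tic)[1, 3])   # never recorded
})

test_that("tissue masking recovers a uniform block and rejects blank images", {
  vals <- matrix(0, 10, 12)
  vals[3:8, 4:9] <- 100
  tic <- new("IonImage", values = vals,
             missing = matrix(FALSE, 10, 12), targetMz = NA_real_,
             tolPpm = NA_real_, label = "TIC")
  m <- tissueMask(tic, "fraction", 0.1)
  expect_identical(unname(m), unname(vals > 0))
  blank <- new("IonImage", values = vals * 0, missing = matrix(FALSE, 10, 12),
               targetMz = NA_real_, tolPpm = NA_real_, label = "TIC")
  expect_error(tissueMask(blank), "all-zero")
})

test_that("phantom masks recover the generator's tissue truth", {
  cfg <- tinyConfig()
  img <- generatePhantom(cfg, condition = "healthy", seed = 3)
  truth <- brainRegionMap(gridShape(img))$mask
  tic <- ticImage(img)
  onT <- mean(imageValues(tic)[truth])
  offT <- mean(imageValues(tic)[!truth])
  expect_gt(onT, offT)
  for (method in c("fraction", "otsu")) {
    m <- tissueMask(tic, method)
    jac <- sum(m & truth) / sum(m | truth)
    expect_gte(jac, 0.95)
  }
})
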