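# Synthetic sagittal-brain phantom: multi-replicate two-condition imzML-ready
# datasets with known ground truth (region map, injected fold changes,
# replicate offsets), plus NCE-ramp fragmentation data for PRM work.

.REGIONS <- c("cerebrum", "cerebellum", "brain_stem", "midbrain")

# deterministic sub-seed derivation; keeps every derived seed < 2^31
.childSeed <- function(seed, key) {
  u <- utf8ToInt(key)
  h <- sum(u * seq_along(u) * 1000003) %% 2147483629
  as.integer((seed %% 2147483629) * 48271 %% 2147483629 + h) %% 2147483629L + 1L
}

#' Per-pixel noise model of the phantom
#'
#' @slot lognormalSigma SD of multiplicative log-normal pixel noise
#'   (log scale).
#' @slot ppmJitterSd SD of the mass error applied to every peak, in ppm
#'   (default 0.8, keeping ~3 SD within the +/- 2.5 ppm instrument spec).
#' @slot replicateOffsetSd SD of the per-replicate global multiplicative
#'   offset, in log2 units (default 0.3).
#' @slot detectionFloor Intensity (charges/s) below which a centroid is not
#'   recorded.
#' @slot decoyDensity Expected decoy (chemical background) peaks per 100 Th
#'   per pixel.
#' @slot decoyMeanIntensity Mean intensity of decoy peaks (charges/s).
#' @export
setClass("NoiseModel", representation(
  lognormalSigma = "numeric", ppmJitterSd = "numeric",
  replicateOffsetSd = "numeric", detectionFloor = "numeric",
  decoyDensity = "numeric", decoyMeanIntensity = "numeric"))

setValidity("NoiseModel", function(object) {
  vals <- c(object@lognormalSigma, object@ppmJitterSd, object@replicateOffsetSd,
            object@detectionFloor, object@decoyDensity, object@decoyMeanIntensity)
  if (any(vals < 0)) return("noise parameters must be >= 0")
  TRUE
})

#' @param lognormalSigma,ppmJitterSd,replicateOffsetSd,detectionFloor,decoyDensity,decoyMeanIntensity
#'   See slot documentation.
#' @rdname NoiseModel-class
#' @export
noiseModel <- function(lognormalSigma = 0.4, ppmJitterSd = 0.8,
                       replicateOffsetSd = 0.3, detectionFloor = 10,
                       decoyDensity = 5, decoyMeanIntensity = 25) {
  new("NoiseModel", lognormalSigma = lognormalSigma, ppmJitterSd = ppmJitterSd,
      replicateOffsetSd = replicateOffsetSd, detectionFloor = detectionFloor,
      decoyDensity = decoyDensity, decoyMeanIntensity = decoyMeanIntensity)
}

#' Collision-induced fragmentation model for the PRM precursor
#'
#' Precursor survival decays logistically with normalized collision energy;
#' the fragment pool is split between the galactose-loss fragment (m/z 282)
#' and the galactose-plus-water-loss fragment (m/z 264) by a logistic
#' conversion curve centered at `crossoverNce`, the energy where the two
#' fragments are exactly equal. Fractions of (precursor + both fragments)
#' always sum to 1.
#'
#' @slot survivalMid NCE (%) at which half the precursor survives.
#' @slot survivalSlope Logistic width of the survival decay (% NCE).
#' @slot crossoverNce NCE (%) where the two fragments are equal (default 16).
#' @slot fragSlope Logistic width of the 282 -> 264 conversion (% NCE).
#' @export
setClass("FragmentationModel", representation(
  survivalMid = "numeric", survivalSlope = "numeric",
  crossoverNce = "numeric", fragSlope = "numeric"))

#' @param survivalMid,survivalSlope,crossoverNce,fragSlope See slots.
#' @rdname FragmentationModel-class
#' @export
fragmentationModel <- function(survivalMid = 14, survivalSlope = 5,
                               crossoverNce = 16, fragSlope = 6) {
  new("FragmentationModel", survivalMid = survivalMid,
      survivalSlope = survivalSlope, crossoverNce = crossoverNce,
      fragSlope = fragSlope)
}

#' Expected ion fractions at a collision energy
#'
#' @param fm A [FragmentationModel-class].
#' @param nce NCE values (%).
#' @return data.frame(nce, precursor, frag282, frag264); rows sum to 1.
#' @export
fragmentationFractions <- function(fm, nce) {
  s <- 1 / (1 + exp((nce - fm@survivalMid) / fm@survivalSlope))
  g <- 1 / (1 + exp(-(nce - fm@crossoverNce) / fm@fragSlope))
  data.frame(nce = nce, precursor = s,
             frag282 = (1 - s) * (1 - g), frag264 = (1 - s) * g)
}

#' Construct a lipid panel entry
#'
#' A panel row describes one target species: its molecular formula (or, for
#' species known only by observed m/z, the m/z directly), LIPID MAPS
#' category, adduct split, per-region baseline abundance, per-region
#' disease-condition log2 fold change, an optional extra fold change inside
#' the visual-cortex hotspot, and the doped-solvent suppression.
#'
#' @param name Species label.
#' @param formula Hill formula string, or NA for m/z-only entries.
#' @param category LMSD category code (FA/ST/SP/GL/GP/PK/PR/SL).
#' @param mz Observed m/z for formula-less entries.
#' @param adducts Named numeric of adduct fractions summing to 1 (names from
#'   [builtinAdducts()]); ignored for m/z-only entries.
#' @param baseline Baseline abundance (charges/s): single value or named
#'   per-region vector.
#' @param log2fc Disease-vs-healthy log2 fold change: single value or named
#'   per-region vector.
#' @param hotspotLog2fc Additional log2 fold change inside the hotspot
#'   (diseased condition only).
#' @param solventLog2 log2(doped/standard) detection change.
#' @return One-row data.frame with list columns.
#' @export
panelEntry <- function(name, formula = NA_character_, category = "SP",
                       mz = NA_real_, adducts = c("M+H" = 1),
                       baseline = 100, log2fc = 0, hotspotLog2fc = 0,
                       solventLog2 = -1) {
  expand <- function(v) {
    if (is.null(names(v))) return(stats::setNames(rep(v[1], 4), .REGIONS))
    out <- stats::setNames(numeric(4) * 0, .REGIONS)
    out[names(v)] <- v
    out
  }
  if (!is.na(formula) && abs(sum(adducts) - 1) > 1e-9)
    stop("adduct fractions must sum to 1 for ", name)
  data.frame(name = name, formula = formula, category = category, mz = mz,
             adducts = I(list(adducts)), baseline = I(list(expand(baseline))),
             log2fc = I(list(expand(log2fc))), hotspotLog2fc = hotspotLog2fc,
             solventLog2 = solventLog2)
}

#' Theoretical ion m/z values of a panel entry
#'
#' @param entry One panel row.
#' @param adductsOnly Optional restriction to a subset of adduct names.
#' @return Named numeric of ion m/z (names = adduct names, or "as-is").
#' @export
speciesIonMz <- function(entry, adductsOnly = NULL) {
  if (is.na(entry$formula)) return(c("as-is" = entry$mz))
  fr <- entry$adducts[[1]]
  nm <- names(fr)
  if (!is.null(adductsOnly)) nm <- intersect(nm, adductsOnly)
  if (!length(nm)) stop("no adducts left for ", entry$name)
  stats::setNames(vapply(nm, function(a) adductMz(entry$formula, a), 0), nm)
}

#' Default lipid panel
#'
#' Roughly 24 species covering the named analytes of a demyelinating-disease
#' brain study — psychosine (the disease marker, scarce in healthy tissue
#' and strongly enriched in cerebellum/brain stem plus a visual-cortex
#' hotspot in disease), cholesterol, two GalCer(d18:1) species,
#' SM(d18:1/16:0), five free fatty acids — plus fourteen m/z-only entries
#' spanning the low/central/high mass-range comparison groups. All species
#' carry a uniform -1 log2 doped-solvent suppression.
#'
#' @return Panel data.frame (one row per species).
#' @export
defaultPanel <- function() {
  psyAdducts <- c("M+H" = 0.7, "M+H-H2O" = 0.1, "M+NH4" = 0.1, "M+Na" = 0.1)
  cholAdducts <- c("M+H-H2O" = 0.6, "M+H" = 0.2, "M+NH4" = 0.1, "M+Na" = 0.1)
  rows <- list(
    panelEntry("psychosine", "C24H47NO7", "SP", adducts = psyAdducts,
               baseline = 6,
               log2fc = c(cerebrum = 0, cerebellum = 2.5, brain_stem = 2.5,
                          midbrain = 1.0),
               hotspotLog2fc = 2.5),
    panelEntry("cholesterol", "C27H46O", "ST", adducts = cholAdducts,
               baseline = c(cerebrum = 1800, cerebellum = 2400,
                            brain_stem = 2400, midbrain = 2000)),
    panelEntry("GalCer(d18:1/18:0)", "C42H81NO8", "SP",
               adducts = c("M+H" = 0.6, "M+Na" = 0.4), baseline = 400,
               log2fc = c(cerebrum = 0.5, cerebellum = 1.5, brain_stem = 1.5,
                          midbrain = 0.5)),
    panelEntry("GalCer(d18:1/22:0)", "C46H89NO8", "SP",
               adducts = c("M+H" = 1),  # its sodium adduct sits above 800 Th
               baseline = 300,
               log2fc = c(cerebrum = 0.4, cerebellum = 1.2, brain_stem = 1.2,
                          midbrain = 0.4)),
    panelEntry("SM(d18:1/16:0)", "C39H79N2O6P", "SP",
               adducts = c("M+H" = 0.7, "M+Na" = 0.3), baseline = 500,
               log2fc = 0.8),
    panelEntry("oleic acid", "C18H34O2", "FA",
               adducts = c("M+H" = 0.8, "M+Na" = 0.2), baseline = 300),
    panelEntry("linoleic acid", "C18H32O2", "FA",
               adducts = c("M+H" = 0.8, "M+Na" = 0.2), baseline = 250),
    panelEntry("arachidonic acid", "C20H32O2", "FA",
               adducts = c("M+H" = 0.8, "M+Na" = 0.2), baseline = 200),
    panelEntry("EPA", "C20H30O2", "FA",
               adducts = c("M+H" = 0.8, "M+Na" = 0.2), baseline = 150),
    panelEntry("DHA", "C22H32O2", "FA",
               adducts = c("M+H" = 0.8, "M+Na" = 0.2), baseline = 250))
  generic <- list(
    c("PR01 305.2475", "PR", 305.2475, 300),
    c("FA01 313.2737", "FA", 313.2737, 350),
    c("FA01 315.2530", "FA", 315.2530, 300),
    c("FA07 548.5401", "FA", 548.5401, 400),
    c("SP01 566.5506", "SP", 566.5506, 350),
    c("GP01 758.5694", "GP", 758.5694, 500),
    c("GP01 760.5851", "GP", 760.5851, 450),
    c("SP01 761.5886", "SP", 761.5886, 300),
    c("GP01/GP10 762.6007", "GP", 762.6007, 400),
    c("GP01/GP10 764.5225", "GP", 764.5225, 350),
    c("GP01/GP10 766.5381", "GP", 766.5381, 300),
    c("GP01 768.5514", "GP", 768.5514, 300),
    c("GP01 768.5538", "GP", 768.5538, 250),
    c("GP01 772.5851", "GP", 772.5851, 350))
  rows <- c(rows, lapply(generic, function(g)
    panelEntry(g[1], NA_character_, g[2], mz = as.numeric(g[3]),
               baseline = as.numeric(g[4]))))
  do.call(rbind, rows)
}

#' Quadrant region map on a sagittal-brain silhouette
#'
#' Paints a parametric brain-like silhouette (a large cerebral ellipse plus
#' cerebellar, brain-stem and midbrain lobes) on the pixel grid and
#' partitions it into the four study quadrants, with a small visual-cortex
#' hotspot inside the cerebrum. Regions are disjoint and their union is the
#' tissue mask; only this topology (not anatomical accuracy) matters to the
#' downstream statistics.
#'
#' @param gridShape Integer (n_cols, n_rows).
#' @return list(region = integer matrix (0 = background, levels attribute
#'   names the four regions), hotspot = logical matrix, mask = logical
#'   matrix).
#' @export
brainRegionMap <- function(gridShape) {
  nx <- gridShape[1]; ny <- gridShape[2]
  xg <- matrix(rep(seq_len(nx) - 1, each = ny), nrow = ny)
  yg <- matrix(rep(seq_len(ny) - 1, nx), nrow = ny)
  inEllipse <- function(cx, cy, rx, ry)
    ((xg - cx * nx) / (rx * nx))^2 + ((yg - cy * ny) / (ry * ny))^2 <= 1
  cerebrum  <- inEllipse(0.42, 0.45, 0.36, 0.34)
  cerebellum <- inEllipse(0.80, 0.38, 0.14, 0.17)
  brainStem <- inEllipse(0.78, 0.70, 0.16, 0.14)
  midbrain  <- inEllipse(0.62, 0.60, 0.12, 0.12)
  region <- matrix(0L, ny, nx)
  region[cerebrum] <- 1L
  region[midbrain] <- 4L
  region[brainStem] <- 3L
  region[cerebellum] <- 2L
  attr(region, "levels") <- .REGIONS
  hotspot <- inEllipse(0.52, 0.22, 0.05, 0.075) & region == 1L
  list(region = region, hotspot = hotspot, mask = region > 0L)
}

#' Phantom study configuration
#'
#' The study conditions the phantom emulates: grid geometry, panel,
#' replicate counts (3 healthy vs 4 diseased), scan range, and the
#' cholesterol/psychosine spatial anti-correlation injected in the diseased
#' cerebellum (a shared latent field with opposite signs).
#'
#' @slot gridShape Integer (n_cols, n_rows); default 120 x 80.
#' @slot spatialResolution µm per pixel (default 100).
#' @slot panel Panel data.frame (see [defaultPanel()]).
#' @slot nHealthy,nDiseased Replicates per condition.
#' @slot scanRange Numeric (low, high) Th.
#' @slot anticorrelate Character pair of species names sharing the latent
#'   field with opposite signs (length 0 disables).
#' @slot anticorrelateRegion Region in which the field acts.
#' @slot anticorrelateStrength log2 amplitude of the field.
#' @slot holeFraction Fraction of tissue pixels dropped (section damage).
#' @export
setClass("PhantomConfig", representation(
  gridShape = "integer", spatialResolution = "numeric", panel = "data.frame",
  nHealthy = "integer", nDiseased = "integer", scanRange = "numeric",
  anticorrelate = "character", anticorrelateRegion = "character",
  anticorrelateStrength = "numeric", holeFraction = "numeric"))

#' @param gridShape,spatialResolution,panel,nHealthy,nDiseased,scanRange,anticorrelate,anticorrelateRegion,anticorrelateStrength,holeFraction
#'   See slots.
#' @rdname PhantomConfig-class
#' @export
phantomConfig <- function(gridShape = c(120L, 80L), spatialResolution = 100,
                          panel = defaultPanel(), nHealthy = 3L, nDiseased = 4L,
                          scanRange = c(200, 800),
                          anticorrelate = c("psychosine", "cholesterol"),
                          anticorrelateRegion = "cerebellum",
                          anticorrelateStrength = 0.75, holeFraction = 0) {
  new("PhantomConfig", gridShape = as.integer(gridShape),
      spatialResolution = spatialResolution, panel = panel,
      nHealthy = as.integer(nHealthy), nDiseased = as.integer(nDiseased),
      scanRange = as.numeric(scanRange),
      anticorrelate = anticorrelate, anticorrelateRegion = anticorrelateRegion,
      anticorrelateStrength = anticorrelateStrength, holeFraction = holeFraction)
}

# smooth standardized latent field over the tissue (for anti-correlation)
.latentField <- function(gridShape) {
  z <- matrix(stats::rnorm(prod(gridShape)), gridShape[2], gridShape[1])
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(t(z)), sigma = 3))
  f <- t(sm)
  (f - mean(f)) / stats::sd(f)
}

#' Generate one phantom replicate
#'
#' Per tissue pixel and panel species the expected abundance is
#' `baseline(region) * 2^log2fc(region) [diseased] * 2^offset *
#' lognormal-noise`, split across the species' adducts; every peak's m/z is
#' jittered by the ppm noise, uniform decoy peaks are added over the scan
#' range, and centroids below the detection floor are dropped. Fixing the
#' seed fixes every output value.
#'
#' @param cfg A [PhantomConfig-class].
#' @param noise A [NoiseModel-class].
#' @param condition "healthy" or "diseased".
#' @param replicateId Label stored in the metadata.
#' @param seed Integer seed.
#' @param replicateOffsetLog2 Per-replicate systematic offset (log2); drawn
#'   from the noise model when NULL.
#' @param solvent "standard" or "doped" (applies the panel's per-species
#'   suppression when doped).
#' @return A [SpectrumImage-class].
#' @export
generatePhantom <- function(cfg, noise = noiseModel(),
                            condition = c("healthy", "diseased"),
                            replicateId = "R1", seed = 1,
                            replicateOffsetLog2 = NULL,
                            solvent = c("standard", "doped")) {
  condition <- match.arg(condition)
  solvent <- match.arg(solvent)
  set.seed(seed)
  rm <- brainRegionMap(cfg@gridShape)
  nx <- cfg@gridShape[1]; ny <- cfg@gridShape[2]
  npix <- nx * ny

  if (is.null(replicateOffsetLog2))
    replicateOffsetLog2 <- stats::rnorm(1, 0, noise@replicateOffsetSd)

  latent <- NULL
  if (length(cfg@anticorrelate) == 2 && condition == "diseased")
    latent <- .latentField(cfg@gridShape)

  # pixel order: row-major, x fastest; region per pixel in that order
  regionVec <- as.integer(t(rm$region))
  hotspotVec <- as.logical(t(rm$hotspot))
  tissue <- which(regionVec > 0L)
  nT <- length(tissue)
  antiRegion <- match(cfg@anticorrelateRegion, .REGIONS)

  pixL <- list(); mzL <- list(); intL <- list()
  for (i in seq_len(nrow(cfg@panel))) {
    entry <- cfg@panel[i, ]
    base <- entry$baseline[[1]][regionVec[tissue]]
    if (condition == "diseased") {
      base <- base * 2^(entry$log2fc[[1]][regionVec[tissue]])
      hs <- hotspotVec[tissue]
      if (entry$hotspotLog2fc != 0 && any(hs))
        base[hs] <- base[hs] * 2^entry$hotspotLog2fc
      if (!is.null(latent) && entry$name %in% cfg@anticorrelate) {
        sgn <- if (entry$name == cfg@anticorrelate[1]) 1 else -1
        inReg <- regionVec[tissue] == antiRegion
        lf <- as.vector(t(latent))[tissue][inReg]
        base[inReg] <- base[inReg] *
          2^(sgn * cfg@anticorrelateStrength * lf)
      }
    }
    if (solvent == "doped") base <- base * 2^entry$solventLog2
    amount <- base * 2^replicateOffsetLog2 *
      exp(stats::rnorm(nT, 0, noise@lognormalSigma))
    ions <- speciesIonMz(entry)
    frac <- if (is.na(entry$formula)) 1 else entry$adducts[[1]][names(ions)]
    for (j in seq_along(ions)) {
      intj <- amount * frac[j]
      mzj <- ions[j] * (1 + stats::rnorm(nT) * noise@ppmJitterSd * 1e-6)
      pixL[[length(pixL) + 1L]] <- tissue
      mzL[[length(mzL) + 1L]] <- mzj
      intL[[length(intL) + 1L]] <- intj
    }
  }

  # decoy background everywhere on the grid
  lambda <- noise@decoyDensity * diff(cfg@scanRange) / 100
  nd <- stats::rpois(npix, lambda)
  if (sum(nd) > 0) {
    pixL[[length(pixL) + 1L]] <- rep.int(seq_len(npix), nd)
    mzL[[length(mzL) + 1L]] <- stats::runif(sum(nd), cfg@scanRange[1], cfg@scanRange[2])
    intL[[length(intL) + 1L]] <- stats::rexp(sum(nd), 1 / noise@decoyMeanIntensity)
  }

  pix <- unlist(pixL, use.names = FALSE)
  mz <- unlist(mzL, use.names = FALSE)
  int <- unlist(intL, use.names = FALSE)
  keep <- int >= noise@detectionFloor & mz >= cfg@scanRange[1] &
    mz <= cfg@scanRange[2]
  pix <- pix[keep]; mz <- mz[keep]; int <- int[keep]

  keepPix <- rep(TRUE, npix)
  if (cfg@holeFraction > 0) {
    holes <- sample(tissue, round(cfg@holeFraction * nT))
    keepPix[holes] <- FALSE
    drop <- pix %in% holes
    pix <- pix[!drop]; mz <- mz[!drop]; int <- int[!drop]
  }

  ord <- order(pix, mz)
  pix <- pix[ord]; mz <- mz[ord]; int <- int[ord]
  ties <- which(diff(mz) <= 0 & diff(pix) == 0)
  if (length(ties)) mz[ties + 1L] <- mz[ties] + 1e-9

  # remap pixel ids onto retained pixels and build CSR pointers
  newId <- cumsum(keepPix)
  counts <- tabulate(newId[pix], nbins = sum(keepPix))
  coords <- cbind(x = (which(keepPix) - 1L) %% nx,
                  y = (which(keepPix) - 1L) %/% nx)
  md <- acquisitionMetadata(spatialResolution = cfg@spatialResolution,
                            scanRange = cfg@scanRange, condition = condition,
                            replicateId = replicateId, solvent = solvent)
  new("SpectrumImage", mz = mz, intensity = int,
      pointers = c(1L, 1L + cumsum(counts)), coords = coords,
      gridShape = cfg@gridShape, metadata = md)
}

#' Multi-replicate phantom cohort with ground truth
#'
#' Collection of replicate [SpectrumImage-class] datasets plus the truth
#' record the generator used: region map, injected fold changes and
#' per-replicate offsets.
#'
#' @slot images List of [SpectrumImage-class].
#' @slot info data.frame(replicate_id, condition, seed, offset_log2).
#' @slot truth list(regionMap, hotspot, mask, panel, anticorrelate).
#' @export
setClass("PhantomCohort", representation(images = "list", info = "data.frame",
                                         truth = "list"))

setMethod("show", "PhantomCohort", function(object) {
  cat("PhantomCohort:", nrow(object@info), "replicates (",
      sum(object@info$condition == "healthy"), "healthy /",
      sum(object@info$condition == "diseased"), "diseased )\n")
  print(object@info[, c("replicate_id", "condition", "offset_log2")])
})

#' @describeIn PhantomCohort-class Replicate images.
#' @param x A PhantomCohort.
#' @export
setGeneric("cohortImages", function(x) standardGeneric("cohortImages"))
#' @rdname PhantomCohort-class
#' @export
setMethod("cohortImages", "PhantomCohort", function(x) x@images)

#' @describeIn PhantomCohort-class Replicate-level metadata.
#' @export
setGeneric("cohortInfo", function(x) standardGeneric("cohortInfo"))
#' @rdname PhantomCohort-class
#' @export
setMethod("cohortInfo", "PhantomCohort", function(x) x@info)

#' @describeIn PhantomCohort-class Generator ground truth.
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
#' @rdname PhantomCohort-class
#' @export
setMethod("cohortTruth", "PhantomCohort", function(x) x@truth)

#' Generate a full two-condition cohort
#'
#' Default study design: 3 healthy and 4 diseased technical replicates, each
#' with an independently drawn systematic offset and its own sub-seed
#' derived from the root seed.
#'
#' @param cfg A [PhantomConfig-class].
#' @param noise A [NoiseModel-class].
#' @param seed Root integer seed.
#' @param solvent Passed to [generatePhantom()].
#' @return A [PhantomCohort-class].
#' @export
generateCohort <- function(cfg, noise = noiseModel(), seed = 1,
                           solvent = "standard") {
  conds <- c(rep("healthy", cfg@nHealthy), rep("diseased", cfg@nDiseased))
  ids <- c(paste0("WT", seq_len(cfg@nHealthy)),
           paste0("TW", seq_len(cfg@nDiseased)))
  set.seed(.childSeed(seed, "replicate-offsets"))
  offsets <- stats::rnorm(length(conds), 0, noise@replicateOffsetSd)
  seeds <- vapply(ids, function(id) .childSeed(seed, id), 0L)
  images <- lapply(seq_along(conds), function(i)
    generatePhantom(cfg, noise, conds[i], ids[i], seeds[i],
                    replicateOffsetLog2 = offsets[i], solvent = solvent))
  rm <- brainRegionMap(cfg@gridShape)
  truthFc <- do.call(rbind, lapply(seq_len(nrow(cfg@panel)), function(i)
    data.frame(species = cfg@panel$name[i], region = .REGIONS,
               log2fc = unname(cfg@panel$log2fc[[i]]),
               hotspot_log2fc = cfg@panel$hotspotLog2fc[i])))
  new("PhantomCohort", images = images,
      info = data.frame(replicate_id = ids, condition = conds,
                        seed = seeds, offset_log2 = offsets),
      truth = list(regionMap = rm$region, hotspot = rm$hotspot,
                   mask = rm$mask, log2fc = truthFc,
                   anticorrelate = cfg@anticorrelate))
}

#' Generate an NCE-ramp fragmentation dataset
#'
#' At each collision energy, emits `nScans` replicate spectra of the
#' psychosine precursor (m/z 462.3425) and its two quantitative fragments
#' (282.2791 and 264.2686) with model-expected abundances, multiplicative
#' scan noise and small mass jitter — the delimited (nce, scan, mz,
#' intensity) table a PRM ramp experiment produces.
#'
#' @param fm A [FragmentationModel-class].
#' @param nceGrid NCE values (%), non-empty.
#' @param nScans Scans per NCE.
#' @param seed Integer seed.
#' @param totalAbundance Total ion current per scan (charges/s).
#' @param scanNoiseSigma Log-normal scan-to-scan noise SD (0 = noiseless).
#' @param ppmJitterSd Mass jitter SD in ppm.
#' @return data.frame(nce, scan, ion, mz, intensity).
#' @export
generateBreakdownData <- function(fm, nceGrid = seq(8, 45, by = 1), nScans = 5,
                                  seed = 1, totalAbundance = 1e4,
                                  scanNoiseSigma = 0.1, ppmJitterSd = 0.5) {
  if (!length(nceGrid)) stop("nceGrid must be non-empty")
  set.seed(seed)
  ionMz <- prmIonMz()
  fr <- fragmentationFractions(fm, rep(nceGrid, each = nScans))
  n <- nrow(fr)
  rows <- lapply(names(ionMz), function(ion) {
    expected <- totalAbundance * fr[[ion]]
    data.frame(nce = fr$nce, scan = rep(seq_len(nScans), length(nceGrid)),
               ion = ion,
               mz = ionMz[[ion]] * (1 + stats::rnorm(n) * ppmJitterSd * 1e-6),
               intensity = expected * exp(stats::rnorm(n, 0, scanNoiseSigma)))
  })
  out <- do.call(rbind, rows)
  out[order(out$nce, out$scan, out$mz), ]
}

#' Generate a PRM phantom image at one collision energy
#'
#' Per-pixel MS2 phantom: the psychosine abundance field of the diseased (or
#' healthy) phantom is split into surviving precursor (with its theoretical
#' isotope envelope) and the two fragments at the model fractions for `nce`,
#' so fragment images are deterministic fractions of the precursor image.
#'
#' @param cfg A [PhantomConfig-class] (its psychosine panel entry is used).
#' @param noise A [NoiseModel-class] (decoys are not added: PRM spectra are
#'   precursor-filtered).
#' @param fm A [FragmentationModel-class].
#' @param nce Collision energy (%).
#' @param seed Integer seed.
#' @param condition Condition of the underlying tissue.
#' @param gain Signal gain vs MS1 acquisition (longer PRM accumulation).
#' @param envelopePeaks Isotope peaks emitted for the precursor.
#' @return A [SpectrumImage-class] with scan range 40-500 Th.
#' @export
generatePrmImage <- function(cfg, noise = noiseModel(), fm = fragmentationModel(),
                             nce = 16, seed = 1, condition = "diseased",
                             gain = 4, envelopePeaks = 4) {
  set.seed(seed)
  rm <- brainRegionMap(cfg@gridShape)
  nx <- cfg@gridShape[1]; ny <- cfg@gridShape[2]
  entry <- cfg@panel[cfg@panel$name == "psychosine", ]
  if (!nrow(entry)) stop("panel has no psychosine entry")
  regionVec <- as.integer(t(rm$region))
  hotspotVec <- as.logical(t(rm$hotspot))
  tissue <- which(regionVec > 0L)
  nT <- length(tissue)
  base <- entry$baseline[[1]][regionVec[tissue]]
  if (condition == "diseased") {
    base <- base * 2^(entry$log2fc[[1]][regionVec[tissue]])
    hs <- hotspotVec[tissue]
    base[hs] <- base[hs] * 2^entry$hotspotLog2fc
  }
  A <- gain * base * exp(stats::rnorm(nT, 0, noise@lognormalSigma))
  fr <- fragmentationFractions(fm, nce)
  env <- isotopePattern(entry$formula, envelopePeaks, adduct = "M+H")
  ionMz <- prmIonMz()
  mzL <- list(); intL <- list(); pixL <- list()
  for (k in seq_along(env@mz)) {
    pixL[[k]] <- tissue
    mzL[[k]] <- env@mz[k] * (1 + stats::rnorm(nT) * noise@ppmJitterSd * 1e-6)
    intL[[k]] <- A * fr$precursor * env@abundance[k]
  }
  for (ion in c("frag282", "frag264")) {
    pixL[[length(pixL) + 1L]] <- tissue
    mzL[[length(mzL) + 1L]] <- ionMz[[ion]] *
      (1 + stats::rnorm(nT) * noise@ppmJitterSd * 1e-6)
    intL[[length(intL) + 1L]] <- A * fr[[ion]]
  }
  pix <- unlist(pixL); mz <- unlist(mzL); int <- unlist(intL)
  keep <- int >= noise@detectionFloor
  pix <- pix[keep]; mz <- mz[keep]; int <- int[keep]
  ord <- order(pix, mz)
  pix <- pix[ord]; mz <- mz[ord]; int <- int[ord]
  npix <- nx * ny
  counts <- tabulate(pix, nbins = npix)
  coords <- cbind(x = (seq_len(npix) - 1L) %% nx, y = (seq_len(npix) - 1L) %/% nx)
  md <- acquisitionMetadata(spatialResolution = cfg@spatialResolution,
                            scanRange = c(40, 500), condition = condition,
                            replicateId = "PRM", injectionTime = 15)
  new("SpectrumImage", mz = mz, intensity = int,
      pointers = c(1L, 1L + cumsum(counts)), coords = coords,
      gridShape = cfg@gridShape, metadata = md)
}

#' Theoretical PRM ion m/z values
#'
#' Protonated psychosine and its two neutral-loss fragments (galactose loss;
#' galactose plus water loss), computed from first principles.
#'
#' @return Named numeric: precursor, frag282, frag264.
#' @export
prmIonMz <- function() {
  pre <- adductMz("C24H47NO7", "M+H")
  f282 <- neutralLossMz(pre, "C6H12O6")
  c(precursor = pre, frag282 = f282, frag264 = neutralLossMz(f282, "H2O"))
}
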