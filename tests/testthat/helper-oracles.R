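# Independent brute-force oracles used to validate the package's fast paths.

# linear scan over every peak of every pixel: the definitional ion image
linearScanImage <- function(img, targetMz, tolPpm, reducer = "sum") {
  lo <- targetMz * (1 - tolPpm * 1e-6)
  hi <- targetMz * (1 + tolPpm * 1e-6)
  g <- gridShape(img)
  out <- matrix(0, nrow = g[2], ncol = g[1])
  co <- pixelCoords(img)
  for (i in seq_len(nPixels(img))) {
    s <- spectrumAt(img, co[i, 1], co[i, 2])
    keep <- s$mz >= lo & s$mz < hi
    v <- if (!any(keep)) 0 else if (reducer == "sum") sum(s$intensity[keep])
         else max(s$intensity[keep])
    out[co[i, 2] + 1, co[i, 1] + 1] <- v
  }
  out
}

# Benjamini-Hochberg by the step-up definition: find the largest k with
# p_(k) <= k/m * alpha; adjusted p is the standard monotone transform
bhStepUpOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# exhaustive isotopologue enumeration: every composition of each element's
# atoms over its isotopes, multinomial-weighted, aggregated by nucleon offset
enumeratePatternOracle <- function(formulaText, nPeaks) {
  tab <- list(
    H  = list(mass = c(1.00782503207, 2.01410177812), p = c(0.999885, 0.000115)),
    C  = list(mass = c(12.0, 13.00335483507), p = c(0.9893, 0.0107)),
    N  = list(mass = c(14.00307400443, 15.00010889888), p = c(0.99636, 0.00364)),
    O  = list(mass = c(15.99491461957, 16.99913175650, 17.99915961286),
              p = c(0.99757, 0.00038, 0.00205)),
    Na = list(mass = 22.9897692820, p = 1),
    P  = list(mass = 30.97376199842, p = 1),
    S  = list(mass = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
              p = c(0.9499, 0.0075, 0.0425, 0.0001)),
    Cl = list(mass = c(34.968852682, 36.965902602), p = c(0.7576, 0.2424)))
  toks <- regmatches(formulaText,
                     gregexpr("[A-Z][a-z]?[0-9]*", formulaText))[[1]]
  sym <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(ifelse(grepl("[0-9]", toks), sub("^[A-Za-z]+", "", toks), 1))

  compositions <- function(n, k) {
    if (k == 1) return(matrix(n, 1, 1))
    out <- NULL
    for (i in 0:n) out <- rbind(out, cbind(i, compositions(n - i, k - 1)))
    out
  }
  # per element: data.frame(offset, mass, prob) over all compositions
  perElement <- lapply(seq_along(sym), function(j) {
    e <- tab[[sym[j]]]
    k <- length(e$mass)
    comp <- compositions(cnt[j], k)
    off0 <- round(e$mass) - round(min(e$mass))
    data.frame(
      offset = as.integer(comp %*% off0),
      mass = as.numeric(comp %*% e$mass),
      prob = apply(comp, 1, function(x) stats::dmultinom(x, prob = e$p)))
  })
  cur <- data.frame(offset = 0L, mass = 0, prob = 1)
  for (d in perElement) {
    cur <- data.frame(
      offset = as.integer(outer(cur$offset, d$offset, "+")),
      mass = as.numeric(outer(cur$mass, d$mass, "+")),
      prob = as.numeric(outer(cur$prob, d$prob)))
    cur <- cur[cur$prob > 1e-15, ]
    agg <- stats::aggregate(cbind(prob, wmass = prob * mass) ~ offset, cur, sum)
    cur <- data.frame(offset = agg$offset, mass = agg$wmass / agg$prob,
                      prob = agg$prob)
  }
  cur <- cur[order(cur$offset), ]
  keep <- seq_len(min(nPeaks, nrow(cur)))
  list(mz = cur$mass[keep], abundance = cur$prob[keep] / sum(cur$prob[keep]))
}

# small random centroided image for I/O and extraction tests
randomSpectrumImage <- function(nx = 5, ny = 4, maxPeaks = 12,
                                scanRange = c(200, 800)) {
  coords <- as.matrix(expand.grid(x = 0:(nx - 1), y = 0:(ny - 1)))
  spectra <- lapply(seq_len(nrow(coords)), function(i) {
    n <- sample.int(maxPeaks, 1)
    list(mz = sort(runif(n, scanRange[1], scanRange[2])),
         intensity = runif(n, 1, 1e4))
  })
  spectrumImage(spectra, coords, c(nx, ny),
                acquisitionMetadata(scanRange = scanRange))
}

# tiny phantom configuration for fast tests
tinyConfig <- function(...) {
  phantomConfig(gridShape = c(40L, 28L), ...)
}

# panel with every regional/hotspot effect removed (null configuration)
nullPanel <- function() {
  p <- defaultPanel()
  p$log2fc <- I(lapply(p$log2fc, function(x) x * 0))
  p$hotspotLog2fc <- 0
  p
}
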