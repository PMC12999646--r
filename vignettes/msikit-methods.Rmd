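---
title: "Methods: targeted MSI lipidomics with a validated brain phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted MSI lipidomics with a validated brain phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msikit)
```

# What the package computes

msikit analyzes centroided mass spectrometry imaging (MSI) data for
targeted lipidomics: confirming a marker lipid's identity, mapping where it
sits in a tissue section, and testing how its abundance differs between
conditions. The motivating system is a demyelinating-disease mouse model in
which psychosine (galactosylsphingosine, C24H47NO7) accumulates in the
posterior brain while healthy tissue carries it near the detection limit.

Because raw instrument data are large and not required to validate the
statistics, the package ships a first-class synthetic data generator — a
"brain phantom" — whose every injected parameter is recorded as ground
truth. All higher-level claims in the test suite are parameter-recovery
claims against that truth.

# Exact-mass layer

Monoisotopic masses are sums of most-abundant-isotope masses (IUPAC-CIAAW
2021 values, ≥ 6 decimals). An adduct ion's m/z is

$$ m/z = \frac{m(M) + m(\text{added}) - m(\text{removed}) - n_e m_e}{|z|} $$

with the electron mass $m_e$ subtracted once per removed electron. The
electron term matters at the precision this field reports: the cholesterol
ammonium adduct rounds to 404.3887 only with the correction; ignoring it
misses by ≈ 0.5 mTh. Values are kept at full precision internally and
rounded (half-even, R's `round`) to 4 decimals only for display.

Isotope envelopes are computed by convolving per-element single-atom
isotope distributions (binary exponentiation over atom counts), aggregating
by integer nucleon offset — fine structure is merged, matching what an
Orbitrap displays at lipid masses and resolution — then truncating to the
requested number of peaks and renormalizing. The test suite checks this
fast path against an independent exhaustive isotopologue enumeration
(multinomial expansion per element) to 1e-6 in relative abundance.

# imzML model and windowing conventions

Only processed-mode (per-pixel centroid) imzML is supported: the pipeline
operates on centroided Orbitrap-style data and the phantom emits centroids.
m/z arrays are stored as 64-bit floats, intensities as 32-bit floats (the
common dialect), with MD5-checksummed external binaries. Pixels missing
inside the grid are legal — degraded sections have holes — and contribute
nothing: they are excluded from masks and ROI means rather than treated as
zeros.

Ion images use half-open ppm windows
$[t(1-\delta\cdot10^{-6}),\ t(1+\delta\cdot10^{-6}))$ so adjacent windows
partition the axis and no centroid can be counted twice. The default
half-width is 5 ppm — the instrument's ±2.5 ppm mass accuracy doubled for
window safety; the phantom's mass jitter (SD 0.8 ppm) keeps ≈ 3 SD inside
±2.5 ppm. Multiple in-window centroids are summed (abundances are charges
per second; summing matches that semantics), with a max reducer available.
The extraction is tested for exact equality against a per-pixel linear-scan
oracle. How any particular commercial viewer windows or interpolates is not
modelled; the half-open convention is this package's own, stated one.

# The phantom: what it emulates

The generator paints a parametric sagittal-brain silhouette (a cerebral
ellipse plus cerebellar, brain-stem and midbrain lobes) on a default
120 × 80 grid at 100 µm. Only the region topology matters to the
statistics — four disjoint quadrants covering the tissue, plus a small
visual-cortex hotspot inside the cerebrum — so no atlas is used. The fourth
quadrant needs a name; "midbrain" is a configurable label and no test
depends on it.

Per pixel and species the expected abundance is

```
baseline(region) × 2^log2fc(region)   [diseased only]
                × 2^hotspot_log2fc    [diseased, hotspot pixels]
                × 2^offset(replicate) × LogNormal(0, σ)
```

split across the species' adducts at fixed fractions, each peak's m/z
jittered with ppm noise, uniform decoy peaks added over the scan range, and
centroids below a detection floor dropped (left-censoring, as on a real
instrument). Defaults, chosen once as realistic study conditions:

| parameter | default | rationale |
|---|---|---|
| grid, resolution | 120 × 80 px, 100 µm | sagittal section at the study's finest raster |
| replicates | 3 healthy / 4 diseased | the study's technical-replicate design |
| pixel noise σ | 0.4 (log scale) | moderate per-pixel biological + sampling spread |
| mass jitter SD | 0.8 ppm | 3 SD within the ±2.5 ppm accuracy spec |
| replicate offset SD | 0.3 log₂ | reproduces the observed replicate-wide systematic offsets |
| detection floor | 10 charges/s | censors scarce analytes as acquisition does |
| decoys | 5 peaks / 100 Th / px, mean 25 | chemical background without swamping tissue TIC |
| psychosine | baseline 6; log₂fc 2.5 (cerebellum, brain stem), 1.0 (midbrain), hotspot +2.5 | scarce in healthy tissue, strongly enriched posteriorly, hotspot-only in cerebrum |
| scan range | 200–800 Th | the range used for the marker-lipid evaluation |

The default panel (24 species) covers the named analytes — psychosine,
cholesterol, two GalCer(d18:1) species, SM(d18:1/16:0), five free fatty
acids — plus fourteen m/z-only ions spanning the low (300–325), central
(545–570) and upper (745–770 Th) mass-range comparison groups. All species
carry a −1 log₂ doped-solvent suppression, emulating the observed
preference for the standard electrospray composition. A shared latent
Gaussian field (smoothed, SD 1, amplitude 0.75 log₂) multiplies psychosine
up and cholesterol down in the diseased cerebellum, injecting the spatial
anti-correlation a colocalization plot should detect.

What the phantom does **not** emulate: per-pixel isotope envelopes for MS1
species (only the PRM precursor gets an envelope), fragment chemistry
beyond the two quantitative fragments, realistic anatomy, registration
errors between serial sections, and matrix/ionization spatial gradients.
Passing tests therefore demonstrate that the *statistical machinery*
recovers known inputs under realistic noise — not that any biological
conclusion about real tissue is reproduced.

All randomness flows from one root seed through named, deterministic
sub-seeds (per replicate, per module), so a fixed seed fixes every output
byte, including the serialized imzML (its UUID is derived from the payload
hash).

# ROI statistics and the three z-score schemes

Ten square ROIs per quadrant (40 total) are placed by uniform random
packing — candidates are all top-left corners whose full square lies inside
the region, and candidates overlapping a placed square are pruned — which
is deterministic per seed and fails loudly, naming the region, if the
region cannot hold the requested count. ROI side defaults to 3 px: small
enough that 10 disjoint squares fit the smallest default-quadrant, large
enough to average pixel noise. ROI abundance is the **mean** over ROI
pixels (sum would scale with ROI size); the log transform is log₁₀ with the
detection floor added, so fully censored ROIs stay finite. The log base and
mean-vs-sum choices are conventions this package documents rather than
facts inherited from any instrument software.

z-scores standardize log abundances within a stratum, always within
condition:

- **replicate**: (replicate, species) — each analyte against that
  replicate's own average;
- **global**: (condition, species) — against the analyte's average across
  all replicates of the condition;
- **region-global**: (condition, region, species).

Their disagreement is diagnostic: a replicate-wide systematic offset moves
that replicate's global and region-global means in *all* regions while its
replicate-normalized means stay at zero — the signature separating an
acquisition-scale artifact from regional biology. The acceptance suite
injects a 0.5-log₂ offset and verifies exactly this pattern, and verifies
that a homogeneous phantom (no regional effects; and, for the global
schemes, no replicate offsets — which those schemes exist to expose) keeps
every region × replicate boxplot mean within ±0.5 SD.

# Differential analysis

Whole-tissue abundance per replicate is the mean summed-adduct abundance
over the TIC-derived tissue mask (no TIC normalization by default — raw
abundances are reported; masking uses the fractional threshold, with Otsu
available). The volcano test is Welch's t on log₂ replicate abundances —
the multiple-testing correction (Benjamini–Hochberg) is standard for this
analysis, and Welch's unequal-variance test is the conservative default for
3-vs-4 designs; a Mann–Whitney alternative is wired in. log₂fc is the
difference of mean log abundances (symmetric in group order). Significance
needs |log₂fc| > 0.6 *and* adjusted p < 0.05; effect sizes are additionally
banded (0.6–1.5 small/moderate, 1.5–2 intermediate, > 2 large) as labels
only.

Zero abundances cannot enter a log: whole-tissue zeros are excluded with a
warning (and a species whose group drops below 2 positive replicates is
reported as NA rather than aborting the panel); **regional** volcano
instead adds the detection floor to the replicate-level regional means
before the log, because regional means of a scarce, censored analyte are
legitimately zero and the floor offset — the same convention as the ROI log
transform — keeps those comparisons defined and conservative.

With 3 vs 4 replicates and a 0.3-log₂ replicate offset SD, a genuinely
large effect routinely fails to reach adjusted p < 0.05; the package's own
worked example shows psychosine at log₂fc ≈ 4.8, class "large", adjusted
p ≈ 0.44. Power, not effect, is the limiting factor at this design size,
which is why the validation suite checks effect-size recovery rather than
significance counts. Under a null panel the per-cohort
significant fractions are strongly correlated across species (the shared
replicate offsets move the whole panel together), so the type-I check uses
a cohort-clustered Monte-Carlo standard error.

The solvent comparison is purely descriptive, as the underlying analysis
is: per-species log₂(doped/standard) on-tissue means, box statistics per
LMSD category, summed abundances and fold ratios for the three mass-range
ion groups (14 member ions), and the fraction of those ions preferring the
standard solvent. Species undetected under either solvent are flagged and
excluded from ratios.

# PRM layer

The fragmentation model is a logistic precursor-survival curve
(midpoint 14 % NCE, slope 5) with the fragment pool split between the
galactose-loss ion (m/z 282.2791) and the galactose-plus-water-loss ion
(m/z 264.2686) by a logistic conversion centered at the crossover energy
(default 16 %, slope 6). The model encodes the observed qualitative
behavior: both fragments form directly at low energy; above ≈ 35 % NCE the
larger fragment declines as the smaller one rises; at the crossover the two
are exactly equal.

"Optimal NCE" is formalized as the grid point minimizing the fragment
fraction difference subject to a minimum total fragment yield (default
0.25), ties resolving to the lower energy — the published description
("optimized", fragments "approximately equivalent") does not pin down a
criterion, so this one is documented and configurable (an obvious
alternative is maximum summed fragment yield). Recovery of the configured
crossover within one 1 %-grid step is part of the acceptance suite across
crossovers 10–30 %.

PRM phantom images build the fragments as fixed fractions of the per-pixel
precursor field, so precursor/fragment colocalization approaches r = 1 by
construction — which is the point: the test verifies the extraction and
scoring chain, not fragment chemistry. Isotope-envelope matching assigns
observed peaks to theoretical entries by nearest m/z within tolerance and
reports the cosine similarity of the abundance vectors.

# Numerical and scale choices

Display rounding is half-even at 4 decimals; nothing is rounded internally.
Stratum SDs use the sample (n−1) estimator; a zero-SD stratum yields z = 0
with a warning, a stratum of fewer than two rows is an error naming the
stratum. Tied m/z within a pixel after jitter (probability ~0) are
separated by 1e-9 Th to preserve strict ordering. Boxplot statistics are
R's Tukey `boxplot.stats`.

Test problem sizes are the package's own choices balancing Monte-Carlo
precision against suite runtime: 50 seeded cohorts at the full 120 × 80
default for effect recovery, 200 null cohorts at 40 × 28 for type-I
control (grid size affects within-replicate precision, not test
calibration, which is driven by replicate offsets), 25 seeds per crossover
energy for NCE recovery, and a 180 × 120 grid (> 10 000 tissue pixels) for
the law-of-large-numbers generator check.

# Known limitations

- Positive ion mode, charge 1, and the five built-in adducts only; no
  negative-mode or multiply charged species.
- No profile-mode data, no 3-D volumes, no section-to-section registration.
- Metabolite annotation (database lookup, FDR-scored putative IDs) is out
  of scope: the panel file supplies names, formulas and categories as
  inputs.
- The phantom's noise is pixel-independent given the latent field;
  real MSI noise has spatial structure (laser energy drift, sprayer
  gradients) the generator does not model.
- Welch's t on 3-vs-4 log abundances is approximate for heavily censored
  species; the NA-reporting path and the floor convention keep those cases
  visible rather than silently dropped.
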