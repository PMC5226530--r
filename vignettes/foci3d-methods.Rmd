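---
title: "Quantifying bright and dim DNA-damage foci in 3D: methods and design"
author: "foci3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bright and dim DNA-damage foci in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foci3d)
```

# The problem

Topoisomerase inhibitors (camptothecin, etoposide, mitoxantrone) induce
DNA damage whose nuclear markers — γH2AX and 53BP1 immunofluorescent foci
— can be related spatially to sites of ongoing DNA replication (EdU
labeling). γH2AX foci fall into two phenomenologically distinct classes:
large, intense ("bright") foci, the conventional double-strand-break
markers, and small, faint ("dim") foci of less certain origin. Deciding
whether each class sits at replication sites, at 53BP1-marked repair
centres, or at random requires per-focus measurement in 3D and spatial
statistics computed inside the irregular nuclear volume.

`foci3d` implements that analysis as a reusable pipeline: focus detection
by orthogonal-section maxima searches, iterative-flooding segmentation,
volume/intensity measurement and bright/dim classification,
nearest-neighbour analysis, and normalized Ripley K (L-function)
statistics with a Monte-Carlo CSR reference — together with a synthetic
image generator that provides ground truth for every stage, since the
original microscope images are not publicly available.

# Image model and the synthetic generator

A nucleus is a calibrated three-channel 8-bit stack (53BP1, γH2AX, EdU)
with voxels of (0.13, 0.06, 0.06) µm (z, y, x), matching confocal
acquisition at 60 nm pixel size and 130 nm z-steps. The generator
(`simulateNucleus`) emulates:

* **Geometry.** An ellipsoidal nuclear mask; the default
  48×256×256-voxel grid holds a flattened ellipsoid of semi-axes
  (2.5, 6, 6) µm, about 377 µm³. This is a deliberately scaled-down
  nucleus (a real adherent-cell nucleus is ~1500 µm³) chosen so a full
  multi-nucleus study runs on a desk machine; all downstream code
  accepts arbitrary masks.
* **Foci.** Diffraction-limited anisotropic Gaussian spots. Two γH2AX
  populations are drawn from lognormal amplitude/width distributions —
  bright: amplitude ~LN(log 120, 0.3), lateral σ ~LN(log 0.17 µm, 0.15);
  dim: amplitude ~LN(log 30, 0.25), lateral σ ~LN(log 0.09 µm, 0.15);
  axial σ is 1.8× lateral (confocal axial elongation). These defaults
  were calibrated once so that the *rendered* populations straddle the
  classifier thresholds (0.25 µm³, 35 a.u.): the bright/dim boundary is
  then a property the classifier must recover, not an artifact of the
  draw. Default counts (15 bright, 25 dim, 15 53BP1, 80 EdU per nucleus)
  preserve the per-volume densities of a drug-treated mid-S-phase
  nucleus at the reduced geometry, so the fraction of foci closer than
  one optical resolution element to a neighbour — the fraction no
  detector can separate — matches full-size data.
* **Spatial structure.** Positions are continuous (µm) and only
  rasterized at render time. Three models: CSR (uniform over mask voxel
  centres with sub-voxel jitter — the null of the L-function), a
  Thomas-like cluster process, and colocalization (a configurable
  fraction of points placed at reference-channel positions plus an
  isotropic Gaussian offset, default σ = 0.15 µm). Treatment presets
  encode the study design: CPT-like nuclei colocalize bright γH2AX with
  EdU (f = 0.8) and 53BP1 with bright γH2AX (f = 0.9); MTX-like nuclei
  are fully CSR; dim foci are CSR in every preset.
* **Optics and noise.** Spots are convolved with a Gaussian PSF
  (σ = 0.08 µm lateral, 0.18 µm axial). Because a Gaussian convolved
  with a Gaussian is again Gaussian, the clean image is rendered
  analytically at quadrature-combined widths — exact, with amplitude
  defined as the post-PSF peak height. Noise follows the standard
  confocal approximation `Poisson(gain·signal)/gain` with gain 4
  photons per code value, Gaussian read noise (σ = 1 a.u.) and a
  constant offset (4 a.u.), giving a background spread of ≈1.4 a.u. A
  diffuse nucleoplasmic level (10 a.u.) is added inside the mask:
  without it the nucleus would be invisible to image-based
  segmentation, which matches no real immunofluorescence image.
  Quantization saturates at 255.

What the generator does **not** emulate: realistic (Gibson–Lanni) PSFs,
chromatic aberration, photobleaching, chromatin-texture-dependent focus
placement, substage-specific replication patterns, or irregular nuclear
shapes. Tests passing on this generator therefore demonstrate
correctness of the measurement and statistics pipeline under a
controlled image model — not robustness to every property of real
microscope data.

# Detection

Peaks are local intensity maxima in 3D, located as the conjunction of 2D
prominence-based maxima searches in orthogonal section families. The 2D
search (`findMaxima2D`) uses noise-tolerance semantics: a pixel is
reported iff the 8-connected flood region above (peak − prominence)
contains no brighter pixel, does not span the whole section, and the
pixel is the representative of its merged basin. An exhaustive
brute-force oracle for this rule backs the implementation in the tests.

`findMaxima3D` intersects the xy-section maxima with maxima of
orthogonal families within a 1-voxel match radius, ascends each survivor
to its 3D local maximum, deduplicates, and merges peaks closer than 2
voxels laterally and 1 axially (brighter peak wins). Three refinements,
each forced by a measured failure mode on synthetic data, deserve
explanation:

* **Hill-climb to the 3D maximum.** The counted objects are 3D maxima;
  without the ascent, section maxima on the flanks of a bright spot
  detect it repeatedly along the optical axis, and a strict in-place
  "is a 3D maximum" test instead discards genuine candidates that land
  one voxel off the summit.
* **Pre-smoothing of the detection grid** (`smoothForDetection`,
  pipeline default σ = (0.5, 1, 1) voxels). On raw 8-bit data, shot
  noise splits the top of a small focus into twin maxima several voxels
  apart, duplicating dim foci and fabricating short-range dim–dim
  clustering. Deconvolution — used on the real data, but out of scope
  here — has the same noise-suppressing effect. Coordinates come from
  the smoothed grid; flooding, volumes and intensities never do.
* **Either-family conjunction** (pipeline default). Requiring
  confirmation specifically from xz sections loses dim foci that sit in
  the axially elongated flank of a brighter neighbour: in that family
  the dim focus is not a maximum at all. Accepting confirmation from
  *either* the xz or the yz family treats the two lateral axes
  symmetrically and removes this failure mode; `findMaxima3D` itself
  defaults to the plain xy∧xz conjunction.

The prominence is derived per nucleus (`autoProminence`) as k = 5 times
a robust background spread — the interpolated one-sigma lower-tail
quantile distance from the in-mask median, computed
histogram-interpolated for integer data. This estimator equals the
scaled MAD of sub-median voxels for Gaussian backgrounds but does not
collapse on quantized Poisson backgrounds, where the discrete MAD snaps
to whole code values. It replaces the original workflow's per-nucleus
manual tuning with a reproducible rule driven by the same quantities
(background level and spread). A constant background falls back to
prominence 1 with a warning.

# Segmentation and measurement

Each peak seeds a region grown by level-descending flooding
(`floodRegions`): thresholds descend from the brightest peak towards a
floor in steps of one code value; at each level, unassigned voxels at or
above the level join the unique region they touch (26-connectivity);
voxels touching two or more regions are frozen as boundary voxels,
assigned to the nearer seed peak (ties to the brighter), and never
conduct further growth. Growth within a level proceeds in synchronous
sweeps, so the result is independent of voxel enumeration order — which
is also what makes the C++ implementation exactly comparable to the
plain R oracle used in the tests.

The flooding floor defaults to the in-mask median + 3 background SDs.
The choice is a percolation argument: with a floor only 1 SD above the
median, ~15% of background voxels are floodable, above the ~10% site
percolation threshold of 26-connectivity, and regions leak into
system-spanning noise clusters; at 3 SDs the floodable background
fraction (~0.5%) is far below threshold and regions remain compact.

Per focus, volume is the voxel count times the physical voxel volume
(4.68×10⁻⁴ µm³ at default calibration), and mean intensity is computed
**from the raw grid** over unsaturated region voxels only. Saturated
voxels (at the top code value) are flagged, never altered, and excluded
from both numerator and denominator; an all-saturated region reports the
top code value with a flag. Registration shifts between channels can be
corrected by integer-voxel cross-correlation — integer deliberately,
since sub-voxel interpolation would resample the raw intensities that
feed the classifier.

# Classification

A γH2AX focus is **bright** iff volume ≥ 0.25 µm³ *or* raw mean
intensity ≥ 35 a.u. (8-bit scale); otherwise **dim**. The boundaries are
inclusive by default (the source wording is ambiguous between "at
least" and "over"); `inclusive = FALSE` selects strict inequalities, and
a dedicated test pins the boundary behaviour. Bright + dim equals the
γH2AX total by construction; 53BP1 and EdU foci stay unclassified.

Because flooding cannot place a dim focus inside a region already
claimed by a bright focus, dim counts are underestimated where bright
foci are dense. Following the original analysis this is surfaced, not
corrected: `runNucleus` reports the fraction of nuclear volume occupied
by bright regions as an occupancy diagnostic.

# Spatial statistics

All statistics use physical (µm) coordinates, so the 0.13 vs 0.06 µm
anisotropy is handled once, upstream. Nearest-neighbour distances
(`nnDistances`) are exact 3D Euclidean minima (self-pairs excluded in
auto mode); histograms use right-open 0.1 µm bins to 2 µm with an
overflow bin, and medians come from unbinned distances. Distances are
pooled across nuclei before histogramming by default (per-nucleus
averaging is available), since the aggregation order in the original
presentation is ambiguous.

The association measure is a normalized Ripley statistic: for each
distance r, the observed number of ordered source–target pairs within r
is divided by its expectation under complete spatial randomness and 1
is subtracted, so L = 0 is random association and L = 1 means twice the
random pair count. This ratio-minus-one form (not Besag's square-root
variance stabilization) is fixed by the definition that L = 1
corresponds to a 100% excess over random.

The CSR expectation (`csrReference`) is estimated by Monte Carlo inside
the actual nuclear mask — both point sets redrawn uniformly with the
observed counts, 100 draws by default (500 in the null-calibration
tests). Sampling inside the mask bakes boundary (edge) effects into the
reference by construction, so no analytic edge correction is needed and
the mask may be arbitrarily irregular. The reference assumes spatial
uniformity of available positions; like the original analysis, the
statistic therefore slightly overestimates association at short
distances when the underlying chromatin density is non-uniform — the
inhomogeneous correction is deliberately out of scope.

Per distance, the across-nuclei mean L is tested against 0 with a
one-sample two-sided t-test (`testLvsZero`), flagged at α = 0.05, with
no multiplicity correction across distances by default (matching the
original analysis; Benjamini–Hochberg is a switch). Two degenerate
regimes are handled explicitly: identical L across nuclei (zero
variance) reports p below the machine floor when the mean differs from
0; distances where fewer than two nuclei contribute are undefined. Note
the discreteness caveat: at distances where the CSR expectation is ≪ 1
pair, every nucleus can observe zero pairs, making L ≡ −1 with zero
variance — a "significant" negative flag that reflects quantization,
not avoidance; interpretation should focus on distances with adequate
expected pair counts. Group comparisons of per-nucleus counts use
Welch's two-sample t-test, with "significance" read as p < 0.05.

# Pipeline and aggregation

`runNucleus` chains the stages for one nucleus: saturation flagging,
optional registration correction, mask (supplied or Otsu-derived from
the summed smoothed channels, largest 26-connected component), detection
per channel, flooding, measurement, classification, then
nearest-neighbour sets (bright/dim γH2AX → EdU and → 53BP1) and seven
L-curves (auto: bright, dim, 53BP1; cross: bright/dim × EdU/53BP1).
Channels without usable foci are skipped with a log entry; a failing
nucleus is marked in the manifest and never aborts the study
(`analyzeStudy`). `aggregateStudy` averages counts per treatment ×
substage stratum (SD, n), pools NN distances, summarizes L-curves via
`testLvsZero`, compares strata with `compareCounts`, and flags strata
below 18 nuclei as under-powered. Every stochastic step is seeded from
the run configuration; reruns are bit-identical.

S-phase substage is consumed as metadata: the expert visual
classification of replication patterns is not automated here.

# Numerical choices and problem sizes

* Distance grid 0.1–2 µm in 0.1 µm steps for L-curves and histograms
  (the biology of interest is below ~1 µm).
* Flood step 1 code value (8-bit data); 26-connectivity everywhere.
* Monte-Carlo CSR: 100 draws per reference in the pipeline, 500 where
  the null itself is under test; all seeded.
* Test-suite problem sizes are chosen for a desk machine: unit tests use
  32×96×96 nuclei (~51 µm³); the end-to-end and null-calibration tests
  use the full default geometry with 20 nuclei per condition, and the
  type-I-error study runs 1000 replicates of 8 small nuclei at a single
  distance.
* Degenerate inputs: empty masks, empty peak sets, flat images,
  all-saturated regions, single-point auto statistics and zero-target
  channels all have defined, tested behaviour (error or flagged skip,
  never silent zeros).

# Known limitations

Detection recall saturates around 0.95 for γH2AX at default conditions:
the residual misses are foci within one resolution element of a
brighter neighbour, which no maxima-based detector separates — the
analogue of the dim-count underestimation the occupancy metric tracks.
The Monte-Carlo reference cost scales with n_sims × n²; for much larger
point sets an analytic edge-corrected reference would be preferable.
The generator's PSF and noise are idealized; conclusions about
robustness to real optics require real (deconvolved) data, which the
pipeline accepts but cannot validate here.
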