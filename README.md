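# foci3d

Quantitative 3D analysis of DNA-damage and replication foci in confocal
nuclei.

Cells treated with topoisomerase inhibitors (camptothecin, etoposide,
mitoxantrone) accumulate nuclear γH2AX foci of two kinds: large, intense
**bright** foci — the classical double-strand-break markers, co-localized
with 53BP1 — and small, faint **dim** foci whose origin and spatial
organisation differ. `foci3d` measures both classes in calibrated
three-channel 3D stacks (53BP1, γH2AX, EdU replication labeling) and
quantifies their spatial relationships inside the nuclear volume, for
cell-biology labs asking where damage sits relative to replication and
repair.

## What it computes

For each nucleus (multi-channel 8-bit TIFF with explicit voxel
calibration, default 0.13 × 0.06 × 0.06 µm):

1. **Detection** — focus peaks as local intensity maxima in 3D, found as
   the conjunction of ImageJ-style prominence ("noise tolerance") maxima
   searches in orthogonal 2D section families; the prominence is derived
   per nucleus as 5× a robust background spread.
2. **Segmentation** — per-focus regions by iterative flooding:
   thresholds descend from each peak, voxels join the unique touching
   region, contested voxels freeze at the boundary of the nearer peak.
   Volume = voxel count × voxel volume; mean intensity always from the
   **raw** image, excluding saturated voxels.
3. **Classification** — bright iff volume ≥ 0.25 µm³ **or** raw mean
   intensity ≥ 35 a.u. (8-bit); else dim.
4. **Nearest neighbours** — distances from each γH2AX focus (by class)
   to the nearest replication (EdU) or 53BP1 focus; pooled histograms
   with medians.
5. **Normalized Ripley L-functions** — for source/target point sets and
   distance r, `L(r) = observed pairs ≤ r / CSR-expected pairs ≤ r − 1`,
   so L = 0 is random association and L = 1 a 100% excess. The CSR
   expectation is Monte-Carlo, resampled uniformly *inside the actual
   nuclear mask*, which handles edge effects and irregular masks by
   construction. Per distance, the across-nuclei mean L is t-tested
   against 0 (α = 0.05).

A synthetic-data module generates full studies with known ground truth —
ellipsoidal nuclei, two focus populations straddling the classifier
thresholds, configurable cross-channel colocalization, Gaussian PSF,
Poisson + read noise — so every stage is testable end to end. See the
methods vignette (`vignettes/foci3d-methods.Rmd`) for the model and all
parameter choices.

## Worked example

Simulate one camptothecin-like nucleus (bright γH2AX colocalized with
EdU and 53BP1, dim γH2AX spatially random) and analyze it:

```r
library(foci3d)
sim <- simulateNucleus(id = "demo", treatment = "CPT",
                       substage = "S-IV", seed = 11)
res <- runNucleus(sim$record, runConfig(nSims = 100, seed = 12))

res$counts[, c("channel", "class", "count")]
#>     channel        class count
#> 1 gammaH2AX       bright    14
#> 2 gammaH2AX          dim    23
#> 3     53BP1 unclassified    15
#> 4       EdU unclassified    77

res$nn$bright_to_EdU$median   # 0.258 (um)
res$nn$dim_to_EdU$median      # 0.857 (um)
round(lValues(res$lcurves$bright_x_53BP1)[c(2, 3, 5)], 2)
#> 79.00 49.00 34.14   # L at r = 0.2, 0.3, 0.5 um
```

The generator placed 15 bright and 25 dim foci; the pipeline recovers
14 and 23. Bright foci sit a median 0.26 µm from the nearest
replication site — inside one focus diameter, i.e. at replication
sites — while the random dim foci sit 0.86 µm away. The bright × 53BP1
L-values of 30–80 at short range mean tens of times more close pairs
than chance; for CSR channels L stays near 0. `simulateStudy` /
`analyzeStudy` / `aggregateStudy` (or `runStudy`) scale this to
multi-nucleus, multi-treatment designs with per-stratum means, pooled
histograms, significance-flagged mean L-curves and under-powered-stratum
warnings. A command-line wrapper for the simulate/analyze/aggregate
steps is in `inst/scripts/foci3d-pipeline.R`.

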