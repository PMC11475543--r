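# exmloc

Nanoscale receptor localization analysis for expansion-microscopy images of
brain microcapillaries.

## The problem

Receptor-mediated transcytosis across the blood–brain barrier requires cargo
receptors (transferrin receptor, sortilin, basigin, ...) to reach the
*abluminal* (brain-facing) membrane of brain endothelial cells. A capillary
wall is only a few hundred nanometers thick, well below the confocal
diffraction limit, so conventional imaging cannot tell an abluminal receptor
from an intracellular one. Expansion microscopy (ExM) solves this physically:
the specimen is embedded in a swellable gel and expanded ~5× in all three
dimensions, so a standard confocal microscope resolves nanoscale positions —
at the price of an E³ = 125-fold signal dilution that leaves images at very
low signal-to-noise ratio.

`exmloc` implements the downstream quantification pipeline for such data:

1. **Simulation** (`simulate_capillary`) — seeded, ground-truthed synthetic
   3D stacks of 5×-expanded immunostained microcapillaries: a tubular
   endothelial wall coated by a thin abluminal collagen IV shell, nuclei
   arrangements that distinguish capillary types 1–3, receptor spots placed
   at controlled distances from the shell, E³ signal dilution, anisotropic
   PSF blur, and Poisson + Gaussian noise.
2. **Segmentation** (`train_segmenter`, `predict_masks`) — iteratively
   trained supervised pixel classification (two signal classes plus
   background, 12 annotation rounds by default) replacing the commercial
   deep-learning spot segmenter, plus classical baselines
   (`blob_fallback`) and connected-component spot extraction
   (`extract_spots`).
3. **Distance mapping** (`nearest_distances`) — for every receptor spot, the
   nearest distance to the collagen IV reference on anisotropic physical
   coordinates (108 × 108 × 310 nm voxels), divided by the expansion factor
   to give biological nanometers; an exhaustive oracle
   (`brute_force_nearest`) ships alongside.
4. **Statistics** (`bin_distances`, `capillary_fractions`,
   `two_way_anova_tukey`) — distances binned into abluminal (0–100 nm),
   intracellular (100–200, 200–1000 nm) and residual (1–3 µm) classes,
   per-capillary fractions (the capillary is the replication unit), and a
   two-way ANOVA (receptor × bin, type-II SS) with Tukey-adjusted receptor
   comparisons within bins. Capillary typing from nuclei signatures
   (`classify_capillary_type`) and nuclei-uniformity QC
   (`nuclei_uniformity_qc`) complete the stage.

## Worked example

```r
library(exmloc)

res <- run_localization_experiment(
  group_mixtures = list(
    TfR_like     = c(abluminal = 0.08, intracellular_proximal = 0.22,
                     intracellular_distal = 0.70),
    basigin_like = c(abluminal = 0.32, intracellular_proximal = 0.28,
                     intracellular_distal = 0.40)),
  n_capillaries = 4, n_train_stacks = 3, rounds = 12,
  volume_shape = c(192, 192, 48),
  geometry_params = list(lumen_radius = 700, wall_thickness = 300),
  mean_spots = 150, seed = 11)

tapply(res$profiles$frac_abluminal, res$profiles$receptor, mean)
#> basigin_like     TfR_like
#>    0.3422332    0.1077846

res$stats$anova_table
#>           term          F            p stars
#> 1     receptor   1.771638 1.956865e-01    ns
#> 2          bin 216.126158 1.694906e-17  ****
#> 3 receptor:bin  49.424146 2.010479e-10  ****

subset(res$stats$tukey, bin == "abluminal")
#>         bin                contrast estimate       SE        p_adj stars
#> 1 abluminal basigin_like - TfR_like       35 4.038229 7.429034e-09  ****
```

Two simulated receptor populations with true abluminal fractions 0.08 and
0.32 are pushed through the full pipeline (training on truth-annotated
stacks, segmentation, distance mapping, binning). The recovered group-mean
abluminal fractions (0.11 and 0.34 here) track the truth, and the Tukey
comparison in the 0–100 nm bin declares the basigin-like group significantly
more abluminal — the contrast the method is built to detect. The `receptor`
main effect is expectedly flat (both groups carry similar total spot
counts); the localization signal lives in the receptor × bin interaction and
the within-bin contrasts.

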