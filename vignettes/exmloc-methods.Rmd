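---
title: "Methods: simulating and quantifying receptor localization in expanded capillaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying receptor localization in expanded capillaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(exmloc)
```

## Scope and model

`exmloc` quantifies where endothelial cargo receptors sit relative to the
abluminal surface of brain microcapillaries in 5×-expanded, immunostained
specimens. The abluminal surface is marked by collagen IV, a basement
membrane protein coating only the brain-facing side of the endothelial tube;
the luminal (blood-facing) side carries none. The measurement chain is:
segment the receptor and collagen channels of a 3D confocal stack into
discrete objects, compute for each receptor spot the nearest distance to the
collagen reference on physical (gel-space) coordinates, divide by the linear
expansion factor E to return to the biological scale, and classify each
distance into localization bins: abluminal [0, 100) nm, intracellular
[100, 200) and [200, 1000) nm, residual [1000, 3000] nm. Per-capillary bin
counts feed a two-way ANOVA (receptor × bin) with Tukey-adjusted receptor
comparisons within bins; the capillary, not the spot, is the replication
unit.

Because no real image data ships with the package, a synthetic-capillary
generator is a first-class module: every stage is validated against
simulated stacks whose ground truth (spot positions, true surface distances,
true bins, structure masks) is known exactly.

## The synthetic capillary generator

**Geometry.** The capillary is a straight (optionally gently sinusoidally
bent) cylinder: a lumen of radius `lumen_radius`, an endothelial wall of
thickness `wall_thickness`, and a continuous collagen shell of thickness
`collagen_shell_thickness` (default 100 nm, biological scale) on the
abluminal face. Real capillaries are irregular, but the distance statistics
this pipeline measures depend only on spot placement relative to the shell,
so a parametric tube is the right testable idealization. Nuclei are rendered
as filled ellipsoids in type-specific arrangements: type 1 (microcapillary)
a discontinuous axial line with at most a configured few peripheral nuclei;
type 2 additionally several peripheral nuclei; type 3 additionally elongated
nuclei oriented perpendicular to the vessel axis, as mural cells on
pre-capillary vessels. A `nuclei_uniform = FALSE` mode inflates the
nuclei-size coefficient of variation (default jitter CV 0.08, non-uniform
0.45) to exercise the expansion-uniformity QC.

**Spot placement.** Each receptor spot draws a distance bin from a mixture
and a distance d uniformly inside that bin; the spot sits radially at
`lumen_radius + wall_thickness - d` from the axis, at uniform azimuth and
axial position. For d up to the wall thickness this is inside the
endothelial wall; larger d places the spot in the lumen volume, which is how
the generator realizes the 0.2–1 µm (and, geometry permitting, 1–3 µm)
distances observed in real data — an extended cell body is not modeled, only
the distance-to-shell that the pipeline measures. Bins that reach deeper
than `lumen_radius + wall_thickness` are geometrically infeasible and raise
an error rather than silently truncating the mixture.

**Rendering.** Biological coordinates are mapped to gel space by
multiplying by E, rasterized onto the acquisition grid (defaults 108 × 108 ×
310 nm voxels; receptor spots deposit their photon mass trilinearly), blurred
with an anisotropic Gaussian PSF (default σ = 110, 110, 300 nm gel), offset
by a background rate, and converted to counts by a Poisson draw plus
Gaussian read noise. Per-voxel expected signal scales as
`photons_per_marker / E^3`: the volumetric dilution that makes 5× expansion
a 125-fold signal loss. The default photon/noise preset
(`photons_per_marker = 20000`, background 5, read noise 2) was tuned once so
the receptor channel's SNR — mean spot peak minus mean background, over the
background SD — lands mid-way in the 2–5 band that characterizes expanded
specimens, then frozen; a test pins the band.

**What the simulator does not emulate.** Uniform isotropic expansion only:
no local distortion fields, no gelation chemistry, no pericyte or
smooth-muscle collagen double layers, no autofluorescent debris. Passing
tests therefore demonstrate correctness of the measurement chain under the
stated imaging physics, not robustness to every artifact of real gels;
the nuclei-uniformity QC is the pipeline's (and the bench protocol's) guard
against non-uniform expansion.

## Trainable pixel segmentation

The low SNR defeats plain thresholding (the package ships Otsu and
Laplacian-of-Gaussian baselines in `blob_fallback`; a benchmark test records
their recall against the trained segmenter). The segmenter is a per-channel
binary logistic classifier — signal vs background — over handcrafted
multiscale features: raw intensity plus Gaussian-smoothed intensity,
gradient magnitude and Laplacian at scales of 150, 300 and 600 nm (gel),
all computed with physical anisotropic voxel sizes. A linear classifier over
these features keeps training desk-scale, deterministic and
order-invariant (annotations are canonically sorted before each fit), which
a neural backend would not; the pipeline's contribution is the measurement
chain, not the classifier family.

Training runs in `rounds = 12` cycles of an active-learning loop that
mirrors iterative hand-annotation: each round the oracle contributes
`n_per_class = 200` voxels per class per training stack, drawn from round 2
on preferentially where the current model disagrees with the oracle. In
tests the oracle derives from simulation truth: voxels whose noiseless
structure intensity exceeds 65% of a per-channel reference (the median spot
peak, or the median shell/nucleus plateau) are confident signal; below 35%
is confident background; the fringe in between is never annotated. The
symmetric placement around the half-maximum matters: a classifier separating
these two classes puts its decision boundary near the blurred structure's
half-max crossing, which for a Gaussian-blurred edge coincides with the true
structure boundary. This keeps segmented shells from inflating and biasing
distances — the same half-max edge criterion microscopists use for sizing.

Prediction takes the per-voxel argmax, with exact ties going to background
(conservative in low SNR). Spots are 26-connected components of the mask;
components under `min_voxels = 4` are discarded but counted (mask mass is
conserved in the report). Neither the connectivity nor the minimum spot size
of the commercial tool is documented anywhere, so both are explicit
configuration here.

## Distance mapping

Distances are computed in gel-space nanometers on anisotropic physical
coordinates — voxel indices are converted to voxel-center positions (index +
0.5 times the pitch) before any geometry; there is no isotropic resampling
and hence no interpolation artifact at the 310 nm axial pitch. The result is
divided by E for the biological-scale distance that the bins are defined on.

Two metric modes exist because the reference structure is ambiguous in
principle: `centroid_to_centroid` (receptor centroid to nearest collagen
spot centroid, kd-tree accelerated) mirrors a spot-to-spot pipeline;
`centroid_to_surface` (default; receptor centroid to nearest collagen mask
voxel center, computed exactly in C++) treats the collagen shell as the
extended membrane it is, which is the physically right reading of an
"abluminal = within 100 nm" statement. Ties break to the smallest collagen
identifier in both modes, and `brute_force_nearest` provides the exhaustive
oracle; a test requires bit-identical agreement, ties included, across 100
seeded instances.

The resolution bound to keep in mind: one voxel diagonal is
√(108² + 108² + 310²) ≈ 346 nm gel, i.e. ≈ 69 nm biological after
de-expansion. Noiseless end-to-end recovery is tested to within this bound;
it is also why 0–100 nm is the finest bin the acquisition can support.

## Statistics

Distances bin with half-open intervals [a, b), the last bin closed — a
distance of exactly 100 nm is intracellular; the boundary convention is
fixed here because determinism requires one. Distances beyond the last edge
go to an overflow category that is reported, never dropped. Per-capillary
fractions divide by the binned total.

The group comparison is a fixed-effects two-way ANOVA on per-capillary
per-bin values with type-II sums of squares (via `car::Anova`), followed by
Tukey-adjusted pairwise receptor contrasts within each bin (via `emmeans`).
Type-II is the appropriate choice for the unbalanced per-receptor capillary
counts (10 vs 14 vs 14 in the motivating design). The default response is
the per-capillary **count** per bin, with fractions available: fractions sum
to one within each capillary, which makes the receptor main effect
degenerate by construction, whereas counts keep all three terms meaningful —
the receptor main effect then tests total-abundance differences and its
type-I error calibrates correctly (verified at 0.05 ± 0.02 over 500 null
replicates on tabulated counts). The localization question itself lives in
the receptor × bin interaction and the within-bin Tukey contrasts. No
mixed-effects modeling of spots within capillaries is attempted: the
capillary-level ANOVA matches the motivating analysis, and the per-capillary
aggregation already absorbs spot-level correlation.

Capillary typing formalizes the visual nuclei-signature rules: the capillary
axis is the principal direction of the collagen mask; a detected nucleus is
*perpendicular* when its long axis (from component second moments) is more
than 60° off the capillary axis with elongation ≥ 1.4, *peripheral* when its
radial offset exceeds half the shell's median radial distance, else
*axial*. Any perpendicular nucleus ⇒ type 3; at most 2 peripheral ⇒ type 1;
otherwise type 2. The thresholds are documented heuristics, configurable,
and reach ≥ 90% accuracy over 50 simulated capillaries spanning the types.
The QC computes the CV of nuclei equivalent diameters and rejects
capillaries above `cv_threshold = 0.25`, the automated analog of discarding
non-uniformly expanded capillaries by eye.

## Numerical and design choices

- All randomness flows from one master seed through named substreams
  (geometry, placement, noise, annotation, ...), so stages are individually
  reproducible and reordering one does not perturb another. Identical
  configuration and seed reproduce stacks, truth tables and result files
  bit-identically.
- Gaussian blur uses a separable truncated kernel (radius 3σ,
  edge-replicating padding): constant volumes stay constant, interior
  impulses conserve mass.
- Logistic fits standardize features and suppress perfect-separation
  warnings (expected on noiseless fixtures); fits are deterministic given
  the sorted annotation set.
- Degenerate inputs are first-class: empty receptor sets yield empty
  distance tables, an empty collagen reference is an error, designs with
  empty cells are rejected with the offending cell named, zero
  between-group variance reports `ns` rather than NaN stars.
- Problem sizes: the validation experiments use 192 × 192 × 48 voxel stacks
  with a reduced tube (lumen 700 nm, wall 300 nm, shell 100 nm, biological)
  so that the full tube plus PSF margin fits the volume; 10 capillaries per
  group with a Poisson mean of 150 spots; 5 training stacks and 12 rounds.
  These are the package's chosen study conditions for desk-scale validation;
  the geometry is a scaled-down microcapillary, which leaves distance
  statistics unchanged because they depend only on shell-relative placement.
  The 1–3 µm residual bin cannot be realized inside this reduced tube, so
  imaging simulations place no residual mass and residual-bin behaviour is
  validated on tabulated-count simulations instead.

## Known limitations

- Uniform scalar E only; local anisotropic distortion is visible to the QC
  but not modeled or corrected.
- The segmented shell boundary sits near the half-maximum, not exactly at
  the membrane; residual boundary bias of a few tens of nanometers
  (sub-voxel) propagates into bin fractions near the 100 nm edge. The
  parameter-recovery test bounds the net effect at ±0.05 absolute on the
  abluminal fraction under the frozen noise preset.
- Whether the motivating commercial pipeline measured centroid-to-centroid
  or centroid-to-surface, in expanded or de-expanded units, is not
  documented; both modes are implemented and the expansion correction is
  explicit, rather than guessing one.
- `read_stack`/`write_stack` use plain multi-page TIFF with a JSON metadata
  sidecar; OME-XML metadata is not written, and external OME-TIFFs are
  ingested by supplying channel names and voxel sizes explicitly.
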