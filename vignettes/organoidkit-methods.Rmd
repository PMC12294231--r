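---
title: "Quantifying organoid phenotype, motility and matrix remodeling: methods"
author: "organoidkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying organoid phenotype, motility and matrix remodeling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidkit)
```

# Scope and data model

`organoidkit` quantifies 3D cultures of tumor organoids grown in
collagen/Matrigel hydrogels: the shape phenotype of mature organoids
(cystic, solid, invasive), the motility and protrusive activity of early
organoid seeds, the subcellular localization of EMT markers, the collagen
lattice around organoids, live/dead drug response, and the scalar assay
formulas used alongside (2^-ddCt, Z-score matrices, TGI, SRC/GC,
Tan-delta).

All image data live in two S4 containers. A `VoxelImage` is a 3D voxel
array ordered `(z, y, x)` (the first index varies fastest along z) with
per-axis physical spacing in micrometres; multi-channel stacks add a named
channel dimension. A `LabelImage` is its integer-labeled counterpart
(0 = background). Every physical quantity in the package is carried in
micrometres and hours; nothing depends on a global pixel-size setting. The
`(z, y, x)` order and half-open voxel indexing are package conventions —
microscopy formats do not standardize them — and the TIFF I/O writes a JSON
sidecar with spacing and channel names because baseline TIFF has no
three-axis spacing tag.

Because the assays this package models are measured on microscope data that
cannot ship with code, every stage has a phantom generator with analytic
ground truth (`simulateOrganoid()`, `simulateFiberField()`,
`simulateTracks()`, `simulateMarkerStack()`, `simulateLiveDeadField()`,
`simulateDoseResponse()`). The test suite and the acceptance script run the
full pipeline against those phantoms.

# 3D morphometry

`computeDescriptors()` reports, per label:

* **volume** — voxel count times voxel volume; **equivalent diameter** from
  the volume of the equivalent ball.
* **surface area** — Crofton formula with 13 sampling directions (3 axes,
  6 face diagonals, 4 body diagonals) and the standard direction weights;
  boundary crossings are counted with the image border treated as
  background. The estimator assumes near-isotropic voxels and uses the
  geometric-mean spacing; strongly anisotropic grids should be resampled
  first.
* **sphericity** — `pi^(1/3) * (6V)^(2/3) / A`, clipped at 1.
* **circularity** — `4 pi A / P^2` on the axial (z) maximum projection,
  with a 4-direction Crofton perimeter. The axial projection is the view
  the microscope sees; a 3D "circularity" has no standard definition.
* **convexity** — `V / V(hull)` where the hull volume comes from an
  incremental 3D convex hull over the boundary-voxel centers. On digital
  shapes the voxel body can slightly exceed the center-point hull, so the
  ratio is clipped at 1.
* **geodesic elongation** — geodesic diameter over the diameter of the
  largest inscribed ball. The geodesic diameter uses a two-sweep Dijkstra
  on the 5x5x5 visible-displacement graph (chamfer error about 1–2 %,
  versus about 8 % for the plain 26-neighborhood); long moves are rejected
  when both half-way voxels fall outside the mask, so paths cannot tunnel
  through background. The inscribed radius is the maximum of the Euclidean
  distance transform plus a quarter-voxel compensation for sampling the
  continuous EDT maximum at voxel centers; without it the descriptor
  fluctuates by several percent with grid alignment.
* **lumen radius** — a lumen is a background connected component
  (6-connectivity for background, 26 for foreground) with no path to the
  image border, assigned to the unique label that surrounds it; the radius
  is the largest ball inscribed in that cavity. Bodies without an enclosed
  cavity report 0.

Labels touching the image border are flagged (`border_touching`) because
their descriptors may be truncated.

Voxelization limits worth knowing: descriptors of bodies only a few voxels
across are intrinsically noisy (a half-voxel surface displacement is a
several-percent effect); the invariance tests therefore use bodies with a
smallest semi-axis of at least ~15 voxels, where dimensionless descriptors
are stable to about 2 % across a two-fold spacing change and about 5 %
under rotation.

# Phenotype classification

The classifier follows the usual morphometry-SVM recipe: Z-score
standardization (fitted on training data only), an RBF-kernel SVM with
`C = 1`, and feature selection by Cohen's kappa. Three choices are fixed
here because they are commonly left implicit:

* **Kernel width.** `gamma = 1 / (n_features * mean feature variance)`
  computed after standardization — the variance-scaled heuristic most SVM
  front-ends default to. With standardized features this is essentially
  `1 / n_features`.
* **Kappa-based feature ranking.** Each feature is scored alone: a
  1D nearest-class-mean classifier is evaluated by Cohen's kappa under the
  same seeded, stratified folds used for model validation
  (`rankFeatures()`). Constant features score 0; ties break
  lexicographically so rankings are reproducible.
* **Cross-validation.** `crossValidate()` uses seeded stratified folds
  (within each class, shuffled samples are dealt round-robin), refits the
  standardization inside every training fold, and reports overall and
  per-fold accuracy plus kappa.

Two model configurations mirror the two culture conditions: a three-class
Cyst/Solid/Invasive model, and a binary Solid/Invasive model for
TGF-beta-conditioned cultures where cystic forms are absent
(`classLevels` in `trainPhenotypeClassifier()`).

`embedDescriptors()` runs t-SNE (1000 iterations, perplexity 50, Euclidean
metric) on standardized features; whether to standardize before embedding
is an open choice in practice, and standardizing keeps the embedding
consistent with what the SVM sees. Perplexity must be below n/3.

On the default phantom panel (100 organoids per class, rendered at 2 um
spacing, cyst radii 24–40 um, solid/invasive radii 14–26 um with 4–9
conical spikes of 10–18 um) the three classes are linearly separable in the
five headline descriptors, 10-fold CV accuracy is above 0.95, and permuted
labels fall to chance. Passing those checks demonstrates that the
descriptor-classifier chain is self-consistent at realistic geometry — not
that real segmentations (with debris, touching organoids, anisotropic PSF
blur) would classify at the same accuracy.

# Motility and protrusions

`trackStats()` computes per track the mean speed
`v = (1/N) * sum_i ||p_i - p_(i-1)|| / (t_i - t_(i-1))` over the N
displacement segments, and the directness index (start-to-end Euclidean
distance over accumulated path length, 1 = straight migration). Whether
the first frame "counts" is a genuine ambiguity in the usual notation; N is
taken as the number of displacement segments, which makes the estimator
exact on constant-step tracks. Gaps in a track are treated as single longer
steps between consecutive recorded points, matching the formula literally.
TrackMate-dialect XML import (`readTrackMate()`) maps spots to physical
`(t, x, y, z)`.

`extractProtrusions()` implements the classic opening/XOR scheme: maximum
intensity projection, Laplacian-of-Gaussian blob response (default sigma
2 px), Otsu threshold and hole filling — or a user-supplied binary mask —
then binary opening with a disc whose radius must exceed the protrusion
half-width; mask XOR body is the protrusion mask, components under
`minSize` pixels are discarded, and each protrusion's length is its
geodesic diameter. The machine-learning segmenter used interactively on
real data is deliberately replaced by this deterministic classical
segmenter plus the mask bypass, since trained pixel classifiers are not
reproducible from a text description. Opening is idempotent, so re-running
on the returned body yields zero protrusions.

# EMT marker localization

Channels are percentile-normalized: `(I - P1) / (P99 - P1)`, clipped below
at 0 but not above 1 so junctions brighter than P99 keep their contrast.
The junction ROI is the deterministic surrogate of a hand-drawn line: the
3D segment between two nucleus centroids dilated to a 2 um band, minus the
nucleus interiors. Junctional intensity is the mean of ROI voxels at or
above Otsu's threshold computed *within the ROI* (not globally — the ROI is
the stated scope of the threshold). The CDH1 ratio divides by the mean
cytoplasmic intensity, the CTNNB1 ratio by the mean nuclear intensity; the
nuclear AND is taken over the line-band ROI (configurable), which is the
stricter of the two possible readings.

One cross-channel subtlety: within-channel ratios are unaffected by
per-channel normalization (the scale cancels), but the log CDH1/VIM call
compares two different channels, so `scoreMarkerStack()` normalizes CDH1
and VIM with percentiles of their *pooled* intensities. Normalizing each
channel by its own P99 would drive every channel's bright structures to ~1
and erase the level difference the call is built on. The call is epithelial
for log10 ratio > 0, mesenchymal for < 0, and flagged indeterminate at
exactly 0.

The marker phantom places two cells whose nuclei abut the shared junction
band, so the centroid-to-centroid band minus nuclei is the junction zone
itself; junction contrast and VIM level are then recovered exactly in the
noise-free limit. Real stacks add PSF blur, depth attenuation and
off-target staining that the phantom does not model; recovery there
depends on segmentation quality.

# Collagen lattice and remodeling

`segmentFibers()` does per-slice Gaussian background subtraction (sigma
20 px) followed by a global Otsu threshold. `fiberMetrics()` reports fiber
thickness (twice the mean EDT on the distance-ridge voxels, minus one
voxel for the center-to-center bias), density (voxel percentage) and pore
diameter (twice the mean pore-space EDT at its regional maxima) — the EDT
conventions that make a drawn rod of radius r read ~2r and a spherical
pore of radius r read ~2r.

`doughnutROI()` builds the peri-organoid band — all voxels within 7 um
(the default band width, configurable) outside the organoid boundary — and
an equal-thickness control band starting at `controlOffset` (default three
band widths; at least two are enforced so the control cannot sit inside
the remodeling halo). `compaction()` is the fiber density in the band over
the density in the control; the density-based definition (rather than
summed intensity) is fixed here because it is scale-free and robust to
illumination, and the intensity variant would be redundant after Otsu
segmentation anyway.

`fiberAnisotropy()` estimates per-pixel orientation from the 2D structure
tensor of the axial maximum projection (Sobel gradients at sigma 1,
tensor smoothing at sigma 4), restricted to fiber pixels inside the ROI,
and reports the length of the coherence-weighted mean resultant vector of
the doubled orientation angles — the anisotropy index alpha in [0, 1],
invariant to 180-degree fiber flips and image rotation. Analysis is 2D on
projections, matching how such data are presented; a true-3D orientation
mode is out of scope.

Two sizing choices are statistical, not aesthetic. The isotropic noise
floor of a resultant-length estimator is ~0.886/sqrt(m) with m effective
independent orientation patches; with tensor smoothing at sigma 4 a patch
spans roughly (4 sigma)^2 pixels, so the default fiber field
(4 x 1024 x 1024 voxels at 1 um, 0.75 um fiber radius, 10 um segments,
10 % density) provides a few thousand patches and an isotropic alpha of
~0.01–0.02 — comfortably inside the < 0.05 regime expected of an isotropic
lattice, with aligned fields reading > 0.95. Second, a 7 um band around a
30 um organoid contains a limited number of independent fiber segments, so
single-field compaction estimates carry ~3 % sampling noise; compaction
checks therefore average a few seeds. Alpha rises monotonically with the
generator's von Mises concentration but sits above the raw resultant of
the sampling distribution (coherence weighting and tensor averaging act as
a consensus filter); the index is a comparative measure, not an estimator
of kappa.

# Viability and dose response

`segmentLiveDead()` thresholds the two channels at fixed intensities and
counts connected components. The default liveness rule is live-channel
AND NOT dead-channel: the dead stain marks compromised nuclei, so a doubly
stained object counts as dead. A literal mask-intersection rule (doubly
stained = live) is available as `strictPaper = TRUE` for compatibility
with pipelines defined that way. `relativeViability()` is the live-count
ratio of treated to control; counts (not volumes) are the default unit
because seeding density, not organoid size, is what the assay controls.

`fitIG50()` fits the four-parameter logistic
`v = bottom + (top - bottom) / (1 + (dose/ig50)^hill)` on a log10 dose
axis with Levenberg–Marquardt least squares. The model choice itself is a
package decision (the assay literature overwhelmingly uses 4PL), and the
initialization is deterministic from the data: plateaus from the
extreme-dose means with dose 0 anchoring the top, IG50 from the geometric
mean of the doses bracketing half-maximum, hill 1. Responses with no
transition are rejected; non-monotone data fit but flag a high residual.
On the seven-point dose grid (0, 0.001, 0.1, 1, 10, 100, 1000 uM) the fit
inverts the generator to better than 1 % noise-free, and recovers IG50
with a median error under 15 % at 5 % multiplicative noise.

# Scalar formulas

`foldChangeDDCT()` computes `2^-[(Ct_gene - Ct_hk)_organoid -
(Ct_gene - Ct_hk)_reference]`. `zscoreMatrix()` standardizes gene rows
with the *population* standard deviation — the printed formula
`Z = (x - mean)/sd` names no Bessel correction, and heat-map Z-scores
conventionally use n — with `ddof = 1` available; rows and columns are
ordered by average-linkage hierarchical clustering on Euclidean distance
(a fixed, documented choice, since plotting libraries leave it to the
caller). `tgi()` is `(Vf - Vi)/Vi` with growth/regression flags;
`tanDelta()` is G''/G'; `metabolicCapacity()` is maximal minus basal;
`normalizedTumorVolume()` divides by the inoculated organoid mass.
Inferential statistics (ANOVA/MANOVA families) are intentionally not
re-implemented; the functions return tidy values any stats package can
consume.

# Pipeline orchestration

`runPipeline()` executes a YAML-configurable stage list (phantom panel,
feature ranking, CV, embedding, abundance, remodeling, dose-response) in
order, with one derived seed per stage, writing every stage output as CSV
plus a JSON manifest carrying the package version, seed, a parameter hash
and per-output md5 checksums; identical configs reproduce identical
checksums. `validatePipelineConfig()` checks the schema (unknown keys and
stages are errors, an infeasible perplexity is a warning) without touching
data. `demoConfig()` is a self-contained demonstration profile. A thin
command-line wrapper over these functions ships in
`inst/scripts/organoid-pipeline.R`; the exported functions are the
interface.

# Problem sizes and determinism

The shipped tests run phantom panels of 300 organoids at 2 um spacing,
fiber fields of 4 x 1024 x 1024 voxels, 1000-track motility sets, and
100-replicate dose-response recoveries — sizes chosen so the full suite
completes in a few minutes on one core while keeping every statistical
margin (chance levels, noise floors, recovery tolerances) a multiple of
its sampling error. All generators and estimators are seed-deterministic;
SVM training, t-SNE and fold assignment take explicit seeds, and identical
seeds give bit-identical outputs.

# Known limitations

* Descriptors on bodies a few voxels across are dominated by voxelization
  noise; render finer or flag small labels.
* Surface area assumes near-isotropic voxels; circularity is a projection
  measure and will differ from slice-based 2D analysis on elongated
  z-structures.
* The anisotropy index is comparative; it is not an unbiased estimator of
  the underlying orientation concentration.
* Phantoms model geometry and compartment contrast, not optics: no PSF,
  no depth attenuation, no spectral bleed-through. Passing the phantom
  suite validates the measurement chain, not microscope-specific
  segmentation quality.
* Segmentation of real nuclei/cytoplasm (deep-learning or interactive
  tools) is out of scope; label images are inputs.
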