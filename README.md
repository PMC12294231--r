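# organoidkit

Quantitative image analysis of 3D tumor organoids grown in engineered
collagen/Matrigel hydrogels — for imaging groups who culture pancreatic (or
other carcinoma) organoids in hydrogels and need the downstream numbers:
which shape phenotype each organoid has, how fast early organoid seeds
migrate and how many protrusions they extend, where EMT markers sit inside
the cells, how much the organoid remodels the collagen lattice around
itself, and how viability responds to drug dose.

## What it computes

**3D morphometry and phenotype classification.** Per-organoid descriptors
from label images: volume, Crofton surface area, sphericity
π^⅓(6V)^⅔ / A, circularity 4πA/P² on the axial projection, convexity
V / V(convex hull), geodesic elongation (geodesic diameter over inscribed
ball diameter) and lumen radius (largest ball inscribed in an enclosed
cavity). On top of those: Cohen's-kappa feature ranking, an RBF-kernel SVM
(C = 1, variance-scaled γ) with Z-score standardization refit inside each
of 10 stratified CV folds, t-SNE embedding (perplexity 50, 1000
iterations) and per-condition phenotype abundance tables.

**Motility.** Mean speed v = (1/N) Σᵢ ‖pᵢ − pᵢ₋₁‖/(tᵢ − tᵢ₋₁) and the
directness index (Euclidean over accumulated distance) per track, CSV and
TrackMate-XML import; protrusion extraction by LoG segmentation, binary
opening and mask XOR, with geodesic protrusion lengths.

**EMT marker localization.** Percentile-normalized channels, a junction
ROI bridging two nucleus centroids, junction/cytoplasm (CDH1) and
junction/nucleus (CTNNB1) ratios with Otsu thresholds taken inside the
ROI, and the log₁₀ CDH1/VIM phenotype call (epithelial > 0,
mesenchymal < 0).

**Matrix remodeling.** Fiber segmentation, thickness/density/pore-diameter
metrics, the 7 µm peri-organoid doughnut ROI, band-over-control compaction,
and the anisotropy index α (coherence-weighted doubled-angle resultant of
structure-tensor orientations; 0 isotropic, 1 aligned).

**Viability and dose response.** Fixed-threshold live/dead counting
(doubly stained objects count dead by default), relative viability, and a
deterministic 4-parameter-logistic IG50 fit on the
0–0.001–0.1–1–10–100–1000 µM dose grid.

**Scalar assay formulas.** 2^−ΔΔCt fold change, Z-score matrices with
hierarchical heat-map ordering, TGI = (V_f − V_i)/V_i, Tan∆ = G″/G′,
SRC/GC = maximal − basal, inoculum-normalized tumor volume.

Every stage has a synthetic phantom generator with analytic ground truth
(`simulateOrganoid`, `simulateFiberField`, `simulateTracks`,
`simulateMarkerStack`, `simulateLiveDeadField`, `simulateDoseResponse`),
so the whole pipeline is testable without microscope data.

## Worked example

```r
library(organoidkit)

# a cystic phantom: 40 um outer radius, 8 um shell, 1 um voxels
ph <- simulateOrganoid("cyst", outerRadius = 40, shellThickness = 8,
                       spacing = 1, seed = 1)
computeDescriptors(ph$labels)
#>   volume sphericity circularity convexity geodesic_elongation lumen_radius
#> 1 130720      0.378           1     0.493              12.152       31.161

# a 90-phantom panel: kappa feature ranking and 10-fold CV
panel <- simulatePhenotypePanel(nPerClass = 30, spacing = 2, seed = 1)
head(rankFeatures(panel$descriptors, panel$classes, folds = 10, seed = 1), 3)
#>               feature     kappa
#> 1          sphericity 1.0000000
#> 2 geodesic_elongation 0.9666667
#> 3           convexity 0.7333333
crossValidate(panel$descriptors, panel$classes, folds = 10, seed = 1)$accuracy
#> [1] 0.9888889

# EMT scoring of a noise-free epithelial marker stack (junction contrast 3)
ep <- simulateMarkerStack("epithelial", junctionContrast = 3, seed = 1)
scoreMarkerStack(ep$image, ep$nuclei, imgData(ep$compartments) == 1)
#>   cdh1_junction_cyto ctnnb1_junction_nuclei log_cdh1_vim phenotype_call flag
#> 1                  3                      3     1.079181     epithelial   ok

# IG50 from a noisy 7-dose viability table (true IG50 = 0.05 uM)
dr <- simulateDoseResponse(ig50 = 0.05, noiseCv = 0.05, seed = 1)
fitIG50(dr$table$dose_uM, dr$table$viability_pct)
#> DoseResponseFit (4PL)
#>   IG50  : 0.04322 uM
#>   hill  : 0.9326
#>   top   : 101.9 %, bottom: -0.04618 %
#>   RMS residual: 0.0387
```

The lumen radius (31.2 µm) recovers the analytic shell geometry
(40 − 8 = 32 µm) to within a voxel; the kappa ranking puts the
shape-separating descriptors on top; the SVM classifies the three phantom
classes at ~99 % in 10-fold CV; the marker scores return the generator's
junction contrast and a positive log CDH1/VIM (epithelial call); and the
4PL fit recovers the simulated IG50 within the noise of a 5 %-CV assay.

An end-to-end demo (phantoms → descriptors → ranking → CV → embedding →
remodeling → dose response, with a checksummed run manifest):

```r
runPipeline(demoConfig(outdir = "demo-run", seed = 1))
```

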