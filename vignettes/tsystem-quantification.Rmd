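---
title: "Quantifying cardiomyocyte t-system remodeling from 3D confocal stacks"
author: "ttquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiomyocyte t-system remodeling from 3D confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttquant)
```

## The biological problem

The transverse tubular system (t-system) of cardiomyocytes is a network of
surface-membrane invaginations (t-tubules, diameters roughly 0.1-0.5 um)
that carries the action potential into the cell interior. At t-tubules,
L-type Ca$^{2+}$ channels (LTCC) sit within nanometers of ryanodine
receptors (RyR) of the sarcoplasmic reticulum, stabilized by
junctophilin-2 (JPH2); these dyadic junctions make excitation-contraction
(EC) coupling fast and synchronous. In failing myocardium the t-system
remodels: tubules are lost, and some dilate into sheet-like structures
("t-sheets") extended along the myocyte long axis. ttquant implements a
complete, tested pipeline that quantifies this remodeling from 3D confocal
stacks, together with junction integrity and the extracellular-matrix
(ECM) fraction of tissue images, and a statistics layer for cells nested
within samples.

The three t-system measures are, for one segmented cell:

* **TT distance** — for every cytosolic voxel, the Euclidean distance (in
  um, honoring anisotropic voxel spacing) to the nearest t-tubule voxel;
  reported as the cell mean. Larger values mean longer diffusion paths and
  poorer EC coupling.
* **TT density** — t-system volume as a percentage of cell volume.
* **TT volume/length ratio** — t-system volume divided by the length of
  its curve skeleton; an estimate of the mean tubule cross-sectional area
  (um$^2$). Dilation towards t-sheets raises it; pure tubule loss does
  not.

The characteristic disease fingerprint is a higher TT distance and a
higher volume/length ratio at an approximately unchanged TT density:
fewer, but dilated, tubules.

## Data model and conventions

Stacks are `ImageStack` objects: a 4D array indexed `(channel, z, y, x)`
with spacing `(dz, dy, dx)` in um (default `(0.2, 0.1, 0.1)`, the
confocal acquisition geometry this pipeline targets). `z` is the optical
axis; coordinates are voxel centers at `index * spacing` with 0-based
indices. Masks use 26-connectivity throughout. TIFF is the interchange
format; spacing and channel names travel in an embedded description
(ttquant JSON or OME-XML) or a sidecar JSON, and reading fails loudly when
no spacing is resolvable, because every downstream number is denominated
in micrometers.

## Restoration

* **Denoising** (`denoise`): 3D median, radius 1 voxel, by default —
  edge-preserving and appropriate for shot noise on sub-resolution
  structures. A Gaussian variant exists for smoother targets.
* **Deconvolution** (`richardsonLucy`): multiplicative Richardson-Lucy
  updates under an anisotropic Gaussian PSF model (defaults
  `sigmaLateral` 0.15 um, `sigmaAxial` 0.45 um — typical NA 1.4 oil
  values). Convolutions run as FFT products under periodic boundaries, so
  total intensity is conserved; updates never go negative. Thin tubules
  converge slowly along the optical axis: volume estimates keep shrinking
  towards truth out to roughly 100-150 iterations, whereas thicker
  structures (sheets, cluster puncta) converge within a few tens. The
  iteration count is therefore an explicit argument everywhere; an
  optional relative-update stop (`stopTol`) is off in the pipeline so runs
  are exactly reproducible.
* **Depth correction** (`correctDepthAttenuation`): fits
  `log(plane foreground mean) ~ z` (foreground = above the per-plane Otsu
  cut) and applies the inverse exponential; gains are normalized to
  minimum 1 so intensity is only amplified. A per-plane normalization mode
  exists; both are idempotent in practice.
* **Spectral unmixing** (`linearUnmix`): the user supplies the mixing
  matrix `M` (`M[i, j]` = fraction of fluorophore `j` in channel `i`);
  the inverse is applied voxel-wise and negatives are clipped. No
  automatic estimation of `M` is attempted.

## Segmentation

`watershedCells` replaces interactive watershed refinement with a
deterministic procedure. Automatic seeding is topological rather than
intensity-based: the membrane channel is thresholded (Otsu), specks are
removed, pinholes are sealed by a 0.3 um closing, the extracellular bath
is identified as the non-membrane region connected to the stack border,
and every *enclosed* non-membrane component — a cell interior, however
dense its tubule network — becomes one seed. A 3D priority-flood watershed
on the Gaussian-smoothed intensity (sigma 0.8 um) then partitions the
volume; bath basins (those covering more than 10% of the border) are
dropped, as are segments below `minCellVolume` (default 500 um$^3$).
An earlier design seeded from distance-transform pockets of the
smoothed-intensity wall mask; it proved unstable for sparsely tubulated
(disease-like) cells, where Otsu on the smoothed image dissolves the wall,
and was replaced.

Two mask conventions are supported deliberately. With
`claimMembrane = TRUE` (default) a label covers the cell's full footprint
including its surface membrane — appropriate when masks are compared
against whole-cell ground truth. The per-cell metrics pipeline instead
uses ridge-cut masks (`claimMembrane = FALSE`), whose boundary runs along
the membrane-intensity ridge, because the surface/t-system split below
assumes exactly that geometry.

`classifyMembrane` partitions in-cell membrane foreground by depth under
the mask boundary: voxels within `shellDepth` (default 0.5 um, about five
lateral voxels) are surface sarcolemma, deeper voxels are t-system. The
two classes are disjoint and exhaust the in-cell foreground; increasing
the depth can only move voxels from t-system to surface. The source study
does not record how surface and tubular membrane were discerned, so this
depth is the module's central free parameter and is exposed everywhere.

## T-system morphometry

The distance map is an exact anisotropic Euclidean distance transform
(separable lower-envelope algorithm), verified voxel-for-voxel against a
brute-force nearest-target search. By default the distance targets are
t-tubules only (the literal reading of "distance to the nearest
t-tubule"); `includeSurface = TRUE` adds the sarcolemma for users
following the variant common elsewhere in the literature. The reported
mean is over cytosolic voxels — interior voxels excluding the membrane
targets themselves — so the zeros on tubule voxels do not dilute it;
`includeTargets = TRUE` averages over every in-cell voxel instead.

Skeleton length uses topology-preserving curve thinning (simple-point
removal in six directional subiterations). Two guards matter in practice
and are worth documenting: a *plate-rim guard* (a border voxel of a thin
plate may only be removed once the peeling front reaches it; otherwise a
one-voxel-thick sheet is consumed from a corner within a single pass and
its medial line is lost) and *half-space line-end protection* (a voxel
whose foreground neighbors all lie in one face-adjacent half-space is a
curve tip; deleting such tips serially would eat a two-voxel ribbon from
its end). Length is then the minimum spanning tree weight of the
skeleton's 26-adjacency graph per component (Euclidean inter-center edge
weights), which counts each digitized centerline step exactly once —
summing *all* neighbor-pair edges would double-count diagonal chords at
corners — plus a short walk from every degree-1 endpoint through the
original mask to compensate the end caps that thinning consumes. Spur
branches shorter than 0.3 um are pruned first. On digitized test
geometry this measures a 5.0 um tube as 4.9-5.0 um in both lateral and
axial orientation, a radius-0.25 um cylinder's volume/length ratio within
6% of $\pi r^2$, and a 0.3 x 2.0 um slab near its analytic 0.6 um$^2$,
strictly above the cylinder — the t-sheet signature.

## Junctions and ECM

Protein clusters are connected components (26-connectivity by default) of
the per-channel Otsu foreground inside the cell mask, with components
below 4 voxels rejected as noise. Cluster density is the count per cell
volume (um$^{-3}$). Co-localization is cluster-level and boolean: an LTCC
cluster counts as co-localized with RyR (or JPH2) when they share at least
`minOverlapVoxels` (default 1) voxels; the full per-cluster overlap
distribution is returned so stricter cuts can be applied post hoc. The
intact-junction fraction is the percentage of LTCC clusters co-localized
with both RyR and JPH2. Because sub-resolution puncta lose most of their
peak intensity to the PSF, the junction arm of the pipeline deconvolves
before thresholding (30 iterations by default); without it, blur halos of
clusters planted 3.5 radii apart co-localize spuriously and the intact
fraction more than doubles.

The ECM fraction of a WGA-stained tissue stack is the volume fraction
above `histogram mode + k x SD` (defaults: 256-bin histogram over the
analyzed region's range, ties to the lower bin, `k = 1`, statistics over
the whole region of interest). The rule makes the fraction invariant
under affine intensity rescaling and monotone non-increasing in `k`. On a
featureless Gaussian field the rule admits the upper ~16% intensity tail
at `k = 1` — a property worth knowing when interpreting near-zero
fractions.

## Statistics for nested data

Cells are pseudo-replicates within a sample (patient); the group contrast
is therefore estimated by the linear mixed model
`value ~ group + (1 | sample)`, fitted by REML. Inference on the fixed
effect uses a t test with Satterthwaite denominator degrees of freedom.
This choice was made by simulation: at the study design of 5 + 5 samples
with 10 cells each (random-intercept SD 0.10, residual SD 0.15), the
normal (Wald z) approximation rejects a true null 9.3% of the time at
$\alpha = 0.05$, while Satterthwaite holds 5.3%; the package exposes
`dfMethod = "wald"` for comparison. Boundary fits (zero between-sample
variance) are flagged, not errored — the estimate then equals ordinary
least squares. One-way ANOVA across samples tests whether samples stem
from different populations; Welch's unequal-variance t-test serves
two-condition comparisons without a nesting structure; Holm-Bonferroni
adjusts across endpoints. All four are verified against independent
formula or enumeration oracles.

## The phantom generator

Real stacks from the motivating study are not publicly deposited, so
every stage is validated on synthetic phantoms with exact ground truth.

The cell phantom is an elliptic cylinder (defaults 18 um long, semi-axes
5 and 4 um) with a 0.25 um surface shell and a t-tubule lattice:
transverse planes at the sarcomere period (2.0 um) carrying a grid of
tubule line segments (in-plane spacing 3.5 um, radius 0.15 um — the
smallest radius resolvable at 0.1 um lateral sampling), plus sparse axial
connectors (probability 0.15). These defaults give a truth TT density
near 2% and a truth mean TT distance near 0.8-1.0 um, the scale expected
for intact pediatric myocardium. Disease is modeled by two dials stated
as the study conditions: `keepProb = 0.5` (each lattice tubule lost with
probability one half) and `sheetFraction = 0.3` with a 1.5 um
longitudinal sheet width (selected tubules dilated along the cell's long
axis into t-sheets with roughly four times the cross-section; the width
is calibrated on the truth geometry so the dilation compensates the loss
and the disease family stays density-matched to control in expectation). The
geometric consequence is the fingerprint above: distance up,
volume/length up, density approximately compensated. Truth ships with
every phantom: exact voxel sets, the per-segment planting record and the
analytic centerline length (sum of the generating chord lengths).

The imaging forward model applies PSF blur, optional exponential depth
attenuation, optional spill-over mixing, then a constant background
(default 5), Poisson shot noise (`poissonScale` 1) and Gaussian read
noise (SD 3). At the membrane intensity of 100 this leaves a foreground
SNR of about 10. Junction puncta are planted at amplitude 1000 because a
0.2 um sphere retains only ~10% of its peak after blur; the default
amplitude is chosen so the *post-blur* peak SNR is again about 10. The
tissue phantom packs jittered nearest-center cell cross-sections
separated by a bright interstitial band whose width is solved by
bisection to hit a target ECM fraction; the realized fraction is recorded
exactly.

What the phantoms deliberately do not emulate: fluorophore photophysics
(bleaching, blinking), depth-dependent PSF broadening, motion or drift,
sarcomere disarray, nuclei and organelle shadows, and partial-volume
texture inside cells. Passing the phantom suite therefore demonstrates
correctness of the measurement chain under a realistic noise and blur
model, not robustness to every artifact of real tissue.

## Problem sizes and numerical choices

The shipped validation suite uses sizes chosen to make a full run a
matter of minutes on one core: the two-group study runs 5 + 5
pseudo-samples x 8 cells on 12 x 8 x 7 um cells (about 0.6 Mvoxel per
stack) with the lattice spacing scaled to 2.8 um so the cross-section
carries the same number of tubules per plane as the full-size geometry;
single-cell recovery runs the full-size phantom with 150 deconvolution
iterations; the junction phantom uses a ~2000 um$^3$ cell (about 200
LTCC clusters) with 30 iterations; mixed-model calibration uses 1000 null
and 500 effect replicates. Sample-to-sample biological variability in the
study is emulated by jittering the lattice spacing (+/-7%), sarcomere
period (+/-5%) and keep probability (+/-0.04) per pseudo-sample, which
gives the random intercept something real to absorb.

Other numerical choices: Otsu and the histogram mode use 256 bins with
ties to the lower bin; thresholds are strict (`>`); the watershed breaks
priority ties by insertion order, making it deterministic; closing and
erosion run through the exact anisotropic distance transform, so
structuring elements are true physical balls; every stochastic generator
takes one seed and restores the caller's RNG state.

## Known limitations

* The surface-versus-t-system split is a geometric convention
  (`shellDepth`); against membrane that genuinely runs parallel to the
  surface just below it, any depth rule misclassifies.
* Without deconvolution the blur halo inflates detected tubule volume by
  roughly a factor of two at these settings. The inflation depends on the
  structure mix (thin tubules carry more surface per volume than sheets),
  so group comparisons of *density* made without deconvolution are only
  approximately unbiased — with as few as five samples per group, the
  density contrast can wander on either side of zero from study to study.
  The distance and volume/length contrasts are far more robust to this.
  With deconvolution the density bias falls to about +0.2 points at 150
  iterations on the control phantom, at a substantial runtime cost.
* The volume/length ratio presumes a curve-like skeleton; for extreme
  sheet dominance a medial-surface measure would be more faithful.
* The LMM layer fits a single fixed factor with a random intercept, the
  design of the motivating study; random slopes and multi-factor designs
  are out of scope.
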