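# ttquant

Quantification of cardiomyocyte **t-system remodeling**, **EC-coupling
junction integrity** and **extracellular-matrix fraction** from 3D
confocal image stacks — with a fully ground-truthed synthetic phantom
generator and a statistics layer for cells nested within samples.

## Scientific scope

The transverse tubular system (t-system) carries excitation into cardiac
myocytes; its loss and dilation into sheet-like "t-sheets" is a hallmark
of failing myocardium. Given a membrane-stained 3D stack (voxel spacing
`(dz, dy, dx)`, typically `0.2 x 0.1 x 0.1` µm), ttquant restores the
image (median denoising, Richardson–Lucy deconvolution, depth-attenuation
correction, linear spectral unmixing), segments cells (topologically
seeded 3D watershed, morphological closing), splits membrane into surface
sarcolemma versus t-system, and computes per cell:

- **TT distance** — mean over cytosolic voxels *v* of
  `min_{t ∈ tubules} ‖v − t‖` (anisotropic Euclidean metric, µm); the
  EC-coupling relevant diffusion distance,
- **TT density** — `100 · V(t-system) / V(cell)` (%),
- **TT volume/length** — `V(t-system) / L(skeleton)` (µm²), an estimate
  of mean tubule cross-sectional area that rises when t-sheets form,
- cell area (largest optical section, µm²) and cell volume (µm³).

Three-channel immunostains (LTCC, RyR, JPH2) are analyzed by
connected-component cluster detection: cluster densities (µm⁻³), pairwise
cluster co-localization, and the **intact-junction fraction** — the
percentage of LTCC clusters overlapping both a RyR and a JPH2 cluster.
WGA-stained tissue yields the **ECM fraction**: the volume fraction above
the `mode + k·SD` intensity threshold. Group comparisons use the linear
mixed model `value ~ group + (1 | sample)` (REML, Satterthwaite df) with
one-way ANOVA, Welch t-tests and Holm–Bonferroni correction.

Because no raw stacks from the motivating work are publicly deposited,
the package ships a first-class phantom generator (`generateCellPhantom`,
`generateJunctionPhantom`, `generateTissuePhantom`, `applyImaging`) whose
ground truth — exact voxel sets, analytic centerline lengths, planting
records — scores every stage of the pipeline.

## Worked example

Simulate a two-group study (5 control vs 5 myocarditis-like
pseudo-samples, 8 cells each), image every phantom with the confocal
forward model, run the full per-cell pipeline and the statistics layer:

```r
library(ttquant)
rep <- runPhantomStudy(nSamples = 5, cellsPerSample = 8, seed = 101,
                       tubuleSpacing = 2.8,
                       cellArgs = list(lengthUm = 12, semiAxisY = 4,
                                       semiAxisZ = 3.5))
print(rep)
```

```
StudyReport: 80 cells, 10 samples, 2 groups

  cell_area: control 82.4 +/- 0.022 (n=40) | myocarditis 83.3 +/- 0.18 (n=40)
  cell_volume: control 414 +/- 0.23 (n=40) | myocarditis 417 +/- 0.91 (n=40)
  tt_density: control 3.96 +/- 0.038 (n=40) | myocarditis 4.23 +/- 0.17 (n=40)
  tt_distance_mean: control 0.655 +/- 0.0038 (n=40) | myocarditis 0.948 +/- 0.02 (n=40)
  tt_volume_length_ratio: control 0.11 +/- 0.00054 (n=40) | myocarditis 0.122 +/- 0.002 (n=40)

  LMM tt_distance_mean: effect 0.293, p = 1.31e-05 (Holm 2.63e-05)
  LMM tt_density: effect 0.278, p = 0.334 (Holm 0.334)
  LMM tt_volume_length_ratio: effect 0.012, p = 1.44e-07 (Holm 4.31e-07)
```

Reading the output: values are group mean ± standard error over cells.
The disease-like preset (tubule keep probability 0.5, 30% t-sheets)
shows the remodeling fingerprint — mean TT distance up by ~0.3 µm and
volume/length up (both mixed-model p < 0.05 with the per-sample random
intercept), while TT density is statistically unchanged: fewer but
dilated tubules. (This quick run skips deconvolution, so *absolute*
densities carry the blur-halo inflation discussed in the methods
vignette; the truth densities of the same phantoms are in `rep$truth`.) Per-cell rows are in `rep$metrics` (a tidy metrics
table, `writeMetrics()` writes CSV); per-sample means and the underlying
`lme4` fits are in `rep$sampleMeans` and `rep$stats`.

Single stacks go through the same machinery:

```r
st  <- readStack("cell.ome.tif")                       # spacing from metadata
res <- processCellStack(st, rlIterations = 150)        # t-system metrics
jun <- processJunctionStack(st3, cellMask, rlIterations = 30)  # LTCC/RyR/JPH2
ecm <- ecmFraction(getChannel(st, "WGA"), k = 1, spacing = spacing(st))
```

File-driven studies are configured in YAML and run with
`runPipeline("study.yaml", outDir = "report/")`, which writes
`metrics.csv`, `group_summary.csv` and `report.json`.

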