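# tractopet

Tract-disruption-stratified quantification of TSPO-PET in multiple sclerosis,
with a fully synthetic validation cohort.

## Scientific background

Multiple sclerosis (MS) lesions sever white-matter (WM) tracts, and the axons
passing through a lesion degenerate along their entire length — so the injury
caused by a lesion extends far into normal-appearing white matter (NAWM).
Chronic active lesions, visible on susceptibility MRI as **paramagnetic rim
lesions (PRLs)**, are suspected to cause more severe tract damage and more
innate-immune activation than rimless lesions. **TSPO-PET** images activated
microglia in vivo, so the combination of normative tractography and dynamic
TSPO-PET can ask: *is microglial activation in NAWM higher where the passing
tracts are disrupted by lesions — and higher still where they are disrupted
by PRLs?*

`tractopet` implements that full analysis chain:

1. **Tract disruption** (`computeDisruptionMap`): per voxel, the fraction of
   normative streamlines through the voxel that also cross a lesion mask,
   computed by exact segment–grid traversal (compiled); stratified into
   *none* {0}, *low* (0, 0.1], *mid* (0.1, 0.9), *high* [0.9, 1], with an
   optional 10-bin sweep.
2. **PET quantification** (`extractReferenceTAC`, `computeDVRMap`):
   supervised-cluster pseudo-reference extraction (exact NNLS against four
   kinetic class curves), then voxelwise Logan reference-plot DVR
   (distribution volume ratio) over frames with mid-time ≥ t\* = 20 min, on a
   22-frame / 60-minute dynamic schedule (`pkFrameSchedule`).
3. **Normalisation** (`buildGroupWMMask`, `excludeBoundary`, `zscoreMap`):
   DVR maps restricted to a strict-majority healthy-control WM mask minus a
   1 mm guard band around ventricles/gray matter, standardised voxelwise
   against the control cohort.
4. **Group statistics** (`stratifiedMeanZ`, `runGroupAnalysis`): per-stratum
   mean z per subject; PRL+ vs PRL− ANCOVA (age, sex, EDSS, MS subtype),
   paired PRL- vs non-PRL-disruption contrasts within PRL+ patients, EDSS
   models, global DVR group contrasts; Benjamini–Hochberg correction within
   each analysis family.
5. **Synthetic cohorts** (`generateCohort`): a seeded generator producing a
   study-shaped cohort (11 controls, 26 PRL+, 18 PRL− by default) with a
   shared normative tractogram, spherical PRL/non-PRL lesions, a planted
   disruption-linked DVR effect (with extra weight on PRL-disrupted voxels),
   per-subject diffuse WM variability, and full dynamic PET simulated from a
   one-tissue model with tri-exponential plasma input and frame-duration-
   scaled multiplicative noise.
6. **I/O and pipeline** (`readVolume`/`writeVolume`, `readTractogram`
   (TRK/TCK), `readPipelineConfig`, `runPipeline`, and the CLI at
   `inst/scripts/tractopet.R` with `simulate` / `disrupt` / `quantify` /
   `normalize` / `analyze` / `run-all` subcommands over NIfTI/TCK/CSV/JSON
   files).

The methods, parameter choices and limitations are documented in the vignette
source `vignettes/tract-disruption-pet.Rmd`.

## Worked example

```r
library(tractopet)

cohort <- generateCohort(CohortConfig(seed = 42L))
cohort
#> MSCohort: 55 subjects (11 HC, 26 PRL+, 18 PRL-), 400 streamlines, seed 42

res <- analyzeCohort(cohort)
subset(res$results,
       analysis %in% c("prl_status_ancova", "paired_prl_vs_nonprl"),
       select = c(analysis, stratum, estimate, stat, p, p_adj))
#>              analysis stratum estimate    stat        p    p_adj
#>     prl_status_ancova    none  -0.1339 -0.3122 7.57e-01 9.31e-01
#>     prl_status_ancova     low   0.0426  0.0876 9.31e-01 9.31e-01
#>     prl_status_ancova    high   2.3898  4.1666 1.78e-04 5.34e-04
#>  paired_prl_vs_nonprl    none   0.0717  0.1619 8.73e-01 8.73e-01
#>  paired_prl_vs_nonprl     low   0.9142  1.4248 1.67e-01 2.50e-01
#>  paired_prl_vs_nonprl    high   5.2959 38.7175 7.74e-24 2.32e-23
```

The planted effect is recovered exactly where the design says it should be:
PRL+ patients show elevated normalised TSPO uptake only in highly disrupted
NAWM, and within PRL+ patients the PRL-disrupted voxels exceed the
non-PRL-disrupted ones — while the undisrupted strata stay null.

The same analysis runs file-to-file:

```sh
Rscript inst/scripts/tractopet.R init-config --out config.json
Rscript inst/scripts/tractopet.R run-all --config config.json --out results/
```

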