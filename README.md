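# zmapsoz

Surface-based Z-score distribution mapping (Z-map) of interictal
FDG-PET for presurgical evaluation of drug-resistant epilepsy.

In patients being evaluated for epilepsy surgery, focal cortical
hypometabolism on FDG-PET marks candidate epileptogenic cortex, but
healthy cortex varies regionally too. The Z-map approach compares a
patient to a healthy-control template vertex by vertex on the cortical
surface,

    Z_v = (x_v - mu_v) / sigma_v,

where `mu_v` and `sigma_v` are the per-vertex mean and SD of identically
normalized control uptake. The bottom 0.5% of vertices defines the
hypometabolic set, the Destrieux parcels containing them (hemispheres
kept distinct) form the prediction, and SEEG-defined seizure-onset
regions are the reference standard. Region-level concordance is reported
as sensitivity (TPR), specificity (TNR), PPV, NPV, accuracy and Cohen's
kappa, for the whole cohort and stratified by lobe and hemisphere.

The package implements the full chain as tested, reusable components:

* **Volume preprocessing** — adaptive brain masking (coefficient 0.4,
  sigma 2 mm), Gaussian smoothing in world mm, NCC-gated affine
  registration (6/12 dof, gate 0.85), van Cittert partial volume
  correction (PSF FWHM 5 mm), cerebellum-referenced SUVR.
* **Surface mapping** — trilinear sampling at 50% cortical depth along
  inward normals, mass-conserving geodesic-Gaussian smoothing
  (FWHM 20 mm), template-space projection.
* **Z statistics** — global mean normalization, control template
  (sample SD, n−1), Z-maps, bottom-fraction selection, region naming,
  free-threshold viewer overlays.
* **Electrode localization** — cylindrical contact voxelization
  (0.8 × 2 mm, with supersampling on coarse grids) and the strict
  >50%-of-footprint gray-matter rule.
* **Concordance** — region instances from verified contacts
  (any-contact SOZ rule), 2×2 counts, the six metrics with flagged
  undefined values, stratified reporting with an insufficiency floor.
* **Synthetic data** — seeded toy cortices, parcellations, control
  cohorts, lesioned patients, phantom PET/MRI scenes with known
  misalignment, and SEEG contact tables with ground truth, so the whole
  pipeline is testable without patient data. The Destrieux
  region-to-lobe lookup (74 regions per hemisphere: 28 frontal,
  11 parietal, 14 temporal, 13 occipital, 8 insular) is bundled.

## Worked example

Plant a −3 SD lesion in one parcel of a toy cortex, build a 23-control
template, and recover the lesion from the Z-map:

```r
library(zmapsoz)

lh <- makeToySurface(3, seed = 42, "lh")
rh <- makeToySurface(3, seed = 42, "rh")
cortex <- mergeHemispheres(lh, rh)
parc <- mergeParcellations(makeParcellation(lh, 10, seed = 42),
                           makeParcellation(rh, 10, seed = 42))

cfg <- simulationConfig(n_controls = 23, seed = 42)
controls <- lapply(simulateControlCohort(cortex, parc, cfg),
                   globalMeanNormalize)
template <- buildTemplate(controls)

soz <- data.frame(hemisphere = "rh", region = "region_04")
patient <- simulatePatient(cortex, parc, soz, lesion_effect = -3, cfg)
zmap <- computeZMap(globalMeanNormalize(patient$map), template, "example")
zmap
#> ZMap for 'example': 1284 vertices (template n = 23), min Z = -7.63

sel <- selectHypometabolic(zmap, fraction = 0.005, parcellation = parc)
sel@regions
#>   hemisphere    region n_selected_vertices     min_z
#> 1         rh region_04                   6 -7.629015
```

All six selected vertices (0.5% of 1284) fall in the planted parcel:
the Z-map names exactly the lesioned region, with its deepest vertex
7.6 control SDs below the template.

The full volume chain — phantom scene, masking, registration, PVC,
SUVR, projection, Z-map, contact localization and the stratified
metrics table — runs end to end from one seeded config:

```r
res <- runPipeline(zmapRunConfig(seed = 1, output_dir = "run1"))
concordanceMetrics(res$concordance)   # Total / per-lobe / per-hemisphere rows
```

The run directory contains `config.yaml`, `qc.json` (registration NCC
and gate outcome), the Z-map in CSV and FreeSurfer curv form, the
hypometabolic region list, contact assignments, `metrics.csv` in the
Total/lobe/hemisphere layout and raw confusion counts. A thin CLI over
the same functions ships in `inst/cli/zmapsoz.R`
(`simulate | preprocess | project | zmap | localize | evaluate | run`).

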