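---
title: "Surface-based PET Z-score mapping: models, parameters and design choices"
author: "zmapsoz maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based PET Z-score mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the statistic

Interictal FDG-PET of patients with drug-resistant epilepsy typically
shows focal cortical hypometabolism near the epileptogenic zone, but
healthy cortex also shows regionally variable uptake, so raw visual
reading produces false positives. The approach implemented here compares
each patient to a healthy-control template vertex by vertex on the
cortical surface: with per-vertex control mean $\mu_v$ and standard
deviation $\sigma_v$ of identically normalized uptake, the patient map
$x_v$ yields

$$Z_v = \frac{x_v - \mu_v}{\sigma_v}.$$

The 0.5% of vertices with the lowest $Z$ are declared hypometabolic, the
Destrieux parcels containing them (left and right hemispheres kept
distinct) form the predicted set, and SEEG-defined seizure-onset regions
serve as the reference standard for region-level concordance:
sensitivity, specificity, PPV, NPV, accuracy and Cohen's kappa, reported
for the whole cohort and stratified by lobe and hemisphere.

## The processing chain and its assumptions

1. **Brain masking.** The anatomical volume is smoothed with a Gaussian
   ($\sigma = 2$ mm) and thresholded at `intensity_coefficient = 0.4`
   times a robust maximum. The reference statistic for the coefficient is
   not uniquely determined by the method description; we use the 99th
   percentile of the smoothed volume, which is insensitive to isolated
   hot voxels. The largest 6-connected component is kept and interior
   holes filled.
2. **Registration.** PET-to-anatomical alignment uses a 12-parameter
   affine (translation, rotation, scale, shear, composed as
   $T R_z R_y R_x \,\mathrm{Shear}\,\mathrm{Scale}$; a 6-parameter rigid
   mode is available, and is the default for the simulated rigid
   misalignments). The optimizer is multi-start Nelder–Mead over a
   two-level image pyramid maximizing normalized cross-correlation; no
   gradient information is needed, and fixed starting points keep runs
   reproducible. At the fine level the similarity is evaluated on a
   stride-2 voxel subsample; the reported NCC is always full-resolution.
   An alignment whose final NCC does not exceed the 0.85 gate is
   reported as failed, never silently accepted.
3. **Partial volume correction.** Van Cittert iteration
   $f_{k+1} = f_k + \alpha(g - h \ast f_k)$, $f_0 = g$, with an isotropic
   Gaussian PSF of FWHM 5 mm (the scanner's stated spatial resolution),
   $\alpha = 1$ and 10 iterations, with non-negativity clamping after
   each step and a divergence guard (stop and warn if the residual norm
   grows twice in a row). The method description names only the
   algorithm; $\alpha$ and the iteration count are standard textbook
   settings and are exposed in the configuration.
4. **SUVR.** Division by the mean uptake in the cerebellum mask. The
   ordering PVC → SUVR is a package choice (the source description does
   not fix it); because SUVR is a global rescaling, the order only
   matters through PVC's clamping, and both steps are configurable.
5. **Surface projection.** Each vertex samples the volume trilinearly at
   `vertex - 0.5 * thickness * normal`, i.e. at 50% cortical depth along
   the inward normal (normals point outward on the pial-like surface;
   the sign convention is fixed and covered by an exactness test on
   linear fields). Vertices outside the field of view are flagged
   missing; more than 10% missing aborts as a geometry mismatch.
6. **Surface smoothing (FWHM 20 mm).** Exact geodesic convolution is
   replaced by iterated lumped-mass graph diffusion
   $x \leftarrow x + \Delta t\, M^{-1}(A - D)x$, which conserves the
   surface-area-weighted mean exactly on closed meshes. Each pass adds
   kernel variance of roughly $\lambda_{\mathrm{eff}} \bar h^2/2$ per
   tangent direction ($\bar h$ = mean edge length), so the iteration
   count is $\lceil \sigma^2 / (\lambda_{\mathrm{eff}} \bar h^2 / 2)
   \rceil$ with $\sigma = \mathrm{FWHM}/2.3548$. A numerical calibration
   test checks the realized FWHM of a smoothed delta against the request
   within 25%.
7. **Normalization and template.** Global mean normalization divides a
   map by its cortex-mask mean, removing inter-subject scale. The
   template uses the per-vertex sample mean and the $n-1$ sample SD
   (unbiased at a 23-subject cohort); vertices whose SD falls below
   $10^{-6}$ of the mean template level are flagged degenerate rather
   than allowed to produce infinite Z.
8. **Selection.** $k = \max(1, \lfloor 0.005 \cdot \text{usable}
   \rfloor)$ lowest-Z vertices, missing vertices excluded from numerator
   and denominator, ties broken by ascending vertex index; the fraction
   is computed over both hemispheres jointly (a per-hemisphere variant
   is a one-line change in the caller). A region is hypometabolic as
   soon as one selected vertex carries its label (`min_vertices` raises
   the bar if desired). These rounding and tie rules are package
   decisions — the method description states only "0.5%" — chosen to be
   deterministic and exactly testable.
9. **Contact localization.** A contact is a cylinder of diameter 0.8 mm
   and length 2 mm. Its footprint is the set of label-volume voxels
   whose centres fall inside the cylinder; when the grid is coarser than
   the contact (footprint under 8 voxels) candidate voxels are
   subdivided (at least 4 per axis, refined until the sub-grid pitch is
   below half the contact radius) and fractional occupancy is used. The
   contact is assigned to a region only when that region holds strictly
   more than 50% of the footprint, the denominator being the whole
   footprint including background and white matter — a documented
   reading, since the source rule does not say how non-gray labels enter
   the denominator. Exact 50/50 splits fail verification.
10. **Region instances and metrics.** Verified contacts collapse to one
    instance per (patient, hemisphere, region); an instance is SOZ if
    any of its contacts carries the SEEG onset flag (the source does not
    define the collapsing rule; any-contact is the default and is
    recorded in the outputs). Cohen's kappa uses
    $p_e = [(TP{+}FN)(TP{+}FP) + (FP{+}TN)(FN{+}TN)]/N^2$. Metrics with
    zero denominators are flagged `NA`, never coerced to zero. Strata
    with fewer than 30 instances (configurable) are flagged
    insufficient instead of being reported numerically, mirroring the
    exclusion of under-sampled lobes from cohort reporting; the Total
    row is always reported.

## The synthetic data model

No patient data ship with the package; a seeded generator produces every
input the chain consumes.

* **Surfaces.** Subdivided icosahedra ($10 \cdot 4^n + 2$ vertices;
  default $n = 3$, 642 per hemisphere) deformed to hemisphere-sized
  ellipsoids (semi-axes 28 × 65 × 50 mm, centres at $x = \pm 30$ mm).
  Vertex thickness equals the local geometric depth of the phantom gray
  ribbon plus a small smooth seeded perturbation, clamped to
  [1.5, 4.5] mm, so mid-depth sampling lands mid-ribbon by construction.
* **Parcellation.** Farthest-point seeds grown breadth-first over mesh
  edges give edge-connected parcels (default 10 per hemisphere) with a
  lobe attached cyclically. The real Destrieux lobe lookup (74 regions
  per hemisphere: 28 frontal, 11 parietal, 14 temporal, 13 occipital,
  8 insular) ships as a static table; the published counts sum to 74
  while the accompanying text also mentions one unclassified region, so
  the table keeps the five counts as printed and carries the medial
  wall as an optional "unclassified" row. The lobe membership of each
  named region is authored from standard sulco-gyral anatomy (the
  source does not print the mapping) and is synthetic in that sense.
* **Control cohort.** Each control map is a smooth regional baseline
  (seeded region levels in [0.9, 1.3], feathered across boundaries)
  plus vertex-independent Gaussian noise with SD
  `control_noise_sd * baseline`. The default cohort is 23 controls with
  8% noise — a typical inter-subject coefficient of variation for
  normalized cortical FDG uptake. Spatial noise correlation is
  deliberately absent: it is the simplest model that exercises the Z
  statistic, and the calibration test (held-out control Z mean ≈ 0, SD
  ≈ 1) is exact under it.
* **Patients.** A control draw with `lesion_effect` × control SD added
  over whole parcels (default −3, i.e. the planted deficit equals the
  reporting convention of "three standard deviations below controls").
  Region-aligned lesions match the region-level evaluation unit;
  partial-parcel lesions can be produced by passing a custom region
  list.
* **Phantom volumes.** A 64³ grid at 3 mm: head ellipsoid with skull
  shell and soft tissue, the two hemisphere ellipsoids with a
  92–100% radial gray ribbon whose activity follows the same baseline
  (and lesions) as the surface cohort, a white-matter bridge and
  brainstem capsule keeping the brain 6-connected, and a spherical
  cerebellum of uniform reference uptake. The observed PET is the true
  activity blurred with the 5 mm PSF and resampled under a known rigid
  misalignment (default translation (4, −3, 2) mm); the ground truth
  records the transform registration should recover. Scanner physics
  beyond the Gaussian PSF, cortical folding and deformable anatomy are
  explicitly not modelled.
* **Contacts.** Electrodes run radially outward from a target region's
  deepest representative voxel, contacts at a centre-to-centre pitch of
  `length + spacing` (2 mm + 1.5 mm; the stated inter-contact spacing is
  interpreted as the insulation gap, since a 1.5 mm pitch would overlap
  2 mm contacts). Ground-truth contact regions are majority labels over
  the true footprints; contacts in planted SOZ regions carry the onset
  flag.

In the end-to-end pipeline the control template is built the way the
real workflow builds it — from identically processed data: an
unlesioned phantom is blurred, corrected and projected once, and each
control's multiplicative vertex variation rides on that projected
baseline. Systematic projection bias therefore cancels in the Z-score,
and what remains measurable is the planted lesion.

## What passing tests do and do not show

The generator's Gaussian, spatially independent noise and ellipsoidal
geometry make the Z statistic exactly calibrated and lesions cleanly
recoverable; real cortical folding, spatially correlated physiology,
reconstruction artifacts and registration failure modes are all absent.
Passing the planted-lesion recovery checks therefore validates the
statistical machinery and the plumbing, not clinical performance; the
published cohort-level concordance values cannot be recomputed here
because the underlying patient data are not deposited.

## Problem sizes and determinism

Default test-time sizes are 642-vertex hemispheres, 23-control cohorts,
64³ phantoms and 100-seed recovery loops — sizes at which every check
runs on a laptop core. All randomness flows through a single seed per
generator call (internally split into independent streams), so every
artifact of a run, including the full pipeline output directory, is
bit-for-bit reproducible from (config, seed); the test suite asserts
this on the byte level.

## Known limitations

* Surface smoothing is a diffusion approximation of geodesic Gaussian
  convolution; its realized FWHM is accurate to roughly ±15% on
  near-uniform meshes and degrades on highly irregular ones.
* The van Cittert scheme amplifies high-frequency noise if iterated far
  beyond the default; the divergence guard stops it but does not make
  more iterations useful.
* Subcortical structures (hippocampus, amygdala) are outside a
  surface-based analysis and outside the bundled cortical lookup; deep
  sources of seizure onset are invisible to the method by design.
* The registration capture range is roughly ±10 mm / ±10° around the
  multi-start grid; larger misalignments fail the NCC gate and abort
  the pipeline rather than degrade silently.
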