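Package: zmapsoz
Title: Surface-Based PET Z-Score Mapping for Seizure Onset Zone Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Vertex-wise Z-score distribution mapping (Z-map) of
    interictal FDG-PET against a healthy-control template on the cortical
    surface, for presurgical evaluation of drug-resistant epilepsy.
    Implements the volume preprocessing chain (adaptive brain masking,
    Gaussian smoothing, NCC-gated affine registration, van Cittert partial
    volume correction, cerebellum-referenced SUVR), projection of PET onto
    cortical surfaces at mid-cortical depth with geodesic smoothing,
    control-template construction and vertex Z-statistics, bottom-fraction
    hypometabolic region extraction on a Destrieux-style parcellation,
    SEEG contact gray-matter localization by the majority-voxel rule, and
    region-level concordance metrics (sensitivity, specificity, PPV, NPV,
    accuracy, Cohen's kappa) stratified by lobe and hemisphere. A seeded
    synthetic-data module generates surfaces, parcellations, control
    cohorts, lesioned patients, phantom volume scenes and contact tables
    so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'concordance.R'
    'volume-preproc.R'
    'electrode-localization.R'
    'io-formats.R'
    'zmap.R'
    'synthetic-surface.R'
    'surface-mapping.R'
    'synthetic-cohort.R'
    'synthetic-volume.R'
    'pipeline.R'
    'utils.R'
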