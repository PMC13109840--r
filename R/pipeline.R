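#' @include synthetic-volume.R surface-mapping.R zmap.R concordance.R
NULL

#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end pipeline in one
#' validated object.  Defaults are the method's reference settings: mask
#' coefficient 0.4, PVC with 5 mm PSF / alpha 1 / 10 iterations, 20 mm
#' surface kernel, 50% sampling depth, bottom 0.5% selection, NCC gate
#' 0.85 and a 30-instance stratum reporting floor.
#' `post_smooth_fwhm_mm` applies scanner-style post-reconstruction
#' smoothing and defaults to 0 because the synthetic phantom PET already
#' carries its PSF; set it (e.g. 4.5 mm) for unsmoothed input data.
#'
#' @param seed master seed; determines every random draw of the run.
#' @param output_dir run directory (created; config echoed into it).
#' @param n_controls,control_noise_sd,lesion_effect,mesh_subdivisions,n_regions_per_hemisphere
#'   synthetic cohort settings (see [simulationConfig()]).
#' @param mask_coefficient,mask_sigma_mm brain-mask settings.
#' @param post_smooth_fwhm_mm optional extra PET smoothing FWHM (mm).
#' @param pvc_fwhm_mm,pvc_alpha,pvc_iterations van Cittert settings.
#' @param registration_dof 6 or 12.
#' @param ncc_gate registration acceptance NCC.
#' @param surface_fwhm_mm surface smoothing FWHM (mm).
#' @param depth_fraction cortical sampling depth fraction.
#' @param selection_fraction bottom-Z selection fraction.
#' @param stratum_floor minimum instances for numeric stratum reporting.
#' @param n_electrodes,contacts_per_electrode synthetic SEEG settings.
#' @param misalign_translation planted PET-to-MRI misalignment (mm).
#' @param grid_dim,voxel_mm phantom grid geometry.
#' @return validated list of class "ZMapRunConfig".
#' @export
zmapRunConfig <- function(seed = 1L,
                          output_dir = tempfile("zmaprun"),
                          n_controls = 23L,
                          control_noise_sd = 0.08,
                          lesion_effect = -3,
                          mesh_subdivisions = 3L,
                          n_regions_per_hemisphere = 10L,
                          mask_coefficient = 0.4,
                          mask_sigma_mm = 2.0,
                          post_smooth_fwhm_mm = 0,
                          pvc_fwhm_mm = 5.0,
                          pvc_alpha = 1.0,
                          pvc_iterations = 10L,
                          registration_dof = 6L,
                          ncc_gate = 0.85,
                          surface_fwhm_mm = 20.0,
                          depth_fraction = 0.5,
                          selection_fraction = 0.005,
                          stratum_floor = 30,
                          n_electrodes = 6L,
                          contacts_per_electrode = 8L,
                          misalign_translation = c(4, -3, 2),
                          grid_dim = 64L,
                          voxel_mm = 3) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_controls >= 2, cfg$selection_fraction > 0,
            cfg$selection_fraction <= 1, cfg$registration_dof %in% c(6, 12),
            cfg$depth_fraction >= 0, cfg$depth_fraction <= 1,
            length(cfg$misalign_translation) == 3)
  structure(cfg, class = "ZMapRunConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the [zmapRunConfig()] arguments; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return a "ZMapRunConfig" list.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(zmapRunConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(zmapRunConfig, vals)
}

withStage <- function(stage, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  cat(sprintf("[%s] completed in %.1f s\n", stage,
              proc.time()[["elapsed"]] - t0), file = log, append = TRUE)
  res
}

#' Run the full synthetic Z-map pipeline
#'
#' Orchestrates simulate, preprocess (mask, registration with NCC gate,
#' PVC, SUVR), surface projection, Z-map and bottom-fraction selection,
#' contact localization and stratified concordance evaluation.  All
#' artifacts (config echo, QC JSON, Z-map overlays, region CSV, contact
#' assignment CSV, metrics CSV, confusion-count JSON) are written into the
#' run directory and are bit-for-bit reproducible from (config, seed).
#' Any stage error aborts the run naming the stage.
#'
#' @param config a [zmapRunConfig()] (or "ZMapRunConfig" list).
#' @return invisibly, a list with the run directory, the
#'   [ConcordanceResult-class], the [ZMap-class], the selection and the
#'   QC report.
#' @export
runPipeline <- function(config = zmapRunConfig()) {
  stopifnot(inherits(config, "ZMapRunConfig"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  log <- out("log.txt")
  cat("zmapsoz pipeline run\n", file = log)
  echo <- config
  echo$output_dir <- NULL
  yaml::write_yaml(unclass(echo), out("config.yaml"))
  cat(paste0("parameters: ",
             paste(names(echo), vapply(echo, function(x)
               paste(format(x), collapse = ","), ""), sep = "=",
               collapse = "; "), "\n"),
      file = log, append = TRUE)

  simcfg <- simulationConfig(
    n_controls = config$n_controls,
    control_noise_sd = config$control_noise_sd,
    lesion_effect = config$lesion_effect,
    mesh_subdivisions = config$mesh_subdivisions,
    n_regions_per_hemisphere = config$n_regions_per_hemisphere,
    seed = config$seed)

  sim <- withStage("simulate", log, {
    scene <- simulateVolumeScene(
      simcfg, misalign_translation = config$misalign_translation,
      grid_dim = config$grid_dim, voxel_mm = config$voxel_mm,
      psf_fwhm_mm = config$pvc_fwhm_mm)
    ct <- simulateContacts(scene$label, scene$label_table,
                           n_electrodes = config$n_electrodes,
                           contacts_per_electrode =
                             config$contacts_per_electrode,
                           soz_regions = scene$soz_regions,
                           seed = config$seed)
    list(scene = scene, contacts = ct)
  })
  scene <- sim$scene

  prep <- withStage("preprocess", log, {
    mask <- brainMask(scene$anatomical, config$mask_coefficient,
                      config$mask_sigma_mm)
    pet <- scene$pet
    if (config$post_smooth_fwhm_mm > 0)
      pet <- gaussianSmoothVolume(pet,
                                  fwhm_mm = config$post_smooth_fwhm_mm)
    reg <- affineRegister(pet, scene$anatomical,
                          dof = config$registration_dof,
                          gate = config$ncc_gate)
    if (!reg$report@passedGate)
      stop(sprintf("registration gate failed (NCC %.3f <= %.2f)",
                   reg$report@finalNCC, reg$report@gate))
    aligned <- resampleAffine(pet, reg$transform, scene$anatomical)
    corrected <- vanCittertPVC(aligned, psf_fwhm_mm = config$pvc_fwhm_mm,
                               alpha = config$pvc_alpha,
                               n_iter = config$pvc_iterations)
    ratio <- suvr(corrected, scene$cerebellum_mask)
    qc <- list(ncc = reg$report@finalNCC,
               ncc_gate = reg$report@gate,
               gate_passed = reg$report@passedGate,
               optimizer_evaluations = reg$report@iterations,
               registration_translation_mm =
                 unname(reg$transform@parameters[1:3]),
               brain_mask_voxels = sum(mask@data > 0),
               brain_mask_ml = sum(mask@data > 0) *
                 prod(voxelSize(mask)) / 1000)
    jsonlite::write_json(qc, out("qc.json"), auto_unbox = TRUE,
                         digits = NA)
    list(suvr = ratio, mask = mask, qc = qc)
  })

  patientNorm <- withStage("project", log, {
    sampled <- sampleAtDepth(prep$suvr, scene$surface,
                             depth_fraction = config$depth_fraction)
    smoothed <- smoothSurfaceMap(scene$surface, sampled,
                                 fwhm_mm = config$surface_fwhm_mm)
    globalMeanNormalize(smoothed)
  })

  zres <- withStage("zmap", log, {
    # Controls go through the same acquisition/projection chain as the
    # patient (as in the real workflow, where the template is built from
    # identically processed control scans): an unlesioned control
    # phantom is blurred, corrected and projected once, and each
    # control's multiplicative vertex variation rides on that projected
    # baseline, so systematic projection bias cancels in the Z-score.
    simcfg0 <- simcfg
    simcfg0$lesion_effect <- 0
    ctrlScene <- simulateVolumeScene(
      simcfg0, misalign_translation = c(0, 0, 0),
      grid_dim = config$grid_dim, voxel_mm = config$voxel_mm,
      psf_fwhm_mm = config$pvc_fwhm_mm)
    ctrlCorr <- vanCittertPVC(ctrlScene$pet,
                              psf_fwhm_mm = config$pvc_fwhm_mm,
                              alpha = config$pvc_alpha,
                              n_iter = config$pvc_iterations)
    ctrlBase <- sampleAtDepth(suvr(ctrlCorr, ctrlScene$cerebellum_mask),
                              scene$surface,
                              depth_fraction = config$depth_fraction)
    baseline <- regionalBaseline(scene$surface, scene$parcellation,
                                 simcfg)
    cohort <- simulateControlCohort(scene$surface, scene$parcellation,
                                    simcfg)
    cohort <- lapply(cohort, function(m) {
      proj <- ctrlBase@values * (m@values / baseline)
      globalMeanNormalize(smoothSurfaceMap(scene$surface, proj,
                                           fwhm_mm =
                                             config$surface_fwhm_mm))
    })
    template <- buildTemplate(cohort)
    zmap <- computeZMap(patientNorm, template,
                        patient_id = sprintf("sim%03d", config$seed))
    sel <- selectHypometabolic(zmap, fraction = config$selection_fraction,
                               parcellation = scene$parcellation)
    writeVertexMap(zmap@z, out("patient_zmap.csv"))
    writeVertexMap(ifelse(is.na(zmap@z), 0, zmap@z),
                   out("patient_zmap.curv"))
    utils::write.csv(sel@regions, out("hypometabolic_regions.csv"),
                     row.names = FALSE)
    list(template = template, zmap = zmap, selection = sel)
  })

  loc <- withStage("localize", log, {
    flt <- filterGrayMatterContacts(sim$contacts$contacts, scene$label,
                                    scene$label_table)
    utils::write.csv(flt$report, out("contact_assignments.csv"),
                     row.names = FALSE)
    flt
  })

  result <- withStage("evaluate", log, {
    lt <- scene$parcellation@lobeTable
    lobeTab <- rbind(cbind(hemisphere = "lh", lt),
                     cbind(hemisphere = "rh", lt))
    instances <- buildRegionInstances(sim$contacts$contacts, loc$report,
                                      lobeTab,
                                      patient_id =
                                        sprintf("sim%03d", config$seed))
    res <- stratifyAndReport(instances, zres$selection,
                             floor = config$stratum_floor)
    utils::write.csv(res@metrics, out("metrics.csv"), row.names = FALSE)
    counts <- res@metrics[, c("Category", "N", "TP", "FP", "FN", "TN")]
    jsonlite::write_json(counts, out("confusion_counts.json"),
                         digits = NA)
    res
  })

  invisible(list(run_dir = config$output_dir, concordance = result,
                 zmap = zres$zmap, selection = zres$selection,
                 qc = prep$qc, instances_file = out("metrics.csv")))
}
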