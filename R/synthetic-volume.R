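#' @include synthetic-cohort.R volume-preproc.R electrode-localization.R
NULL

# Normalized ellipsoid radius of world points: 1 on the surface.
ellipsoidRho <- function(world, center, radii) {
  sqrt(((world[, 1] - center[1]) / radii[1])^2 +
         ((world[, 2] - center[2]) / radii[2])^2 +
         ((world[, 3] - center[3]) / radii[3])^2)
}

#' Simulate a phantom head scene with paired anatomical and PET volumes
#'
#' Builds an ellipsoidal head with a skull shell, two hemisphere
#' ellipsoids (matching [makeToySurface()] geometry) with a gray-matter
#' ribbon whose regional uptake follows the same seeded baseline profile
#' as the surface cohort (with the configured lesions applied), a
#' brainstem bridge and a cerebellum compartment of known uniform
#' reference uptake.  The observed PET volume is the true activity
#' convolved with an isotropic Gaussian PSF (FWHM 5 mm) and misaligned
#' from the anatomical grid by a known rigid transform; everything is
#' deterministic given the config seed.
#'
#' @param config a [simulationConfig()].
#' @param misalign_translation world-mm translation of the planted
#'   misalignment (default c(4, -3, 2)); use c(0, 0, 0) for aligned
#'   grids.
#' @param misalign_rotation planted rotation in radians (default zero).
#' @param grid_dim cubic grid size (default 64).
#' @param voxel_mm isotropic voxel size (default 3 mm).
#' @param psf_fwhm_mm PET point-spread FWHM (default 5 mm).
#' @param reference_uptake uniform cerebellum activity (default 100).
#' @return list with VolumeImage elements `anatomical`, `pet`, `label`,
#'   `cerebellum_mask`, `brain_mask_truth`, `true_activity`, plus
#'   `truth` ([GroundTruth-class]; its trueAffine maps anatomical world
#'   to PET world, i.e. the transform registration should recover),
#'   `label_table`, `surface` (merged toy cortex), `parcellation`, and
#'   `soz_regions`.
#' @export
simulateVolumeScene <- function(config,
                                misalign_translation = c(4, -3, 2),
                                misalign_rotation = c(0, 0, 0),
                                grid_dim = 64L, voxel_mm = 3,
                                psf_fwhm_mm = 5,
                                reference_uptake = 100) {
  stopifnot(inherits(config, "SimulationConfig"))
  hemiRadii <- c(28, 65, 50)
  hemiOffset <- 30
  lh <- makeToySurface(config$mesh_subdivisions, config$seed, "lh",
                       radii = hemiRadii, center = c(-hemiOffset, 0, 0))
  rh <- makeToySurface(config$mesh_subdivisions, config$seed, "rh",
                       radii = hemiRadii, center = c(hemiOffset, 0, 0))
  pl <- makeParcellation(lh, config$n_regions_per_hemisphere, config$seed)
  pr <- makeParcellation(rh, config$n_regions_per_hemisphere, config$seed)
  surface <- mergeHemispheres(lh, rh)
  parc <- mergeParcellations(pl, pr)
  soz <- config$lesion_regions
  if (is.null(soz))
    soz <- data.frame(hemisphere = "lh",
                      region = sort(unique(pl@region))[1],
                      stringsAsFactors = FALSE)

  d <- rep(as.integer(grid_dim), 3)
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -voxel_mm * (d - 1) / 2
  world <- cbind(voxelIndexGrid(d), 1) %*% t(aff)
  world <- world[, 1:3, drop = FALSE]

  rhoHead <- ellipsoidRho(world, c(0, 0, 0), c(70, 85, 75))
  rhoL <- ellipsoidRho(world, c(-hemiOffset, 0, 0), hemiRadii)
  rhoR <- ellipsoidRho(world, c(hemiOffset, 0, 0), hemiRadii)
  ribbonInner <- 1 - toyRibbonFraction
  inHemi <- rhoL <= 1 | rhoR <= 1
  inWhite <- rhoL < ribbonInner | rhoR < ribbonInner
  inRibbon <- inHemi & !inWhite
  capsule <- function(p0, p1, radius) {
    seg <- p1 - p0
    t <- pmin(pmax(as.numeric(sweep(world, 2, p0) %*% seg) / sum(seg^2),
                   0), 1)
    nearest <- outer(t, seg) + rep(p0, each = nrow(world))
    sqrt(rowSums((world - nearest)^2)) <= radius
  }
  # deep white-matter bridge joining the hemispheres across the midline,
  # and a brainstem capsule running down to the cerebellum
  inBridge <- capsule(c(-12, 0, 5), c(12, 0, 5), 12) & !inHemi
  inStem <- capsule(c(0, 0, 0), c(0, -55, -35), 8) & !inHemi & !inBridge
  inCereb <- sqrt(rowSums(sweep(world, 2, c(0, -55, -35))^2)) <= 18 &
    !inHemi & !inBridge & !inStem
  inSkull <- rhoHead <= 1 & rhoHead >= 0.92 &
    !inHemi & !inBridge & !inStem & !inCereb
  inSoft <- rhoHead < 0.92 & !inHemi & !inBridge & !inStem & !inCereb

  # region labels for ribbon voxels: nearest surface vertex
  ribIdx <- which(inRibbon)
  vtx <- surface@vertices
  nearVert <- integer(length(ribIdx))
  block <- 2048L
  for (s in seq(1, length(ribIdx), by = block)) {
    e <- min(s + block - 1L, length(ribIdx))
    W <- world[ribIdx[s:e], , drop = FALSE]
    d2 <- outer(rowSums(W^2), rep(1, nrow(vtx))) -
      2 * W %*% t(vtx) + outer(rep(1, nrow(W)), rowSums(vtx^2))
    nearVert[s:e] <- max.col(-d2, ties.method = "first")
  }
  regKey <- paste(parc@hemisphere, parc@region)
  regions <- sort(unique(regKey))
  codeOf <- 10L + seq_along(regions)
  labelTable <- rbind(
    data.frame(code = c(0L, 1L, 2L, 3L, 4L, 5L),
               hemisphere = NA_character_,
               region = c("background", "soft_tissue", "skull",
                          "white_matter", "brainstem", "cerebellum"),
               gray = FALSE, stringsAsFactors = FALSE),
    data.frame(code = codeOf,
               hemisphere = sub(" .*$", "", regions),
               region = sub("^[^ ]+ ", "", regions),
               gray = TRUE, stringsAsFactors = FALSE))

  lab <- integer(nrow(world))
  lab[inSoft] <- 1L; lab[inSkull] <- 2L
  lab[inWhite | inBridge] <- 3L; lab[inStem] <- 4L; lab[inCereb] <- 5L
  lab[ribIdx] <- codeOf[match(regKey[nearVert], regions)]

  anat <- numeric(nrow(world))
  anat[inSoft] <- 15; anat[inSkull] <- 35
  anat[inRibbon] <- 90; anat[inWhite | inBridge] <- 100
  anat[inStem] <- 95; anat[inCereb] <- 95

  # true metabolic activity: gray ribbon follows the cohort baseline
  # profile (with lesions applied in control-SD units), scaled so the
  # cerebellum reference sits at reference_uptake
  baseline <- regionalBaseline(surface, parc, config)
  sdv <- config$control_noise_sd * baseline
  lesioned <- regKey %in% paste(soz$hemisphere, soz$region)
  patientVert <- baseline
  patientVert[lesioned] <- patientVert[lesioned] +
    config$lesion_effect * sdv[lesioned]
  act <- numeric(nrow(world))
  act[inSoft] <- 5; act[inSkull] <- 2
  act[inWhite | inBridge] <- 0.65 * reference_uptake
  act[inStem] <- 0.75 * reference_uptake
  act[inCereb] <- reference_uptake
  act[ribIdx] <- 1.1 * reference_uptake * patientVert[nearVert]

  trueActivity <- VolumeImage(array(act, d), aff)
  blurred <- gaussianSmoothVolume(trueActivity, fwhm_mm = psf_fwhm_mm)
  trueAffine <- affineTransform(misalign_translation, misalign_rotation,
                                dof = 6L)
  identityMis <- all(misalign_translation == 0) &&
    all(misalign_rotation == 0)
  pet <- if (identityMis) blurred
  else resampleAffine(blurred, solve(trueAffine@matrix), blurred)

  brainTruth <- inHemi | inBridge | inStem | inCereb
  truth <- new("GroundTruth",
               sozRegions = soz[, c("hemisphere", "region")],
               contactRegions = data.frame(contact_id = character(),
                                           hemisphere = character(),
                                           region = character()),
               trueAffine = trueAffine@matrix)
  list(anatomical = VolumeImage(array(anat, d), aff),
       pet = pet,
       label = VolumeImage(array(as.numeric(lab), d), aff,
                           units = "label"),
       cerebellum_mask = VolumeImage(array(as.numeric(inCereb), d), aff,
                                     units = "mask"),
       brain_mask_truth = VolumeImage(array(as.numeric(brainTruth), d),
                                      aff, units = "mask"),
       true_activity = trueActivity,
       truth = truth, label_table = labelTable,
       surface = surface, parcellation = parc, soz_regions = soz)
}

#' Simulate straight SEEG electrode trajectories with cylindrical contacts
#'
#' Each electrode targets one gray-matter region: its deepest contact sits
#' at the region's voxel centroid and further contacts follow the outward
#' radial direction with centre-to-centre pitch `length + spacing` (2 mm
#' contacts separated by a 1.5 mm insulation gap by default).  Planted SOZ
#' regions are always targeted first; remaining electrodes target a
#' seeded random sample of other regions.  The ground-truth region of
#' every contact is the majority label over its true voxel footprint, and
#' contacts whose true region is a planted SOZ region are flagged as
#' seizure onset.
#'
#' @param label_volume integer-label [VolumeImage-class] (from
#'   [simulateVolumeScene()]).
#' @param label_table its label coding table.
#' @param n_electrodes number of electrodes.
#' @param contacts_per_electrode contacts per electrode, in 5..18.
#' @param soz_regions data.frame(hemisphere, region) of planted SOZ
#'   regions.
#' @param seed integer seed.
#' @param spacing_mm insulation gap between consecutive contacts
#'   (default 1.5 mm).
#' @param diameter,length contact cylinder geometry in mm.
#' @return list with `contacts` ([ContactTable-class]) and `truth`
#'   ([GroundTruth-class] carrying the per-contact region assignments).
#' @export
simulateContacts <- function(label_volume, label_table, n_electrodes = 5L,
                             contacts_per_electrode = 8L, soz_regions,
                             seed = 1L, spacing_mm = 1.5,
                             diameter = 0.8, length = 2.0) {
  stopifnot(is(label_volume, "VolumeImage"),
            contacts_per_electrode >= 5, contacts_per_electrode <= 18)
  gray <- label_table[label_table$gray, , drop = FALSE]
  present <- unique(as.integer(label_volume@data))
  gray <- gray[gray$code %in% present, , drop = FALSE]
  if (!nrow(gray)) stop("label volume contains no gray-matter regions")
  sozKey <- paste(soz_regions$hemisphere, soz_regions$region)
  grayKey <- paste(gray$hemisphere, gray$region)
  if (!all(sozKey %in% grayKey))
    stop("SOZ region(s) absent from the label volume: ",
         paste(setdiff(sozKey, grayKey), collapse = ", "))
  others <- setdiff(grayKey, sozKey)
  nOther <- max(0L, n_electrodes - base::length(sozKey))
  targets <- c(sozKey,
               withSeed(childSeed(seed, 40L),
                        sample(others, min(nOther, base::length(others)))))
  targets <- targets[seq_len(min(n_electrodes, base::length(targets)))]

  d <- dim(label_volume@data)
  idxGrid <- voxelIndexGrid(d)
  pitch <- length + spacing_mm
  rows <- list()
  truthRows <- list()
  for (e in seq_along(targets)) {
    code <- gray$code[match(targets[e], grayKey)]
    vox <- idxGrid[as.integer(label_volume@data) == code, , drop = FALSE]
    # deepest contact at the in-region voxel nearest the region centroid
    # (the raw centroid of a curved ribbon patch lies off the ribbon)
    d2c <- rowSums(sweep(vox, 2, colMeans(vox))^2)
    tip <- vox[which.min(d2c), ]
    centroid <- (label_volume@affine %*% c(tip, 1))[1:3]
    hemi <- gray$hemisphere[match(targets[e], grayKey)]
    hemiCenter <- c(if (hemi == "lh") -30 else 30, 0, 0)
    axis <- centroid - hemiCenter
    axis <- axis / sqrt(sum(axis^2))
    for (k in seq_len(contacts_per_electrode)) {
      ctr <- centroid + (k - 1) * pitch * axis
      voxC <- (solve(label_volume@affine) %*% c(ctr, 1))[1:3]
      if (any(voxC < 0) || any(voxC > d - 1))
        stop("electrode trajectory exits the volume (electrode ", e,
             ", contact ", k, ")")
      rows[[base::length(rows) + 1L]] <- data.frame(
        contact_id = sprintf("E%02dC%02d", e, k),
        electrode = sprintf("E%02d", e),
        x = ctr[1], y = ctr[2], z = ctr[3],
        axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
        diameter = diameter, length = length,
        soz_flag = FALSE, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  # ground-truth assignment: majority label over the true voxel footprint
  for (i in seq_len(nrow(df))) {
    a <- tryCatch({
      fp <- voxelizeContact(df[i, ], label_volume)
      assignContactRegion(fp, label_volume, label_table,
                          contact_id = df$contact_id[i])
    }, error = function(e) NULL)
    truthRows[[i]] <- data.frame(
      contact_id = df$contact_id[i],
      hemisphere = if (!is.null(a)) a@hemisphere else NA_character_,
      region = if (!is.null(a)) a@region else NA_character_,
      stringsAsFactors = FALSE)
  }
  truthDf <- do.call(rbind, truthRows)
  isSoz <- !is.na(truthDf$region) &
    paste(truthDf$hemisphere, truthDf$region) %in% sozKey
  df$soz_flag <- isSoz
  list(contacts = new("ContactTable", contacts = df),
       truth = new("GroundTruth",
                   sozRegions = soz_regions[, c("hemisphere", "region")],
                   contactRegions = truthDf,
                   trueAffine = diag(4)))
}
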