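#' @include synthetic-surface.R
NULL

#' Destrieux region-to-lobe lookup
#'
#' Returns the bundled lookup mapping the 74 Destrieux cortical regions of
#' each hemisphere to the five cortical lobes (28 frontal, 11 parietal,
#' 14 temporal, 13 occipital, 8 insular).  The atlas itself does not ship
#' a lobe grouping, so the assignment bundled here was authored from
#' standard sulco-gyral anatomy to reproduce those counts; lateral-fissure
#' segments are grouped with the insula and the marginal cingulate sulcus
#' with the frontal lobe.  The non-cortical medial wall can be included as
#' an extra "unclassified" entry.
#'
#' @param include_unclassified if TRUE, append the Medial_wall row
#'   (lobe "unclassified") per hemisphere.
#' @return data.frame with columns `hemisphere` ("lh"/"rh"), `region`,
#'   `lobe`; 74 rows per hemisphere by default.
#' @examples
#' tab <- destrieuxLobeTable()
#' table(tab$lobe[tab$hemisphere == "lh"])
#' @export
destrieuxLobeTable <- function(include_unclassified = FALSE) {
  path <- system.file("extdata", "destrieux_lobes.csv", package = "zmapsoz",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!include_unclassified) tab <- tab[tab$lobe != "unclassified", ]
  out <- rbind(cbind(hemisphere = "lh", tab),
               cbind(hemisphere = "rh", tab))
  rownames(out) <- NULL
  out
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators.  The defaults
#' are the study conditions the rest of the package is exercised under:
#' a 23-subject control cohort, 8% vertex-wise inter-subject variation of
#' the regional metabolic baseline (typical of normalized cortical FDG
#' uptake), and region-aligned hypometabolic lesions of -3 control SDs.
#'
#' @param n_controls control cohort size (>= 2); default 23.
#' @param n_patients number of synthetic patients; default 1.
#' @param control_noise_sd vertex noise SD as a fraction of the regional
#'   baseline mean; default 0.08.
#' @param lesion_effect planted lesion amplitude in multiples of the
#'   control SD; negative for hypometabolism (default -3).
#' @param lesion_regions data.frame(hemisphere, region) of lesioned parcels
#'   or NULL to let generators pick deterministically.
#' @param mesh_subdivisions icosphere subdivision level; default 3
#'   (642 vertices per hemisphere).
#' @param n_regions_per_hemisphere toy parcellation granularity; default 10.
#' @param seed integer master seed; fully determines all generator output.
#' @return validated list of class "SimulationConfig".
#' @export
simulationConfig <- function(n_controls = 23L, n_patients = 1L,
                             control_noise_sd = 0.08, lesion_effect = -3,
                             lesion_regions = NULL, mesh_subdivisions = 3L,
                             n_regions_per_hemisphere = 10L, seed = 1L) {
  stopifnot(n_controls >= 2, n_patients >= 1, control_noise_sd >= 0,
            mesh_subdivisions >= 1, n_regions_per_hemisphere >= 1,
            is.numeric(seed), length(seed) == 1L)
  if (!is.null(lesion_regions))
    stopifnot(is.data.frame(lesion_regions),
              all(c("hemisphere", "region") %in% names(lesion_regions)))
  structure(list(n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 control_noise_sd = control_noise_sd,
                 lesion_effect = lesion_effect,
                 lesion_regions = lesion_regions,
                 mesh_subdivisions = as.integer(mesh_subdivisions),
                 n_regions_per_hemisphere =
                   as.integer(n_regions_per_hemisphere),
                 seed = seed),
            class = "SimulationConfig")
}

# Smooth regional baseline metabolic profile shared by controls and
# patients: a seeded per-region level in [0.9, 1.3], feathered across
# region boundaries by a few neighbor-averaging passes.
regionalBaseline <- function(surface, parcellation, config) {
  key <- paste(parcellation@hemisphere, parcellation@region)
  regions <- sort(unique(key))
  base <- withSeed(childSeed(config$seed, 10L),
                   stats::runif(length(regions), 0.9, 1.3))
  x <- base[match(key, regions)]
  nb <- surfaceEdgeList(surface@faces, nVertices(surface))
  for (k in 1:3) x <- 0.5 * x + 0.5 * neighborMean(x, nb)
  x
}

# Per-vertex control noise SD implied by the config.
controlNoiseSD <- function(surface, parcellation, config) {
  config$control_noise_sd * regionalBaseline(surface, parcellation, config)
}

#' Simulate a healthy-control cohort of vertex metabolic maps
#'
#' Each control map is the smooth regional baseline profile plus
#' vertex-independent Gaussian noise with SD equal to
#' `control_noise_sd * baseline`; values are clamped positive.  The
#' config seed fully determines the cohort.
#'
#' @param surface a [SurfaceModel-class].
#' @param parcellation matching [Parcellation-class].
#' @param config a [simulationConfig()].
#' @return list of `n_controls` [VertexMap-class] objects.
#' @export
simulateControlCohort <- function(surface, parcellation, config) {
  stopifnot(inherits(config, "SimulationConfig"), config$n_controls >= 2)
  n <- nVertices(surface)
  stopifnot(nVertices(parcellation) == n)
  baseline <- regionalBaseline(surface, parcellation, config)
  sdv <- config$control_noise_sd * baseline
  withSeed(childSeed(config$seed, 20L), {
    lapply(seq_len(config$n_controls), function(i) {
      VertexMap(pmax(baseline + stats::rnorm(n, 0, sdv), 1e-6),
                hemisphere = surface@hemisphere, units = "arbitrary")
    })
  })
}

#' Simulate a patient map with planted regional hypometabolism
#'
#' The patient map is a control draw (baseline + noise) with
#' `lesion_effect * control SD` added inside every lesioned parcel, i.e. a
#' region-aligned metabolic deficit expressed in control-SD units.  The
#' returned [GroundTruth-class] records the planted regions.
#'
#' @param surface a [SurfaceModel-class].
#' @param parcellation matching [Parcellation-class].
#' @param soz_regions data.frame(hemisphere, region) of regions to lesion;
#'   these become the planted seizure-onset regions.
#' @param lesion_effect lesion amplitude in control-SD multiples
#'   (negative = hypometabolic).
#' @param config a [simulationConfig()].
#' @param patient_index index used to decorrelate the RNG stream of
#'   successive patients under one config.
#' @return list with elements `map` ([VertexMap-class]) and `truth`
#'   ([GroundTruth-class]).
#' @export
simulatePatient <- function(surface, parcellation, soz_regions,
                            lesion_effect, config, patient_index = 1L) {
  stopifnot(inherits(config, "SimulationConfig"),
            is.data.frame(soz_regions),
            all(c("hemisphere", "region") %in% names(soz_regions)))
  n <- nVertices(surface)
  key <- paste(parcellation@hemisphere, parcellation@region)
  wanted <- paste(soz_regions$hemisphere, soz_regions$region)
  unknown <- setdiff(wanted, unique(key))
  if (length(unknown))
    stop("unknown region label(s): ", paste(unknown, collapse = ", "))
  baseline <- regionalBaseline(surface, parcellation, config)
  sdv <- config$control_noise_sd * baseline
  map <- withSeed(childSeed(config$seed, 30L + patient_index),
                  baseline + stats::rnorm(n, 0, sdv))
  inLesion <- key %in% wanted
  map[inLesion] <- map[inLesion] + lesion_effect * sdv[inLesion]
  list(map = VertexMap(pmax(map, 1e-6), hemisphere = surface@hemisphere,
                       units = "arbitrary"),
       truth = new("GroundTruth",
                   sozRegions = soz_regions[, c("hemisphere", "region")],
                   contactRegions = data.frame(contact_id = character(),
                                               hemisphere = character(),
                                               region = character()),
                   trueAffine = diag(4)))
}
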