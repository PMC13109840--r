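#' @include AllClasses.R
NULL

asMapValues <- function(map) {
  if (is(map, "VertexMap")) map@values
  else if (is(map, "ZMap")) map@z
  else as.numeric(map)
}

#' Global mean normalization of a vertex map
#'
#' Divides the map by its mean over the cortex mask, minimizing
#' inter-subject metabolic scale differences; after normalization the
#' mask mean is exactly 1 and the result is invariant to any positive
#' rescaling of the input.
#'
#' @param map [VertexMap-class] or numeric vector.
#' @param cortex_mask logical vector of usable cortex vertices; defaults
#'   to all non-missing vertices.
#' @return the normalized [VertexMap-class].
#' @export
globalMeanNormalize <- function(map, cortex_mask = NULL) {
  x <- asMapValues(map)
  hemi <- if (is(map, "VertexMap")) map@hemisphere else "both"
  if (is.null(cortex_mask)) cortex_mask <- !is.na(x)
  stopifnot(length(cortex_mask) == length(x))
  if (!any(cortex_mask)) stop("cortex mask is empty")
  m <- mean(x[cortex_mask], na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("non-positive cortex mask mean: ", m)
  VertexMap(x / m, hemisphere = hemi, units = "normalized")
}

#' Build a control template from normalized control maps
#'
#' Computes the per-vertex sample mean and sample standard deviation
#' (n - 1 denominator) over the control cohort.  Vertices whose SD falls
#' below `sd_floor_frac` times the template's mean scale are flagged
#' degenerate (SD set to NA) so Z-scores there are flagged missing rather
#' than infinite.
#'
#' @param control_maps list of [VertexMap-class] objects (or numeric
#'   vectors) of equal length, already normalized identically.
#' @param sd_floor_frac degeneracy floor as a fraction of the mean
#'   template level (default 1e-6).
#' @return A [ControlTemplate-class].
#' @export
buildTemplate <- function(control_maps, sd_floor_frac = 1e-6) {
  if (length(control_maps) < 2)
    stop("need at least 2 control maps, got ", length(control_maps))
  X <- vapply(control_maps, asMapValues,
              numeric(length(asMapValues(control_maps[[1]]))))
  if (is.null(dim(X))) stop("control maps must share a common surface")
  mu <- rowMeans(X)
  sd <- apply(X, 1, stats::sd)
  floorVal <- sd_floor_frac * mean(abs(mu), na.rm = TRUE)
  sd[sd < floorVal] <- NA_real_
  new("ControlTemplate", mean = mu, sd = sd,
      nControls = as.integer(ncol(X)), normalization = "global-mean")
}

#' Vertex-wise Z-scores of a patient map against a control template
#'
#' `Z = (individual value - group mean) / group standard deviation`
#' per vertex.  Vertices with degenerate template SD or missing patient
#' values are flagged missing (NA).
#'
#' @param patient_map [VertexMap-class] or numeric vector, normalized
#'   identically to the controls and on the same surface.
#' @param template a [ControlTemplate-class].
#' @param patient_id identifier carried in the result.
#' @return A [ZMap-class].
#' @export
computeZMap <- function(patient_map, template, patient_id = "patient") {
  x <- asMapValues(patient_map)
  if (length(x) != length(template@mean))
    stop("patient map length ", length(x),
         " does not match template length ", length(template@mean))
  z <- (x - template@mean) / template@sd
  new("ZMap", z = as.numeric(z), nControls = template@nControls,
      patientId = patient_id)
}

#' Select the bottom fraction of Z-scores
#'
#' Selects the `k = max(1, floor(fraction * usable))` vertices with the
#' lowest Z-scores, where `usable` counts non-missing vertices (missing
#' vertices are excluded from numerator and denominator).  Ties at the
#' cutoff break by ascending vertex index, making the selection exactly
#' deterministic.
#'
#' @param zmap a [ZMap-class] (or numeric vector of Z-scores).
#' @param fraction selection fraction in (0, 1]; default 0.005 (the
#'   bottom 0.5% of vertices).
#' @param parcellation optional [Parcellation-class]; when given, the
#'   selected vertices are mapped to (hemisphere, region) entries via
#'   [verticesToRegions()].
#' @return A [HypometabolicSet-class].
#' @export
selectHypometabolic <- function(zmap, fraction = 0.005,
                                parcellation = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  z <- asMapValues(zmap)
  usable <- which(!is.na(z))
  if (!length(usable)) stop("no usable (non-missing) vertices")
  k <- max(1L, floor(fraction * length(usable)))
  ord <- usable[order(z[usable], usable)]
  sel <- sort(ord[seq_len(k)])
  regions <- if (is.null(parcellation)) {
    data.frame(hemisphere = character(), region = character(),
               n_selected_vertices = integer(), min_z = numeric())
  } else {
    verticesToRegions(sel, parcellation, z = z)
  }
  new("HypometabolicSet", vertexIds = as.integer(sel), fraction = fraction,
      regions = regions)
}

#' Map selected vertices to parcellation regions
#'
#' A region is hypometabolic iff at least one selected vertex carries its
#' label (`min_vertices` raises that bar); left and right homologues stay
#' distinct.  Vertices without a label are excluded with a warning.
#'
#' @param vertex_ids integer vertex indices (1-based).
#' @param parcellation a [Parcellation-class].
#' @param z optional Z vector used to report each region's minimum Z.
#' @param min_vertices minimum selected-vertex count per region
#'   (default 1).
#' @return data.frame with columns hemisphere, region,
#'   n_selected_vertices, min_z.
#' @export
verticesToRegions <- function(vertex_ids, parcellation, z = NULL,
                              min_vertices = 1L) {
  stopifnot(is(parcellation, "Parcellation"))
  n <- nVertices(parcellation)
  vertex_ids <- as.integer(vertex_ids)
  if (any(vertex_ids < 1L | vertex_ids > n))
    stop("vertex ids out of range 1..", n)
  if (!length(vertex_ids))
    return(data.frame(hemisphere = character(), region = character(),
                      n_selected_vertices = integer(), min_z = numeric()))
  reg <- parcellation@region[vertex_ids]
  hemi <- parcellation@hemisphere[vertex_ids]
  unlabeled <- is.na(reg) | reg == ""
  if (any(unlabeled)) {
    warning(sum(unlabeled), " selected vertices carry no region label; ",
            "excluded")
    vertex_ids <- vertex_ids[!unlabeled]
    reg <- reg[!unlabeled]; hemi <- hemi[!unlabeled]
  }
  key <- paste(hemi, reg, sep = "\r")
  cnt <- table(key)
  minz <- if (is.null(z)) rep(NA_real_, length(cnt))
  else tapply(z[vertex_ids], key, min)[names(cnt)]
  out <- data.frame(
    hemisphere = sub("\r.*$", "", names(cnt)),
    region = sub("^.*\r", "", names(cnt)),
    n_selected_vertices = as.integer(cnt),
    min_z = as.numeric(minz), stringsAsFactors = FALSE)
  out <- out[out$n_selected_vertices >= min_vertices, , drop = FALSE]
  out <- out[order(out$hemisphere, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Vertices below a free Z threshold (viewer overlay)
#'
#' Returns the vertices with Z strictly below the threshold, mirroring
#' interactive threshold adjustment in surface viewers; lowering the
#' threshold never adds vertices.
#'
#' @param zmap a [ZMap-class] or numeric Z vector.
#' @param z_threshold finite threshold.
#' @return integer vector of vertex indices (1-based).
#' @export
thresholdOverlay <- function(zmap, z_threshold) {
  stopifnot(is.finite(z_threshold) || z_threshold == Inf)
  z <- asMapValues(zmap)
  which(!is.na(z) & z < z_threshold)
}
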