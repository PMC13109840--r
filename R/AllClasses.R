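#' @import methods
NULL

#' VolumeImage: a 3-D scalar grid with a voxel-to-world affine
#'
#' Container for anatomical, PET or integer-label volumes.  World
#' coordinates are RAS millimetres; voxel indices are 0-based and a voxel's
#' world position is the affine image of its integer index (voxel-centre
#' convention).  This convention matters for the majority-voxel contact
#' rule and is used consistently by every resampling and sampling routine.
#'
#' @slot data 3-D numeric array of intensities or integer labels.
#' @slot affine 4x4 voxel-index-to-world-mm matrix (invertible).
#' @slot units "intensity", "label" or "mask"; label volumes refuse
#'   trilinear resampling.
#' @export
setClass("VolumeImage",
  representation(data = "array", affine = "matrix", units = "character"))

setValidity("VolumeImage", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (any(dim(object@data) < 1L))
    msg <- c(msg, "grid dimensions must all be >= 1")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  else if (abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be invertible")
  if (!object@units %in% c("intensity", "label", "mask"))
    msg <- c(msg, "units must be 'intensity', 'label' or 'mask'")
  if (length(msg)) msg else TRUE
})

#' Construct a VolumeImage
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix; default is an identity grid
#'   with 1 mm voxels.
#' @param units "intensity" (default), "label" or "mask".
#' @return A [VolumeImage-class] object.
#' @export
VolumeImage <- function(data, affine = diag(4), units = "intensity") {
  new("VolumeImage", data = data, affine = affine, units = units)
}

#' SurfaceModel: a triangulated cortical surface
#'
#' @slot vertices n x 3 matrix of world-mm vertex positions.
#' @slot faces m x 3 integer matrix of 1-based vertex indices, consistently
#'   oriented with outward normals.
#' @slot normals n x 3 matrix of outward unit normals.
#' @slot thickness per-vertex cortical thickness in mm (positive).
#' @slot hemisphere "lh", "rh" or "both" (for merged cortices).
#' @export
setClass("SurfaceModel",
  representation(vertices = "matrix", faces = "matrix", normals = "matrix",
                 thickness = "numeric", hemisphere = "character"))

setValidity("SurfaceModel", function(object) {
  msg <- character()
  n <- nrow(object@vertices)
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
  if (any(object@faces < 1L) || any(object@faces > n))
    msg <- c(msg, "faces reference invalid vertices")
  if (nrow(object@normals) != n)
    msg <- c(msg, "normals must match vertex count")
  nrm <- sqrt(rowSums(object@normals^2))
  if (any(abs(nrm - 1) > 1e-6))
    msg <- c(msg, "normals must be unit-norm")
  if (length(object@thickness) != n)
    msg <- c(msg, "thickness must match vertex count")
  if (any(object@thickness <= 0))
    msg <- c(msg, "thickness must be positive")
  if (!object@hemisphere %in% c("lh", "rh", "both"))
    msg <- c(msg, "hemisphere must be 'lh', 'rh' or 'both'")
  if (length(msg)) msg else TRUE
})

#' Parcellation: per-vertex region labels with a lobe lookup
#'
#' Region names are hemisphere-agnostic; the per-vertex `hemisphere`
#' vector pairs with them, so a region instance is always the pair
#' (hemisphere, region).
#'
#' @slot region character vector, one region label per vertex.
#' @slot hemisphere character vector ("lh"/"rh"), one per vertex.
#' @slot lobeTable data.frame with columns `region`, `lobe`; lobe is one of
#'   frontal, parietal, temporal, occipital, insular or unclassified.
#' @export
setClass("Parcellation",
  representation(region = "character", hemisphere = "character",
                 lobeTable = "data.frame"))

setValidity("Parcellation", function(object) {
  msg <- character()
  if (length(object@region) != length(object@hemisphere))
    msg <- c(msg, "region and hemisphere must have equal length")
  if (!all(object@hemisphere %in% c("lh", "rh")))
    msg <- c(msg, "per-vertex hemisphere must be 'lh' or 'rh'")
  if (!all(c("region", "lobe") %in% names(object@lobeTable)))
    msg <- c(msg, "lobeTable needs columns 'region' and 'lobe'")
  else {
    lobes <- c("frontal", "parietal", "temporal", "occipital", "insular",
               "unclassified")
    if (!all(object@lobeTable$lobe %in% lobes))
      msg <- c(msg, "unknown lobe name in lobeTable")
    if (!all(unique(object@region) %in% object@lobeTable$region))
      msg <- c(msg, "every vertex region must appear in lobeTable")
  }
  if (length(msg)) msg else TRUE
})

#' VertexMap: one real value per surface vertex
#'
#' Missing values (out-of-field samples, degenerate template vertices) are
#' encoded as NA, never as sentinel numbers.
#'
#' @slot values numeric vector, one per vertex; NA marks missing.
#' @slot hemisphere "lh", "rh" or "both".
#' @slot units free-text unit tag ("suvr", "z", "arbitrary", ...).
#' @export
setClass("VertexMap",
  representation(values = "numeric", hemisphere = "character",
                 units = "character"))

setValidity("VertexMap", function(object) {
  msg <- character()
  if (any(is.infinite(object@values)))
    msg <- c(msg, "values must be finite or NA")
  if (!object@hemisphere %in% c("lh", "rh", "both"))
    msg <- c(msg, "hemisphere must be 'lh', 'rh' or 'both'")
  if (length(msg)) msg else TRUE
})

#' Construct a VertexMap
#' @param values numeric vector of per-vertex values (NA = missing).
#' @param hemisphere "lh", "rh" or "both".
#' @param units unit tag.
#' @return A [VertexMap-class].
#' @export
VertexMap <- function(values, hemisphere = "both", units = "arbitrary") {
  new("VertexMap", values = as.numeric(values), hemisphere = hemisphere,
      units = units)
}

#' ControlTemplate: per-vertex mean and SD of normalized control metabolism
#'
#' @slot mean per-vertex control mean.
#' @slot sd per-vertex control sample standard deviation (n-1 denominator);
#'   vertices whose SD falls below the degeneracy floor are NA-flagged.
#' @slot nControls number of control subjects used.
#' @slot normalization normalization tag carried for provenance
#'   ("global-mean").
#' @export
setClass("ControlTemplate",
  representation(mean = "numeric", sd = "numeric", nControls = "integer",
                 normalization = "character"))

setValidity("ControlTemplate", function(object) {
  msg <- character()
  if (length(object@mean) != length(object@sd))
    msg <- c(msg, "mean and sd must have equal length")
  if (any(object@sd < 0, na.rm = TRUE)) msg <- c(msg, "sd must be >= 0")
  if (object@nControls < 2L) msg <- c(msg, "nControls must be >= 2")
  if (length(msg)) msg else TRUE
})

#' ZMap: vertex-wise Z-scores of a patient against a control template
#'
#' @slot z per-vertex Z-score; NA where the template SD is degenerate or the
#'   patient value is missing.
#' @slot nControls control cohort size behind the template.
#' @slot patientId free-text patient identifier.
#' @export
setClass("ZMap",
  representation(z = "numeric", nControls = "integer",
                 patientId = "character"))

#' HypometabolicSet: the selected bottom-fraction vertices and their regions
#'
#' @slot vertexIds integer indices (1-based) of selected vertices.
#' @slot fraction selection fraction used (default 0.005).
#' @slot regions data.frame with columns hemisphere, region,
#'   n_selected_vertices, min_z.
#' @export
setClass("HypometabolicSet",
  representation(vertexIds = "integer", fraction = "numeric",
                 regions = "data.frame"))

#' ContactTable: SEEG contact geometry and SOZ flags
#'
#' Each row is one cylindrical contact: centre (mm, world RAS), unit axis,
#' diameter 0.8 mm and length 2 mm by default, plus the SEEG seizure-onset
#' flag.
#'
#' @slot contacts data.frame with columns contact_id, electrode, x, y, z,
#'   axis_x, axis_y, axis_z, diameter, length, soz_flag.
#' @export
setClass("ContactTable", representation(contacts = "data.frame"))

setValidity("ContactTable", function(object) {
  need <- c("contact_id", "electrode", "x", "y", "z",
            "axis_x", "axis_y", "axis_z", "diameter", "length", "soz_flag")
  df <- object@contacts
  msg <- character()
  miss <- setdiff(need, names(df))
  if (length(miss))
    msg <- c(msg, paste("missing columns:", paste(miss, collapse = ", ")))
  else if (nrow(df)) {
    if (anyDuplicated(df$contact_id))
      msg <- c(msg, "duplicate contact ids")
    nrm <- sqrt(df$axis_x^2 + df$axis_y^2 + df$axis_z^2)
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "axis vectors must be unit-norm")
    if (any(df$diameter <= 0) || any(df$length <= 0))
      msg <- c(msg, "diameter and length must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruth: the planted truth behind a synthetic dataset
#'
#' @slot sozRegions data.frame(hemisphere, region) of planted seizure-onset
#'   regions.
#' @slot contactRegions data.frame(contact_id, hemisphere, region) of true
#'   contact region assignments (region NA when none).
#' @slot trueAffine 4x4 matrix used to misalign phantom volumes.
#' @export
setClass("GroundTruth",
  representation(sozRegions = "data.frame", contactRegions = "data.frame",
                 trueAffine = "matrix"))

#' AffineTransform: a 12-parameter affine in a fixed composition order
#'
#' Parameters are (tx, ty, tz) mm, (rx, ry, rz) rad, (sx, sy, sz) scales and
#' (hxy, hxz, hyz) shears.  The matrix is composed as
#' `T %*% Rz %*% Ry %*% Rx %*% Shear %*% Scale` and maps points in the
#' fixed/target world frame to the moving/source world frame.
#'
#' @slot parameters named numeric vector of length 12.
#' @slot matrix the composed 4x4 matrix.
#' @slot dof degrees of freedom actually estimated (6 or 12).
#' @export
setClass("AffineTransform",
  representation(parameters = "numeric", matrix = "matrix", dof = "integer"))

#' RegistrationReport: quality-control outcome of an affine registration
#'
#' @slot finalNCC normalized cross-correlation after alignment, in [-1, 1].
#' @slot passedGate TRUE iff finalNCC exceeds the acceptance gate (0.85).
#' @slot iterations total objective evaluations spent by the optimizer.
#' @slot gate the gate threshold that was applied.
#' @export
setClass("RegistrationReport",
  representation(finalNCC = "numeric", passedGate = "logical",
                 iterations = "integer", gate = "numeric"))

setValidity("RegistrationReport", function(object) {
  if (xor(object@passedGate, object@finalNCC > object@gate))
    "passedGate must equal (finalNCC > gate)" else TRUE
})

#' ContactAssignment: outcome of the majority-voxel gray-matter rule
#'
#' @slot contactId the contact identifier.
#' @slot region assigned region name, or NA when unverified.
#' @slot hemisphere hemisphere of the assigned region, or NA.
#' @slot voxelCounts named numeric vector of (possibly fractional) voxel
#'   counts per overlapped label.
#' @slot majorityFraction largest single-region share of the footprint.
#' @slot verified TRUE iff majorityFraction > 0.5 and the majority label is
#'   a gray-matter region.
#' @export
setClass("ContactAssignment",
  representation(contactId = "character", region = "character",
                 hemisphere = "character", voxelCounts = "numeric",
                 majorityFraction = "numeric", verified = "logical"))

#' ConcordanceResult: stratified 2x2 counts and the six derived metrics
#'
#' @slot metrics data.frame with one row per stratum and columns Category,
#'   N, TP, FP, FN, TN, TPR, TNR, PPV, NPV, ACC, Kappa, reported.
#'   Undefined metrics (zero denominators) are NA, never coerced to 0;
#'   strata under the reporting floor carry reported = FALSE.
#' @slot floor the minimum instance count for numeric reporting.
#' @export
setClass("ConcordanceResult",
  representation(metrics = "data.frame", floor = "numeric"))
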