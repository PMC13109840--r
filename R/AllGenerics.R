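#' @include AllClasses.R
NULL

#' Number of vertices of a surface-indexed object
#' @param x a SurfaceModel, VertexMap, Parcellation, ControlTemplate or ZMap.
#' @return integer vertex count.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' Per-vertex values of a vertex-indexed object
#' @param x a VertexMap, ControlTemplate (mean) or ZMap (z).
#' @return numeric vector, NA marking missing entries.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Hemisphere tag of an object
#' @param x a SurfaceModel or VertexMap.
#' @return "lh", "rh" or "both".
#' @export
setGeneric("hemisphere", function(x) standardGeneric("hemisphere"))

#' @describeIn nVertices vertex count of a surface
#' @export
setMethod("nVertices", "SurfaceModel", function(x) nrow(x@vertices))
#' @describeIn nVertices length of a vertex map
#' @export
setMethod("nVertices", "VertexMap", function(x) length(x@values))
#' @describeIn nVertices number of labelled vertices
#' @export
setMethod("nVertices", "Parcellation", function(x) length(x@region))
#' @describeIn nVertices template length
#' @export
setMethod("nVertices", "ControlTemplate", function(x) length(x@mean))
#' @describeIn nVertices Z-map length
#' @export
setMethod("nVertices", "ZMap", function(x) length(x@z))

#' @describeIn mapValues values of a VertexMap
#' @export
setMethod("mapValues", "VertexMap", function(x) x@values)
#' @describeIn mapValues Z-scores of a ZMap
#' @export
setMethod("mapValues", "ZMap", function(x) x@z)

#' @describeIn hemisphere hemisphere of a surface
#' @export
setMethod("hemisphere", "SurfaceModel", function(x) x@hemisphere)
#' @describeIn hemisphere hemisphere of a vertex map
#' @export
setMethod("hemisphere", "VertexMap", function(x) x@hemisphere)

#' Accessors for VolumeImage
#'
#' `volData` returns the raw 3-D array, `volAffine` the 4x4 voxel-to-world
#' matrix and `voxelSize` the per-axis voxel edge lengths in mm (column
#' norms of the linear part).
#'
#' @param x a [VolumeImage-class].
#' @return array, matrix or length-3 numeric respectively.
#' @export
volData <- function(x) x@data

#' @rdname volData
#' @export
volAffine <- function(x) x@affine

#' @rdname volData
#' @export
voxelSize <- function(x) {
  A <- x@affine[1:3, 1:3, drop = FALSE]
  sqrt(colSums(A^2))
}

#' Surface accessors
#'
#' @param x a [SurfaceModel-class].
#' @return vertex matrix, face index matrix, normal matrix or thickness
#'   vector.
#' @export
surfaceVertices <- function(x) x@vertices

#' @rdname surfaceVertices
#' @export
surfaceFaces <- function(x) x@faces

#' @rdname surfaceVertices
#' @export
vertexNormals <- function(x) x@normals

#' @rdname surfaceVertices
#' @export
vertexThickness <- function(x) x@thickness

#' Parcellation accessors
#'
#' `vertexRegions` returns the per-vertex region labels,
#' `vertexHemispheres` the per-vertex hemisphere tags and `lobeLookup` the
#' region-to-lobe table.
#'
#' @param x a [Parcellation-class].
#' @return character vector or data.frame.
#' @export
vertexRegions <- function(x) x@region

#' @rdname vertexRegions
#' @export
vertexHemispheres <- function(x) x@hemisphere

#' @rdname vertexRegions
#' @export
lobeLookup <- function(x) x@lobeTable

#' ControlTemplate accessors
#' @param x a [ControlTemplate-class].
#' @return numeric vector (mean/sd) or integer count.
#' @export
templateMean <- function(x) x@mean

#' @rdname templateMean
#' @export
templateSD <- function(x) x@sd

#' @rdname templateMean
#' @export
nControls <- function(x) x@nControls

#' Contact-table accessor
#' @param x a [ContactTable-class].
#' @return the underlying data.frame, one row per contact.
#' @export
contacts <- function(x) x@contacts

#' Concordance accessors
#' @param x a [ConcordanceResult-class].
#' @return the stratified metrics data.frame.
#' @export
concordanceMetrics <- function(x) x@metrics

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  vs <- voxelSize(object)
  cat(sprintf("VolumeImage: %d x %d x %d voxels, voxel size %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "SurfaceModel", function(object) {
  cat(sprintf("SurfaceModel (%s): %d vertices, %d faces\n",
              object@hemisphere, nrow(object@vertices), nrow(object@faces)))
  cat(sprintf("  thickness %.2f-%.2f mm\n",
              min(object@thickness), max(object@thickness)))
})

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d vertices, %d regions, %d lobe entries\n",
              length(object@region),
              length(unique(paste(object@hemisphere, object@region))),
              nrow(object@lobeTable)))
})

setMethod("show", "VertexMap", function(object) {
  v <- object@values
  cat(sprintf("VertexMap (%s, %s): %d vertices, %d missing, range [%.4g, %.4g]\n",
              object@hemisphere, object@units, length(v), sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
})

setMethod("show", "ControlTemplate", function(object) {
  cat(sprintf("ControlTemplate: %d vertices from %d controls (%s normalized)\n",
              length(object@mean), object@nControls, object@normalization))
})

setMethod("show", "ZMap", function(object) {
  cat(sprintf("ZMap for '%s': %d vertices (template n = %d), min Z = %.2f\n",
              object@patientId, length(object@z), object@nControls,
              suppressWarnings(min(object@z, na.rm = TRUE))))
})

setMethod("show", "HypometabolicSet", function(object) {
  cat(sprintf("HypometabolicSet: %d vertices (fraction %.4g) in %d regions\n",
              length(object@vertexIds), object@fraction,
              nrow(object@regions)))
})

setMethod("show", "ContactTable", function(object) {
  df <- object@contacts
  cat(sprintf("ContactTable: %d contacts on %d electrodes, %d SOZ-flagged\n",
              nrow(df), length(unique(df$electrode)), sum(df$soz_flag)))
})

setMethod("show", "AffineTransform", function(object) {
  cat(sprintf("AffineTransform (%d dof): t = (%.2f, %.2f, %.2f) mm\n",
              object@dof, object@parameters[1], object@parameters[2],
              object@parameters[3]))
})

setMethod("show", "RegistrationReport", function(object) {
  cat(sprintf("RegistrationReport: NCC = %.4f (gate %.2f, %s), %d evaluations\n",
              object@finalNCC, object@gate,
              if (object@passedGate) "passed" else "FAILED",
              object@iterations))
})

setMethod("show", "ContactAssignment", function(object) {
  cat(sprintf("ContactAssignment '%s': %s (fraction %.2f, %s)\n",
              object@contactId,
              if (is.na(object@region)) "unassigned"
              else paste(object@hemisphere, object@region),
              object@majorityFraction,
              if (object@verified) "verified" else "not verified"))
})

setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf("ConcordanceResult: %d strata (reporting floor %d)\n",
              nrow(object@metrics), as.integer(object@floor)))
  print(object@metrics, row.names = FALSE)
})
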