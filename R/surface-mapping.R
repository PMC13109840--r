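#' @include synthetic-surface.R volume-preproc.R
NULL

#' Sample a volume onto a surface at a cortical depth fraction
#'
#' For each vertex the sample point is
#' `vertex + depth_fraction * thickness * (-normal)`, i.e. the default
#' `depth_fraction = 0.5` samples at 50% cortical depth along the inward
#' surface normal (normals point outward; the cortex lies inward of the
#' pial-like surface).  Values are trilinearly interpolated, so sampling
#' is linear in the volume and exact on linear intensity fields.
#' Out-of-field vertices are flagged missing (NA).
#'
#' @param volume a [VolumeImage-class].
#' @param surface a [SurfaceModel-class] lying inside the volume's field
#'   of view.
#' @param depth_fraction depth along the inward normal as a fraction of
#'   local thickness (0 samples at the vertices themselves).
#' @param max_missing error if more than this fraction of vertices falls
#'   outside the volume (default 0.10), indicating a geometry mismatch.
#' @return A [VertexMap-class] with NA at out-of-field vertices.
#' @export
sampleAtDepth <- function(volume, surface, depth_fraction = 0.5,
                          max_missing = 0.10) {
  stopifnot(is(volume, "VolumeImage"), is(surface, "SurfaceModel"))
  pts <- surface@vertices -
    depth_fraction * surface@thickness * surface@normals
  vals <- sampleVolumeAtWorld(volume, pts, mode = "trilinear", outside = NA)
  fracMissing <- mean(is.na(vals))
  if (fracMissing > max_missing)
    stop(sprintf(paste0("%.1f%% of vertices fall outside the volume ",
                        "field of view (limit %.1f%%): geometry mismatch"),
                 100 * fracMissing, 100 * max_missing))
  VertexMap(vals, hemisphere = surface@hemisphere, units = "intensity")
}

#' Smooth a vertex map with an approximate geodesic Gaussian kernel
#'
#' Iterated lumped-mass graph diffusion,
#' `x <- x + dt * (A x - d x) / m`, with `A` the vertex adjacency, `d`
#' the vertex degree and `m` the Voronoi-style vertex area (one third of
#' incident triangle areas).  Because the uniform graph Laplacian is
#' symmetric, the surface-area-weighted mean of the map is conserved
#' exactly on closed NA-free meshes.  The step `dt = lambda *
#' min(m_i/d_i)` keeps the iteration stable, and the iteration count
#' follows the diffusion relation: each pass adds kernel variance of
#' about `lambda_eff * hbar^2 / 2` per tangent direction (hbar = mean
#' edge length, `lambda_eff = dt * mean(d/m)`), so
#' `n_iter = round(sigma^2 / (lambda_eff * hbar^2 / 2))` with
#' `sigma = fwhm / 2.3548`.  Constant maps are exact fixed points;
#' missing (NA) vertices stay missing and are excluded from the
#' averages.
#'
#' @param surface a [SurfaceModel-class].
#' @param map [VertexMap-class] or numeric vector on the surface.
#' @param fwhm_mm target kernel FWHM in mm (>= 0; 0 returns the input).
#' @param lambda stability fraction of the maximal diffusion step, in
#'   (0, 1]; default 0.5.
#' @return the smoothed [VertexMap-class].
#' @export
smoothSurfaceMap <- function(surface, map, fwhm_mm = 20.0, lambda = 0.5) {
  stopifnot(is(surface, "SurfaceModel"), fwhm_mm >= 0,
            lambda > 0, lambda <= 1)
  x <- if (is(map, "VertexMap")) map@values else as.numeric(map)
  stopifnot(length(x) == nVertices(surface))
  units <- if (is(map, "VertexMap")) map@units else "arbitrary"
  if (fwhm_mm == 0)
    return(VertexMap(x, hemisphere = surface@hemisphere, units = units))
  e <- surfaceEdges(surface)
  v <- surface@vertices
  hbar <- mean(sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2)))
  sigma <- fwhmToSigma(fwhm_mm)
  nb <- surfaceEdgeList(surface@faces, nVertices(surface))
  m <- vertexAreas(surface)
  dt <- lambda * min(m / nb$deg)
  lambdaEff <- dt * mean(nb$deg / m)
  nIter <- max(1L, round(sigma^2 / (lambdaEff * hbar^2 / 2)))
  missing <- is.na(x)
  for (k in seq_len(nIter)) {
    xi <- ifelse(is.na(x), 0, x)
    wi <- as.numeric(!is.na(x))
    Ax <- as.numeric(rowsum(xi[nb$to], nb$from, reorder = TRUE))
    dEff <- as.numeric(rowsum(wi[nb$to], nb$from, reorder = TRUE))
    x <- x + dt * (Ax - dEff * x) / m
    x[missing] <- NA_real_
  }
  VertexMap(x, hemisphere = surface@hemisphere, units = units)
}

#' Project a subject vertex map to a template surface
#'
#' The correspondence maps every template vertex to a subject vertex
#' index; the identity correspondence returns the input unchanged.
#' Spherical registration producing real correspondences is outside this
#' package's scope — the correspondence is an explicit input (identity in
#' the synthetic pipeline).
#'
#' @param map [VertexMap-class] or numeric vector in subject space.
#' @param correspondence integer vector, one subject vertex index (1-based)
#'   per template vertex; must be complete (no NA) and in range.
#' @return the template-space [VertexMap-class].
#' @export
projectToTemplate <- function(map, correspondence) {
  x <- if (is(map, "VertexMap")) map@values else as.numeric(map)
  hemi <- if (is(map, "VertexMap")) map@hemisphere else "both"
  units <- if (is(map, "VertexMap")) map@units else "arbitrary"
  if (anyNA(correspondence))
    stop("correspondence is incomplete: NA entries present")
  correspondence <- as.integer(correspondence)
  if (any(correspondence < 1L) || any(correspondence > length(x)))
    stop("correspondence references subject vertices out of range 1..",
         length(x))
  VertexMap(x[correspondence], hemisphere = hemi, units = units)
}
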