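#' @include AllClasses.R
NULL

# Unit icosahedron with consistently outward-oriented faces.
icosahedronMesh <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  # enforce outward winding (valid test for a convex solid about the origin)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
    nrm <- crossProduct(b - a, c3 - a)
    if (sum(nrm * (a + b + c3)) < 0) f[i, ] <- f[i, c(1, 3, 2)]
  }
  list(v = v, f = f)
}

crossProduct <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# One 4:1 triangle subdivision step with midpoint re-projection onto the
# unit sphere.  Midpoints are deduplicated per undirected edge so the
# result stays a closed manifold.
subdivideSphereMesh <- function(v, f) {
  m <- nrow(f)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  key <- paste(lo, hi)
  first <- !duplicated(key)
  idx <- match(key, key[first])
  mid <- (v[lo[first], , drop = FALSE] + v[hi[first], , drop = FALSE]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  nv0 <- nrow(v)
  newIdx <- nv0 + idx
  ab <- newIdx[seq_len(m)]
  bc <- newIdx[m + seq_len(m)]
  ac <- newIdx[2 * m + seq_len(m)]
  a <- f[, 1]; b <- f[, 2]; c3 <- f[, 3]
  newf <- rbind(cbind(a, ab, ac), cbind(ab, b, bc),
                cbind(ac, bc, c3), cbind(ab, bc, ac))
  list(v = rbind(v, mid), f = unname(newf))
}

# Fraction of the normalized ellipsoid radius occupied by the gray
# ribbon; shared between the toy surfaces and the phantom volume scene so
# that 50%-depth sampling lands mid-ribbon.
toyRibbonFraction <- 0.08

#' Generate a toy cortical hemisphere surface
#'
#' Builds a closed, consistently oriented triangle mesh by icosahedral
#' subdivision of the unit sphere (vertex count `10 * 4^n + 2`), deformed
#' to a hemisphere-sized ellipsoid and offset laterally, with analytic
#' outward unit normals and a per-vertex cortical thickness in
#' [1.5, 4.5] mm.  The thickness is the local geometric depth of the
#' phantom gray ribbon (the shell between 92% and 100% of the normalized
#' ellipsoid radius) plus a small smooth seeded perturbation, so
#' mid-depth sampling of phantom volumes lands inside the ribbon.  A
#' stand-in for reconstructed pial surfaces so the surface pipeline runs
#' at desk scale.
#'
#' @param mesh_subdivisions number of 4:1 subdivision steps (>= 1).
#' @param seed integer; fully determines the thickness field.
#' @param hemisphere "lh" or "rh" (controls the lateral offset sign).
#' @param radii ellipsoid semi-axes (x, y, z) in mm.
#' @param center ellipsoid centre in world mm; default places the
#'   hemisphere at x = -30 (lh) or +30 (rh).
#' @return A [SurfaceModel-class].
#' @examples
#' s <- makeToySurface(2, seed = 1)
#' nVertices(s)  # 162
#' @export
makeToySurface <- function(mesh_subdivisions, seed, hemisphere = "lh",
                           radii = c(28, 65, 50), center = NULL) {
  stopifnot(mesh_subdivisions >= 1, length(radii) == 3, all(radii > 0))
  if (is.null(center))
    center <- c(if (hemisphere == "lh") -30 else 30, 0, 0)
  mesh <- icosahedronMesh()
  for (i in seq_len(mesh_subdivisions))
    mesh <- subdivideSphereMesh(mesh$v, mesh$f)
  u <- mesh$v                                   # unit-sphere coordinates
  vertices <- sweep(u, 2, radii, `*`)
  vertices <- sweep(vertices, 2, center, `+`)
  # ellipsoid normal: gradient of sum((x_i/r_i)^2), expressed via u
  normals <- sweep(u, 2, radii, `/`)
  normals <- normals / sqrt(rowSums(normals^2))
  n <- nrow(vertices)
  # ribbon depth along the normal: fraction / |grad rho| at the surface
  gradRho <- sweep(u, 2, radii, `/`)
  geomThick <- toyRibbonFraction / sqrt(rowSums(gradRho^2))
  jitter <- withSeed(childSeed(seed, 1L), {
    raw <- stats::runif(n, -1, 1)
    nb <- surfaceEdgeList(mesh$f, n)
    for (k in 1:10) raw <- neighborMean(raw, nb)
    raw
  })
  thickness <- pmin(pmax(geomThick + 0.5 * jitter, 1.5), 4.5)
  new("SurfaceModel", vertices = vertices, faces = mesh$f,
      normals = normals, thickness = thickness, hemisphere = hemisphere)
}

# Directed edge list (both directions) as a 2-column matrix, plus degree,
# cached-friendly representation for vectorized neighbor averaging.
surfaceEdgeList <- function(faces, n) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  e <- rbind(e, e[, c(2, 1)])
  key <- (e[, 1] - 1) * n + e[, 2]
  e <- e[!duplicated(key), , drop = FALSE]
  deg <- tabulate(e[, 1], nbins = n)
  list(from = e[, 1], to = e[, 2], deg = deg, n = n)
}

neighborMean <- function(x, nb) {
  s <- rowsum(x[nb$to], nb$from, reorder = TRUE)
  as.numeric(s) / nb$deg
}

#' Undirected edge matrix of a surface
#' @param surface a [SurfaceModel-class].
#' @return 2-column integer matrix, one row per undirected edge.
#' @export
surfaceEdges <- function(surface) {
  f <- surface@faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  unique(cbind(lo, hi))
}

# Per-vertex area: one third of the incident triangle areas.
vertexAreas <- function(surface) {
  v <- surface@vertices; f <- surface@faces
  ab <- v[f[, 2], ] - v[f[, 1], ]
  ac <- v[f[, 3], ] - v[f[, 1], ]
  cx <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  fa <- 0.5 * sqrt(rowSums(cx^2))
  a <- numeric(nrow(v))
  for (j in 1:3) {
    s <- rowsum(fa, f[, j], reorder = FALSE)
    a[as.integer(rownames(s))] <- a[as.integer(rownames(s))] + s / 3
  }
  a
}

#' Partition a surface into edge-connected regions
#'
#' Seeds `n_regions` vertices by farthest-point sampling (deterministic
#' given `seed`) and grows them breadth-first over mesh edges, so every
#' region is an edge-connected patch and the regions partition the vertex
#' set.  A region-to-lobe map over the five cortical lobes is attached,
#' cycling through frontal, parietal, temporal, occipital and insular in
#' region order.
#'
#' @param surface a [SurfaceModel-class] for one hemisphere.
#' @param n_regions number of regions (<= vertex count).
#' @param seed integer seed for the starting vertex.
#' @return A [Parcellation-class].
#' @export
makeParcellation <- function(surface, n_regions, seed) {
  n <- nVertices(surface)
  stopifnot(n_regions >= 1, n_regions <= n)
  if (surface@hemisphere == "both")
    stop("parcellate each hemisphere separately, then mergeParcellations()")
  v <- surface@vertices
  start <- withSeed(childSeed(seed, 2L), sample.int(n, 1L))
  seeds <- integer(n_regions)
  seeds[1] <- start
  d <- sqrt(rowSums(sweep(v, 2, v[start, ], `-`)^2))
  if (n_regions > 1) {
    for (i in 2:n_regions) {
      seeds[i] <- which.max(d)
      di <- sqrt(rowSums(sweep(v, 2, v[seeds[i], ], `-`)^2))
      d <- pmin(d, di)
    }
  }
  nb <- surfaceEdgeList(surface@faces, n)
  lab <- integer(n)                    # 0 = unassigned
  lab[seeds] <- seq_len(n_regions)
  repeat {
    grow <- lab[nb$from] > 0L & lab[nb$to] == 0L
    if (!any(grow)) break
    fromLab <- lab[nb$from[grow]]
    toIdx <- nb$to[grow]
    ord <- order(toIdx, fromLab)       # deterministic tie-break
    toIdx <- toIdx[ord]; fromLab <- fromLab[ord]
    keep <- !duplicated(toIdx)
    lab[toIdx[keep]] <- fromLab[keep]
  }
  if (any(lab == 0L))
    stop("region growing could not cover all vertices ",
         "(disconnected surface?)")
  regionNames <- sprintf("region_%02d", seq_len(n_regions))
  lobes <- rep(c("frontal", "parietal", "temporal", "occipital", "insular"),
               length.out = n_regions)
  new("Parcellation",
      region = regionNames[lab],
      hemisphere = rep(surface@hemisphere, n),
      lobeTable = data.frame(region = regionNames, lobe = lobes,
                             stringsAsFactors = FALSE))
}

#' Merge two hemisphere surfaces into one cortex
#'
#' Concatenates vertices, faces (re-indexed), normals and thickness.  The
#' left hemisphere occupies vertex indices 1..nL, the right hemisphere the
#' remainder; vertex maps and parcellations merged with
#' [mergeParcellations()] follow the same ordering.
#'
#' @param lh,rh left/right [SurfaceModel-class] objects.
#' @return A merged [SurfaceModel-class] with hemisphere "both".
#' @export
mergeHemispheres <- function(lh, rh) {
  stopifnot(lh@hemisphere == "lh", rh@hemisphere == "rh")
  nL <- nVertices(lh)
  new("SurfaceModel",
      vertices = rbind(lh@vertices, rh@vertices),
      faces = rbind(lh@faces, rh@faces + nL),
      normals = rbind(lh@normals, rh@normals),
      thickness = c(lh@thickness, rh@thickness),
      hemisphere = "both")
}

#' @rdname mergeHemispheres
#' @param pl,pr left/right [Parcellation-class] objects (their lobe tables
#'   must agree on shared region names).
#' @export
mergeParcellations <- function(pl, pr) {
  lt <- unique(rbind(pl@lobeTable, pr@lobeTable))
  if (anyDuplicated(lt$region))
    stop("conflicting lobe assignments between hemispheres")
  new("Parcellation",
      region = c(pl@region, pr@region),
      hemisphere = c(pl@hemisphere, pr@hemisphere),
      lobeTable = lt)
}
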