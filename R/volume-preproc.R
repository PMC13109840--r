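#' @include AllClasses.R
NULL

# 1-D discrete Gaussian convolution matrix (n x n), kernel truncated at
# 4 sigma and normalized to unit sum, zero-padded at the boundaries so
# interior mass is conserved exactly.
gaussianConvMatrix <- function(n, sigmaVox) {
  if (sigmaVox < 1e-3) return(diag(n))
  r <- max(1L, ceiling(4 * sigmaVox))
  g <- exp(-(seq(-r, r))^2 / (2 * sigmaVox^2))
  g <- g / sum(g)
  K <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + g[o + r + 1]
  }
  K
}

applyAlongAxis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(arr, perm)
  m <- K %*% matrix(ap, nrow = d[axis])
  ap <- array(m, dim = d[perm])
  aperm(ap, order(perm))
}

#' Separable 3-D Gaussian smoothing in world millimetres
#'
#' The kernel width is specified in mm and scaled per axis by the voxel
#' size, so anisotropic grids are smoothed isotropically in world space.
#' The discrete kernel is normalized, so total intensity is conserved away
#' from the volume boundaries.
#'
#' @param volume a [VolumeImage-class].
#' @param fwhm_mm kernel full width at half maximum in mm (>= 0; 0 is the
#'   identity).  Exactly one of `fwhm_mm`/`sigma_mm` must be given.
#' @param sigma_mm alternatively the Gaussian SD in mm
#'   (sigma = FWHM / 2.3548).
#' @return the smoothed [VolumeImage-class].
#' @export
gaussianSmoothVolume <- function(volume, fwhm_mm = NULL, sigma_mm = NULL) {
  stopifnot(is(volume, "VolumeImage"))
  if (is.null(sigma_mm) == is.null(fwhm_mm))
    stop("give exactly one of fwhm_mm or sigma_mm")
  if (is.null(sigma_mm)) {
    stopifnot(fwhm_mm >= 0)
    sigma_mm <- fwhmToSigma(fwhm_mm)
  }
  stopifnot(sigma_mm >= 0)
  if (sigma_mm == 0) return(volume)
  vs <- voxelSize(volume)
  out <- volume@data
  for (axis in 1:3) {
    K <- gaussianConvMatrix(dim(out)[axis], sigma_mm / vs[axis])
    out <- applyAlongAxis(out, K, axis)
  }
  VolumeImage(out, volume@affine, volume@units)
}

# --- connected components -------------------------------------------------

# Vectorized 6-connected flood fill over a logical 3-D array, returning an
# integer component label array (0 = background).
connectedComponents3D <- function(mask) {
  d <- dim(mask)
  n1 <- d[1]; n12 <- d[1] * d[2]
  labels <- integer(length(mask))
  remaining <- which(mask)
  comp <- 0L
  while (length(remaining)) {
    comp <- comp + 1L
    front <- remaining[1L]
    labels[front] <- comp
    while (length(front)) {
      i <- ((front - 1L) %% n1) + 1L
      j <- (((front - 1L) %/% n1) %% d[2]) + 1L
      k <- ((front - 1L) %/% n12) + 1L
      cand <- c(front[i > 1L] - 1L, front[i < n1] + 1L,
                front[j > 1L] - n1, front[j < d[2]] + n1,
                front[k > 1L] - n12, front[k < d[3]] + n12)
      cand <- unique(cand)
      cand <- cand[mask[cand] & labels[cand] == 0L]
      labels[cand] <- comp
      front <- cand
    }
    remaining <- remaining[labels[remaining] == 0L]
  }
  array(labels, dim = d)
}

#' Adaptive-threshold brain mask
#'
#' Smooths the anatomical volume with a Gaussian (sigma 2 mm), thresholds
#' at `intensity_coefficient` times the robust maximum (99th percentile of
#' the smoothed intensities), keeps the largest 6-connected component and
#' fills interior holes.
#'
#' @param anatomical a [VolumeImage-class]; must not be constant.
#' @param intensity_coefficient threshold coefficient (default 0.4).
#' @param sigma_mm smoothing SD in mm (default 2).
#' @return binary [VolumeImage-class] (units "mask").
#' @export
brainMask <- function(anatomical, intensity_coefficient = 0.4,
                      sigma_mm = 2.0) {
  stopifnot(is(anatomical, "VolumeImage"))
  x <- anatomical@data
  if (diff(range(x)) < 1e-12)
    stop("cannot mask a constant volume: no threshold definable")
  sm <- gaussianSmoothVolume(anatomical, sigma_mm = sigma_mm)@data
  thr <- intensity_coefficient * stats::quantile(sm, 0.99, names = FALSE)
  fg <- sm > thr
  if (!any(fg))
    return(VolumeImage(array(0, dim(x)), anatomical@affine, "mask"))
  comps <- connectedComponents3D(fg)
  largest <- which.max(tabulate(comps[comps > 0L]))
  mask <- comps == largest
  # fill holes: background components not touching the volume border
  bgComps <- connectedComponents3D(!mask)
  d <- dim(mask)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- unique(bgComps[border & bgComps > 0L])
  holes <- bgComps > 0L & !(bgComps %in% outside)
  mask[holes] <- TRUE
  VolumeImage(array(as.numeric(mask), d), anatomical@affine, "mask")
}

#' Normalized cross-correlation of two volumes
#'
#' Pearson correlation of the (optionally masked) intensities; symmetric
#' and invariant to affine intensity rescaling of either argument.
#'
#' @param a,b [VolumeImage-class] objects of equal dimensions.
#' @param mask optional [VolumeImage-class] or logical array selecting the
#'   voxels to correlate (>= 2 voxels, nonzero variance in both images).
#' @return NCC in [-1, 1].
#' @export
ncc <- function(a, b, mask = NULL) {
  stopifnot(is(a, "VolumeImage"), is(b, "VolumeImage"),
            all(dim(a@data) == dim(b@data)))
  va <- as.numeric(a@data); vb <- as.numeric(b@data)
  if (!is.null(mask)) {
    m <- if (is(mask, "VolumeImage")) mask@data > 0 else mask > 0
    stopifnot(all(dim(m) == dim(a@data)))
    va <- va[m]; vb <- vb[m]
  }
  if (length(va) < 2) stop("NCC needs at least 2 voxels")
  if (stats::sd(va) < 1e-12 || stats::sd(vb) < 1e-12)
    stop("NCC undefined: zero variance under the mask")
  stats::cor(va, vb)
}

# --- affine transforms ----------------------------------------------------

#' Construct a 12-parameter affine transform
#'
#' Composition order is fixed as `T %*% Rz %*% Ry %*% Rx %*% Shear %*%
#' Scale`; the transform maps points of the fixed/target world frame into
#' the moving/source world frame (the convention [resampleAffine()] uses).
#'
#' @param translation length-3 translation (mm).
#' @param rotation length-3 rotation about x, y, z (radians).
#' @param scale length-3 axis scales.
#' @param shear length-3 shears (xy, xz, yz).
#' @param dof degrees of freedom tag (6 or 12).
#' @return An [AffineTransform-class].
#' @export
affineTransform <- function(translation = c(0, 0, 0),
                            rotation = c(0, 0, 0),
                            scale = c(1, 1, 1),
                            shear = c(0, 0, 0), dof = 12L) {
  p <- c(translation, rotation, scale, shear)
  names(p) <- c("tx", "ty", "tz", "rx", "ry", "rz",
                "sx", "sy", "sz", "hxy", "hxz", "hyz")
  new("AffineTransform", parameters = p, matrix = affineParamsToMatrix(p),
      dof = as.integer(dof))
}

affineParamsToMatrix <- function(p) {
  T4 <- diag(4); T4[1:3, 4] <- p[1:3]
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- diag(4); Rx[2:3, 2:3] <- matrix(c(cx, sx, -sx, cx), 2)
  Ry <- diag(4); Ry[c(1, 3), c(1, 3)] <- matrix(c(cy, -sy, sy, cy), 2)
  Rz <- diag(4); Rz[1:2, 1:2] <- matrix(c(cz, sz, -sz, cz), 2)
  H <- diag(4); H[1, 2] <- p[10]; H[1, 3] <- p[11]; H[2, 3] <- p[12]
  S <- diag(c(p[7:9], 1))
  T4 %*% Rz %*% Ry %*% Rx %*% H %*% S
}

# --- resampling -----------------------------------------------------------

# Trilinear interpolation of `data` at fractional 0-based voxel coords
# (N x 3).  Exact on linear fields; `outside` fills out-of-field points.
trilinearAtVoxels <- function(data, vox, outside = 0) {
  d <- dim(data)
  x <- vox[, 1]; y <- vox[, 2]; z <- vox[, 3]
  inside <- x >= 0 & y >= 0 & z >= 0 &
    x <= d[1] - 1 & y <= d[2] - 1 & z <= d[3] - 1
  out <- rep(as.numeric(outside), length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1] - 2); fx <- x - x0
  y0 <- pmin(floor(y), d[2] - 2); fy <- y - y0
  z0 <- pmin(floor(z), d[3] - 2); fz <- z - z0
  i000 <- 1 + x0 + d[1] * (y0 + d[2] * z0)
  dx <- 1; dy <- d[1]; dz <- d[1] * d[2]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * data[i000] +
    fx * (1 - fy) * (1 - fz) * data[i000 + dx] +
    (1 - fx) * fy * (1 - fz) * data[i000 + dy] +
    fx * fy * (1 - fz) * data[i000 + dx + dy] +
    (1 - fx) * (1 - fy) * fz * data[i000 + dz] +
    fx * (1 - fy) * fz * data[i000 + dx + dz] +
    (1 - fx) * fy * fz * data[i000 + dy + dz] +
    fx * fy * fz * data[i000 + dx + dy + dz]
  out[inside] <- v
  out
}

nearestAtVoxels <- function(data, vox, outside = 0) {
  d <- dim(data)
  r <- round(vox)
  inside <- r[, 1] >= 0 & r[, 2] >= 0 & r[, 3] >= 0 &
    r[, 1] <= d[1] - 1 & r[, 2] <= d[2] - 1 & r[, 3] <= d[3] - 1
  out <- rep(as.numeric(outside), nrow(vox))
  idx <- 1 + r[inside, 1] + d[1] * (r[inside, 2] + d[2] * r[inside, 3])
  out[inside] <- data[idx]
  out
}

#' Sample a volume at arbitrary world coordinates
#'
#' @param volume a [VolumeImage-class].
#' @param world N x 3 matrix of world-mm points.
#' @param mode "trilinear" or "nearest".
#' @param outside fill value for out-of-field points (use NA to flag).
#' @return numeric vector of length N.
#' @export
sampleVolumeAtWorld <- function(volume, world,
                                mode = c("trilinear", "nearest"),
                                outside = 0) {
  mode <- match.arg(mode)
  stopifnot(ncol(world) == 3)
  inv <- solve(volume@affine)
  vox <- cbind(world, 1) %*% t(inv)
  vox <- vox[, 1:3, drop = FALSE]
  if (mode == "trilinear") trilinearAtVoxels(volume@data, vox, outside)
  else nearestAtVoxels(volume@data, vox, outside)
}

# 0-based voxel index grid of a volume, as an N x 3 matrix (column-major
# voxel order, matching as.numeric(data)).
voxelIndexGrid <- function(d) {
  cbind(rep.int(0:(d[1] - 1), d[2] * d[3]),
        rep.int(rep(0:(d[2] - 1), each = d[1]), d[3]),
        rep(0:(d[3] - 1), each = d[1] * d[2]))
}

#' Resample a volume through an affine transform onto a target grid
#'
#' For each target voxel centre, the transform maps its world position
#' into the moving volume's world frame, where the value is interpolated.
#' Intensity volumes use trilinear interpolation (exact on linear fields);
#' label and mask volumes must use nearest-neighbour.  Out-of-field voxels
#' are set to 0.
#'
#' @param volume the moving [VolumeImage-class].
#' @param transform an [AffineTransform-class] or 4x4 matrix mapping
#'   target world coordinates to moving world coordinates.
#' @param target a [VolumeImage-class] defining the output grid, or a list
#'   with elements `dim` and `affine`; defaults to the input grid.
#' @param mode "trilinear" or "nearest".
#' @return the resampled [VolumeImage-class] on the target grid.
#' @export
resampleAffine <- function(volume, transform, target = volume,
                           mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(is(volume, "VolumeImage"))
  if (volume@units == "label" && mode == "trilinear")
    stop("label volumes must be resampled with mode = 'nearest'")
  M <- if (is(transform, "AffineTransform")) transform@matrix else transform
  stopifnot(all(dim(M) == c(4, 4)))
  tdim <- if (is(target, "VolumeImage")) dim(target@data) else target$dim
  taff <- if (is(target, "VolumeImage")) target@affine else target$affine
  idx <- voxelIndexGrid(tdim)
  world <- cbind(idx, 1) %*% t(taff)
  srcWorld <- world %*% t(M)
  vals <- sampleVolumeAtWorld(volume, srcWorld[, 1:3, drop = FALSE], mode)
  VolumeImage(array(vals, tdim), taff, volume@units)
}

# Antialiased 2x downsampling used by the registration pyramid.
downsampleVolume <- function(volume, factor = 2) {
  sm <- gaussianSmoothVolume(volume,
                             sigma_mm = 0.5 * factor * min(voxelSize(volume)))
  d <- ceiling(dim(volume@data) / factor)
  S <- diag(c(rep(factor, 3), 1))
  resampleAffine(sm, diag(4),
                 target = list(dim = d, affine = volume@affine %*% S))
}

#' NCC-driven affine registration
#'
#' Maximizes the normalized cross-correlation between the fixed volume and
#' the resampled moving volume by multi-start Nelder-Mead over the affine
#' parameters, coarse-to-fine over a 2-level image pyramid.  Rigid
#' alignment (6 dof) is estimated first; with `dof = 12`, scales and
#' shears are refined afterwards.  The report carries the NCC quality
#' gate (default 0.85): a failed gate is reported, never silently passed.
#'
#' @param moving,fixed [VolumeImage-class] objects with overlapping fields
#'   of view.
#' @param dof 6 (rigid) or 12 (full affine).
#' @param gate NCC acceptance threshold (default 0.85).
#' @param translation_starts extra coarse-level translation starts in mm
#'   (multi-start magnitude; default 5).
#' @param mask optional [VolumeImage-class] restricting the NCC to a
#'   region; by default the similarity uses the whole overlapping grid.
#' @return list with elements `transform` ([AffineTransform-class],
#'   mapping fixed world to moving world) and `report`
#'   ([RegistrationReport-class]).
#' @export
affineRegister <- function(moving, fixed, dof = 12L, gate = 0.85,
                           translation_starts = 5, mask = NULL) {
  stopifnot(is(moving, "VolumeImage"), is(fixed, "VolumeImage"),
            dof %in% c(6L, 12L))
  evals <- 0L
  # precomputed per level: fixed voxel world grid, fixed intensity vector
  # and the moving volume's inverse affine -- the per-evaluation work is
  # then one matrix product, one trilinear gather and one correlation
  levelContext <- function(mov, fix, msk, stride = 1L) {
    idx <- voxelIndexGrid(dim(fix@data))
    keep <- if (is.null(msk)) rep(TRUE, nrow(idx)) else as.logical(msk)
    if (stride > 1L)
      keep <- keep & rowSums(idx %% stride) == 0
    world <- cbind(idx[keep, , drop = FALSE], 1) %*% t(fix@affine)
    list(world = world, invMov = solve(mov@affine), movData = mov@data,
         fixVec = as.numeric(fix@data)[keep])
  }
  objective <- function(p, ctx) {
    full <- c(p[1:6], if (length(p) == 12) p[7:12] else c(1, 1, 1, 0, 0, 0))
    M <- affineParamsToMatrix(full)
    vox <- ctx$world %*% t(ctx$invMov %*% M)
    vals <- trilinearAtVoxels(ctx$movData, vox[, 1:3, drop = FALSE])
    evals <<- evals + 1L
    if (stats::sd(vals) < 1e-12) return(1)
    v <- stats::cor(ctx$fixVec, vals)
    if (!is.finite(v)) 1 else -v
  }
  movC <- downsampleVolume(moving)
  fixC <- downsampleVolume(fixed)
  mskC <- if (is.null(mask)) NULL
  else resampleAffine(mask, diag(4), fixC, mode = "nearest")@data > 0
  ctxC <- levelContext(movC, fixC, mskC)
  s <- translation_starts
  starts <- rbind(c(0, 0, 0),
                  s * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                            c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts[i, ], 0, 0, 0)
    fit <- stats::optim(p0, objective, ctx = ctxC,
                        method = "Nelder-Mead",
                        control = list(maxit = 120,
                                       parscale = c(rep(2, 3), rep(0.05, 3))))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  mskF <- if (is.null(mask)) NULL
  else (if (is(mask, "VolumeImage")) mask@data > 0 else mask > 0)
  ctxF <- levelContext(moving, fixed, mskF, stride = 2L)
  fit <- stats::optim(best$par, objective, ctx = ctxF,
                      method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-8,
                                     parscale = c(rep(1, 3), rep(0.02, 3))))
  par <- c(fit$par, 1, 1, 1, 0, 0, 0)
  if (dof == 12L) {
    fit <- stats::optim(par, objective, ctx = ctxF,
                        method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-9,
                                       parscale = c(rep(1, 3), rep(0.02, 3),
                                                    rep(0.01, 3),
                                                    rep(0.01, 3))))
    par <- fit$par
  }
  transform <- affineTransform(par[1:3], par[4:6], par[7:9], par[10:12],
                               dof = dof)
  finalNCC <- ncc(fixed, resampleAffine(moving, transform, fixed), mskF)
  report <- new("RegistrationReport", finalNCC = finalNCC,
                passedGate = finalNCC > gate, iterations = evals,
                gate = gate)
  if (!report@passedGate)
    warning(sprintf("registration NCC %.3f did not pass the %.2f gate",
                    finalNCC, gate))
  list(transform = transform, report = report)
}

# --- partial volume correction & SUVR ------------------------------------

#' Van Cittert iterative partial volume correction
#'
#' Deconvolves the PET point-spread function by the fixed-point iteration
#' `f_{k+1} = f_k + alpha * (g - h (*) f_k)` with `f_0 = g` and `h` an
#' isotropic Gaussian PSF.  Negative values are clamped to zero after each
#' step.  If the residual norm grows on two consecutive iterations the
#' iteration stops early with a warning (divergence guard).
#'
#' @param pet a [VolumeImage-class].
#' @param psf_fwhm_mm PSF full width at half maximum in mm (default 5,
#'   the scanner's isotropic spatial resolution).
#' @param alpha relaxation factor in (0, 2] (default 1).
#' @param n_iter number of iterations (>= 0; default 10).
#' @return the corrected [VolumeImage-class].
#' @export
vanCittertPVC <- function(pet, psf_fwhm_mm = 5.0, alpha = 1.0,
                          n_iter = 10L) {
  stopifnot(is(pet, "VolumeImage"), psf_fwhm_mm > 0,
            alpha > 0, alpha <= 2, n_iter >= 0)
  g <- pet@data
  f <- g
  prevNorm <- Inf
  grew <- 0L
  for (k in seq_len(n_iter)) {
    hf <- gaussianSmoothVolume(VolumeImage(f, pet@affine),
                               fwhm_mm = psf_fwhm_mm)@data
    resid <- g - hf
    rn <- sqrt(sum(resid^2))
    if (rn > prevNorm) {
      grew <- grew + 1L
      if (grew >= 2L) {
        warning("van Cittert residual grew on 2 consecutive iterations; ",
                "stopping at iteration ", k - 1L)
        break
      }
    } else grew <- 0L
    prevNorm <- rn
    f <- pmax(f + alpha * resid, 0)
  }
  VolumeImage(f, pet@affine, pet@units)
}

#' Convert a PET volume to standardized uptake value ratios
#'
#' Divides every voxel by the mean intensity within the reference-region
#' mask (the cerebellum in this pipeline).  The output is invariant to
#' global multiplicative rescaling of the input.
#'
#' @param pet a [VolumeImage-class].
#' @param reference_mask [VolumeImage-class] or logical array; non-empty,
#'   with positive mean PET uptake.
#' @return the SUVR [VolumeImage-class].
#' @export
suvr <- function(pet, reference_mask) {
  stopifnot(is(pet, "VolumeImage"))
  m <- if (is(reference_mask, "VolumeImage")) reference_mask@data > 0
  else reference_mask > 0
  stopifnot(all(dim(m) == dim(pet@data)))
  if (!any(m)) stop("reference mask is empty")
  ref <- mean(pet@data[m])
  if (ref <= 0) stop("non-positive reference-region mean: ", ref)
  VolumeImage(pet@data / ref, pet@affine, pet@units)
}
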