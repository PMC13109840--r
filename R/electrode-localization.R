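#' @include AllClasses.R volume-preproc.R
NULL

#' Compute the voxel footprint of a cylindrical SEEG contact
#'
#' The footprint is the set of label-volume voxels whose centres lie
#' inside the contact cylinder (radius = diameter/2, half-length =
#' length/2 about the centre along the axis).  On grids coarser than the
#' contact (footprint below `min_voxels` centres), each candidate voxel
#' is subdivided 4x per axis and fractional occupancy weights are used
#' instead, keeping the majority rule meaningful at any resolution.
#'
#' @param contact one-row data.frame (or list) with fields x, y, z,
#'   axis_x, axis_y, axis_z, diameter, length (mm, world).
#' @param label_volume a [VolumeImage-class] providing the voxel grid.
#' @param min_voxels threshold below which supersampling engages
#'   (default 8).
#' @return list with `indices` (linear voxel indices), `weights`
#'   (occupancy weights, 1 for whole voxels), and `supersampled` flag.
#' @export
voxelizeContact <- function(contact, label_volume, min_voxels = 8L) {
  stopifnot(is(label_volume, "VolumeImage"))
  ctr <- c(contact$x, contact$y, contact$z)
  axis <- c(contact$axis_x, contact$axis_y, contact$axis_z)
  axis <- axis / sqrt(sum(axis^2))
  r <- contact$diameter / 2
  hl <- contact$length / 2
  d <- dim(label_volume@data)
  inv <- solve(label_volume@affine)
  ctrVox <- (inv %*% c(ctr, 1))[1:3]
  if (any(ctrVox < -0.5) || any(ctrVox > d - 0.5))
    stop("contact centre lies outside the label volume grid")
  # candidate voxel range from the cylinder's loose bounding sphere
  reach <- hl + r
  corners <- as.matrix(expand.grid(ctr[1] + c(-reach, reach),
                                   ctr[2] + c(-reach, reach),
                                   ctr[3] + c(-reach, reach)))
  cvox <- cbind(corners, 1) %*% t(inv)
  lo <- pmax(floor(apply(cvox[, 1:3], 2, min)) - 1, 0)
  hi <- pmin(ceiling(apply(cvox[, 1:3], 2, max)) + 1, d - 1)
  if (any(lo > hi)) stop("empty candidate voxel range")
  idx <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  world <- cbind(idx, 1) %*% t(label_volume@affine)
  inCyl <- function(p) {
    rel <- sweep(p, 2, ctr)
    t <- as.numeric(rel %*% axis)
    rad2 <- rowSums(rel^2) - t^2
    abs(t) <= hl & rad2 <= r^2
  }
  inside <- inCyl(world[, 1:3, drop = FALSE])
  linear <- 1 + idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3])
  if (sum(inside) >= min_voxels) {
    return(list(indices = linear[inside],
                weights = rep(1, sum(inside)), supersampled = FALSE))
  }
  # supersampling fallback: at least 4 sub-centres per axis, refined so
  # the sub-grid pitch stays below half the contact radius even on
  # coarse (several-mm) grids
  vs <- sqrt(colSums(label_volume@affine[1:3, 1:3]^2))
  f <- min(25L, max(4L, ceiling(max(vs) / (r / 2))))
  off <- (seq_len(f) - 0.5) / f - 0.5
  sub <- as.matrix(expand.grid(off, off, off))
  nC <- nrow(idx); m <- nrow(sub)
  pts <- idx[rep(seq_len(nC), each = m), , drop = FALSE] +
    sub[rep(seq_len(m), times = nC), , drop = FALSE]
  pw <- cbind(pts, 1) %*% t(label_volume@affine)
  inside <- inCyl(pw[, 1:3, drop = FALSE])
  w <- as.numeric(rowsum(as.numeric(inside),
                         rep(seq_len(nC), each = m))) / m
  keep <- w > 0
  if (!any(keep))
    stop("contact footprint is empty even after supersampling")
  list(indices = linear[keep], weights = w[keep], supersampled = TRUE)
}

#' Assign a contact to a region by the majority-voxel rule
#'
#' Counts (possibly fractional) footprint voxels per label; the contact is
#' assigned to a region iff that region's share of the full footprint is
#' strictly greater than 0.5 and the label is a gray-matter region.  An
#' exact 50/50 split fails verification.  The denominator is the whole
#' footprint, including background and non-gray labels.
#'
#' @param footprint output of [voxelizeContact()] (list of indices and
#'   weights).
#' @param label_volume the integer-label [VolumeImage-class].
#' @param label_table data.frame with columns code, hemisphere, region,
#'   gray (logical) describing the label volume's coding.
#' @param contact_id identifier carried into the result.
#' @return A [ContactAssignment-class].
#' @export
assignContactRegion <- function(footprint, label_volume, label_table,
                                contact_id = "contact") {
  stopifnot(length(footprint$indices) > 0,
            all(c("code", "hemisphere", "region", "gray") %in%
                  names(label_table)))
  codes <- label_volume@data[footprint$indices]
  counts <- rowsum(footprint$weights, codes)
  countVec <- as.numeric(counts)
  names(countVec) <- rownames(counts)
  total <- sum(countVec)
  top <- which.max(countVec)
  frac <- countVec[top] / total
  topCode <- as.numeric(names(countVec)[top])
  row <- label_table[match(topCode, label_table$code), ]
  isGray <- !is.na(row$gray) && isTRUE(row$gray)
  verified <- frac > 0.5 && isGray
  new("ContactAssignment",
      contactId = as.character(contact_id),
      region = if (verified) row$region else NA_character_,
      hemisphere = if (verified) row$hemisphere else NA_character_,
      voxelCounts = countVec,
      majorityFraction = as.numeric(frac),
      verified = verified)
}

#' Filter a contact table to verified gray-matter contacts
#'
#' Runs [voxelizeContact()] and [assignContactRegion()] for every contact
#' and keeps only those verified by the strict majority rule.  The report
#' lists every input contact with its majority fraction and outcome
#' (contacts whose footprint cannot be computed are reported unverified).
#'
#' @param contact_table a [ContactTable-class].
#' @param label_volume the integer-label [VolumeImage-class].
#' @param label_table label coding table (see [assignContactRegion()]).
#' @return list with `verified` (a [ContactTable-class] of kept contacts)
#'   and `report` (data.frame contact_id, region, hemisphere,
#'   majority_fraction, verified — one row per input contact).
#' @export
filterGrayMatterContacts <- function(contact_table, label_volume,
                                     label_table) {
  stopifnot(is(contact_table, "ContactTable"))
  df <- contact_table@contacts
  emptyReport <- data.frame(contact_id = character(),
                            region = character(),
                            hemisphere = character(),
                            majority_fraction = numeric(),
                            verified = logical())
  if (!nrow(df))
    return(list(verified = contact_table, report = emptyReport))
  rows <- lapply(seq_len(nrow(df)), function(i) {
    a <- tryCatch({
      fp <- voxelizeContact(df[i, ], label_volume)
      assignContactRegion(fp, label_volume, label_table,
                          contact_id = df$contact_id[i])
    }, error = function(e) NULL)
    if (is.null(a))
      data.frame(contact_id = df$contact_id[i], region = NA_character_,
                 hemisphere = NA_character_, majority_fraction = NA_real_,
                 verified = FALSE, stringsAsFactors = FALSE)
    else
      data.frame(contact_id = a@contactId, region = a@region,
                 hemisphere = a@hemisphere,
                 majority_fraction = a@majorityFraction,
                 verified = a@verified, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  keep <- df$contact_id %in% report$contact_id[report$verified]
  list(verified = new("ContactTable", contacts = df[keep, , drop = FALSE]),
       report = report)
}
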