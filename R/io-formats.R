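#' @include AllClasses.R
NULL

#' Read and write volumes as NIfTI-1
#'
#' NIfTI-1 is the canonical volume dialect (MGH is not supported; convert
#' externally).  Round-trips preserve the data bit-exactly for float64
#' payloads and the affine to 1e-6.  The affine maps 0-based voxel indices
#' to world RAS mm (voxel-centre convention).
#'
#' @param path file path (.nii or .nii.gz).
#' @return `readVolume` returns a [VolumeImage-class]; `writeVolume`
#'   returns `path` invisibly.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("volume file does not exist: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  aff <- if (hdr$sform_code > 0)
    rbind(hdr$srow_x, hdr$srow_y, hdr$srow_z, c(0, 0, 0, 1))
  else unclass(RNifti::xform(img))
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(data)), " dimensions")
  VolumeImage(data, matrix(as.numeric(aff), 4, 4))
}

#' @rdname readVolume
#' @param volume a [VolumeImage-class] to write.
#' @param datatype NIfTI datatype; "double" (default) is lossless for
#'   intensities, "int32" suits label volumes.
#' @export
writeVolume <- function(volume, path, datatype = "double") {
  stopifnot(is(volume, "VolumeImage"))
  img <- RNifti::asNifti(volume@data, datatype = datatype)
  RNifti::qform(img) <- structure(volume@affine, code = 2L)
  RNifti::sform(img) <- structure(volume@affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read and write per-vertex maps (FreeSurfer curv or CSV)
#'
#' The binary curv dialect is the FreeSurfer "new-format" curvature file:
#' three 0xFF magic bytes, big-endian int32 vertex/face/values-per-vertex
#' counts, then big-endian float32 values.  The CSV dialect has columns
#' `vertex_id` (0-based) and `value`.  Both round-trip exactly at 32-bit
#' float precision and produce identical in-memory arrays.
#'
#' @param path file path; format inferred from the ".csv" extension unless
#'   `format` is given.
#' @param format "auto", "curv" or "csv".
#' @param n_vertices optional expected length; a mismatch is an error
#'   naming both counts.
#' @return `readVertexMap` returns a numeric vector; writers return `path`
#'   invisibly.
#' @export
readVertexMap <- function(path, format = c("auto", "curv", "csv"),
                          n_vertices = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("vertex map file does not exist: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "curv"
  values <- if (format == "csv") {
    df <- utils::read.csv(path)
    if (!all(c("vertex_id", "value") %in% names(df)))
      stop("CSV vertex map needs columns 'vertex_id' and 'value'")
    df$value[order(df$vertex_id)]
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
    if (!all(magic == 255L)) stop("not a FreeSurfer curv file: ", path)
    vnum <- readBin(con, "integer", size = 4L, endian = "big")
    readBin(con, "integer", size = 4L, endian = "big")          # fnum
    vpv <- readBin(con, "integer", size = 4L, endian = "big")
    if (vpv != 1L) stop("unsupported values-per-vertex: ", vpv)
    readBin(con, "numeric", n = vnum, size = 4L, endian = "big")
  }
  if (!is.null(n_vertices) && length(values) != n_vertices)
    stop("vertex map length ", length(values),
         " does not match surface vertex count ", n_vertices)
  as.numeric(values)
}

#' @rdname readVertexMap
#' @param values numeric vector or [VertexMap-class] to write.
#' @export
writeVertexMap <- function(values, path, format = c("auto", "curv", "csv")) {
  if (is(values, "VertexMap")) values <- values@values
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "curv"
  if (format == "csv") {
    utils::write.csv(data.frame(vertex_id = seq_along(values) - 1L,
                                value = values),
                     path, row.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(c(255L, 255L, 255L)), con)
    writeBin(as.integer(c(length(values), 0L, 1L)), con, size = 4L,
             endian = "big")
    writeBin(as.numeric(values), con, size = 4L, endian = "big")
  }
  invisible(path)
}

#' Read and write SEEG contact tables
#'
#' CSV with columns contact_id, electrode, x, y, z, axis_x, axis_y, axis_z,
#' soz_flag and optionally diameter and length (defaults 0.8 and 2.0 mm).
#' Coordinates are world RAS mm.  Axis vectors deviating from unit norm by
#' more than 1e-3 are renormalized with a warning; zero-norm axes and
#' duplicated contact ids are errors.
#'
#' @param path CSV file path.
#' @return `readContacts` returns a [ContactTable-class]; `writeContacts`
#'   returns `path` invisibly.
#' @export
readContacts <- function(path) {
  if (!file.exists(path)) stop("contact file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("contact_id", "electrode", "x", "y", "z",
            "axis_x", "axis_y", "axis_z", "soz_flag")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("contact table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$contact_id))
    stop("duplicate contact id(s): ",
         paste(unique(df$contact_id[duplicated(df$contact_id)]),
               collapse = ", "))
  if (is.null(df$diameter)) df$diameter <- 0.8
  if (is.null(df$length)) df$length <- 2.0
  nrm <- sqrt(df$axis_x^2 + df$axis_y^2 + df$axis_z^2)
  if (any(nrm < 1e-9)) stop("zero-norm contact axis vector")
  if (any(abs(nrm - 1) > 1e-3))
    warning(sum(abs(nrm - 1) > 1e-3),
            " contact axis vector(s) were not unit-norm; renormalized")
  df$axis_x <- df$axis_x / nrm
  df$axis_y <- df$axis_y / nrm
  df$axis_z <- df$axis_z / nrm
  df$contact_id <- as.character(df$contact_id)
  df$soz_flag <- as.logical(df$soz_flag)
  new("ContactTable", contacts = df[, c(need[1:8], "diameter", "length",
                                        "soz_flag")])
}

#' @rdname readContacts
#' @param table a [ContactTable-class].
#' @export
writeContacts <- function(table, path) {
  stopifnot(is(table, "ContactTable"))
  utils::write.csv(table@contacts, path, row.names = FALSE)
  invisible(path)
}

#' Write a parcellation as a CSV label table
#'
#' Columns vertex_id (0-based), region, hemisphere; the lobe lookup is
#' written alongside with suffix "_lobes.csv".
#'
#' @param parcellation a [Parcellation-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeParcellation <- function(parcellation, path) {
  utils::write.csv(data.frame(
    vertex_id = seq_along(parcellation@region) - 1L,
    region = parcellation@region,
    hemisphere = parcellation@hemisphere), path, row.names = FALSE)
  utils::write.csv(parcellation@lobeTable,
                   sub("\\.csv$", "_lobes.csv", path), row.names = FALSE)
  invisible(path)
}
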