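# 3-D scalar volumes: data array + spacing + origin (axis-aligned).
# world = origin + 0-based voxel index * spacing.

#' 3-D scalar volume
#'
#' @param data numeric 3-D array of voxel intensities.
#' @param spacing voxel spacing in mm, length-3 (or scalar, recycled).
#' @param origin world coordinate (mm) of the center of voxel (0,0,0).
#' @return Object of class `cp_volume` with fields `data`, `spacing`, `origin`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3-D array", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = vec3(origin)),
            class = "cp_volume")
}

#' @export
print.cp_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm, origin (%.3g, %.3g, %.3g)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.cp_volume <- function(x) dim(x$data)

#' Convert 0-based voxel indices to world mm (and back)
#'
#' @param v a `cp_volume` (or any list with `spacing`/`origin`).
#' @param idx numeric vector of length 3, or an n x 3 matrix of 0-based indices.
#' @return World coordinates, same shape as the input.
#' @export
voxel_to_world <- function(v, idx) {
  if (is.matrix(idx))
    sweep(sweep(idx, 2, v$spacing, `*`), 2, v$origin, `+`)
  else v$origin + idx * v$spacing
}

#' @rdname voxel_to_world
#' @param world world coordinates (length 3 or n x 3 matrix).
#' @export
world_to_voxel <- function(v, world) {
  if (is.matrix(world))
    sweep(sweep(world, 2, v$origin, `-`), 2, v$spacing, `/`)
  else (world - v$origin) / v$spacing
}

#' World coordinate of the volume center
#' @param v a `cp_volume`.
#' @return length-3 numeric vector (mm).
#' @export
volume_center <- function(v) voxel_to_world(v, (dim(v$data) - 1) / 2)

#' Block-mean downsampling
#'
#' Reduces each axis by an integer factor using block means; trailing voxels
#' that do not fill a complete block are dropped. Spacing is multiplied by
#' the factor and the origin shifted so that each output voxel sits at the
#' center of its source block (world coordinates are preserved).
#'
#' @param v a `cp_volume`.
#' @param factor integer >= 2.
#' @return The downsampled `cp_volume`.
#' @export
downsample <- function(v, factor) {
  stopifnot(inherits(v, "cp_volume"))
  factor <- as.integer(factor)
  if (factor < 2L) stop("factor must be >= 2", call. = FALSE)
  d <- dim(v$data)
  nd <- d %/% factor
  if (any(nd < 1L)) stop("factor larger than a volume dimension", call. = FALSE)
  a <- v$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
              seq_len(nd[3] * factor), drop = FALSE]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  out <- apply(a, c(2, 4, 6), mean)
  volume(out, spacing = v$spacing * factor,
         origin = v$origin + (factor - 1) / 2 * v$spacing)
}

format_error <- function(msg) {
  stop(errorCondition(msg, class = c("cardioplane_format", "cardioplane_error")))
}

#' Read a 3-D volume from NIfTI or MetaImage
#'
#' NIfTI (`.nii`, `.nii.gz`) is read through RNifti; MetaImage (`.mhd`,
#' `.mha`, uncompressed) through a built-in reader. Spacing and origin are
#' taken from the header; direction cosines are not supported (volumes are
#' assumed axis-aligned).
#'
#' @param path file path.
#' @return A `cp_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such volume file: %s", path))
  ext <- tolower(sub("^.*?((\\.nii(\\.gz)?)|(\\.mhd)|(\\.mha))$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) format_error(
                      sprintf("failed to read NIfTI %s: %s", path, conditionMessage(e))))
    if (length(dim(img)) != 3L)
      format_error(sprintf("%s: expected a 3-D volume", path))
    x <- RNifti::xform(img)
    if (attr(x, "code") == 0L) {
      spacing <- attr(img, "pixdim")[1:3]
      world0 <- c(0, 0, 0)
    } else {
      rot <- x[1:3, 1:3]
      if (max(abs(rot - diag(diag(rot)))) > 1e-6 || any(diag(rot) <= 0))
        format_error(sprintf(
          "%s: oblique or flipped orientation not supported (axis-aligned volumes only)", path))
      spacing <- diag(rot)
      world0 <- x[1:3, 4]
    }
    volume(array(as.numeric(img), dim = dim(img)), spacing = spacing,
           origin = world0)
  } else if (ext %in% c(".mhd", ".mha")) {
    read_metaimage(path)
  } else {
    format_error(sprintf("unsupported volume format: %s", path))
  }
}

#' Write a 3-D volume to NIfTI or MetaImage
#'
#' @param v a `cp_volume`.
#' @param path output path; format chosen by extension as in [read_volume()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "cp_volume"))
  ext <- tolower(sub("^.*?((\\.nii(\\.gz)?)|(\\.mhd)|(\\.mha))$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::asNifti(v$data)
    RNifti::pixdim(img) <- v$spacing
    m <- diag(c(v$spacing, 1))
    m[1:3, 4] <- v$origin
    RNifti::sform(img) <- structure(m, code = 2L)
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (ext %in% c(".mhd", ".mha")) {
    write_metaimage(v, path)
  } else {
    format_error(sprintf("unsupported volume format: %s", path))
  }
  invisible(path)
}

# --- MetaImage (uncompressed) ------------------------------------------------

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list(); nhdr <- 0L
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) format_error(sprintf("%s: truncated MetaImage header", path))
    nhdr <- nhdr + 1L
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) format_error(sprintf("%s: malformed header line '%s'", path, line))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
    if (nhdr > 50L) format_error(sprintf("%s: header too long", path))
  }
  need <- c("NDims", "DimSize", "ElementType")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) format_error(sprintf("%s: missing header fields %s", path,
                                         paste(miss, collapse = ", ")))
  if (hdr$NDims != "3") format_error(sprintf("%s: only 3-D MetaImage supported", path))
  if (!is.null(hdr$CompressedData) && tolower(hdr$CompressedData) == "true")
    format_error(sprintf("%s: compressed MetaImage not supported", path))
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  tinfo <- switch(hdr$ElementType,
                  MET_DOUBLE = list(what = "double", size = 8L),
                  MET_FLOAT = list(what = "double", size = 4L),
                  MET_SHORT = list(what = "integer", size = 2L),
                  MET_UCHAR = list(what = "integer", size = 1L),
                  format_error(sprintf("%s: unsupported ElementType %s", path, hdr$ElementType)))
  n <- prod(d)
  if (hdr$ElementDataFile == "LOCAL") {
    vals <- readBin(con, tinfo$what, n = n, size = tinfo$size,
                    signed = !identical(hdr$ElementType, "MET_UCHAR"))
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path)) format_error(sprintf("%s: missing data file %s", path, raw_path))
    rc <- file(raw_path, "rb"); on.exit(close(rc), add = TRUE)
    vals <- readBin(rc, tinfo$what, n = n, size = tinfo$size,
                    signed = !identical(hdr$ElementType, "MET_UCHAR"))
  }
  if (length(vals) < n) format_error(sprintf("%s: truncated voxel data", path))
  volume(array(as.numeric(vals), dim = d), spacing = spacing, origin = origin)
}

write_metaimage <- function(v, path) {
  ext <- tolower(tools::file_ext(path))
  d <- dim(v$data)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementSpacing = %.17g %.17g %.17g",
                   v$spacing[1], v$spacing[2], v$spacing[3]),
           sprintf("Offset = %.17g %.17g %.17g",
                   v$origin[1], v$origin[2], v$origin[3]),
           "ElementType = MET_DOUBLE")
  if (ext == "mha") {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    writeBin(as.numeric(v$data), con, size = 8L)
  } else {
    raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
    writeLines(c(hdr, sprintf("ElementDataFile = %s", raw_name)), path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.numeric(v$data), con, size = 8L)
  }
  invisible(path)
}

# --- Gaussian smoothing of 3-D arrays ---------------------------------------

#' Separable Gaussian smoothing of a 3-D array
#'
#' Edge handling by replication (clamped indices), so total mass is
#' approximately preserved away from strong edges.
#'
#' @param a 3-D numeric array.
#' @param sigma kernel standard deviation in voxels; 0 returns `a`.
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth3 <- function(a, sigma = 2) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(a)
  for (ax in 1:3) {
    out <- array(0, d)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- pmin(pmax(seq_len(d[ax]) + off, 1L), d[ax])
      out <- out + k[j] * switch(ax,
                                 a[idx, , , drop = FALSE],
                                 a[, idx, , drop = FALSE],
                                 a[, , idx, drop = FALSE])
    }
    a <- out
  }
  a
}
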