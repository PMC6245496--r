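# Per-voxel appearance channels and the binary node test used by both the
# detection (Hough) and refinement (regression) forests.

CHANNEL_NAMES <- c("intensity", "grad_x", "grad_y", "grad_z", "grad_mag")

#' Appearance channels for a volume
#'
#' Channel 0 is the raw intensity; the three gradient channels are 3-D
#' Sobel responses (derivative kernel `(-1, 0, 1)` combined with smoothing
#' `(1, 2, 1)` on the other two axes); `grad_mag` is their Euclidean norm.
#' Volume borders are handled by edge replication.
#'
#' @param v a `cp_volume` with at least 3 voxels per axis.
#' @return Object of class `cp_channels`: a list of 5 named arrays congruent
#'   with the volume, plus `spacing`, `origin` and `dim`.
#' @export
compute_channels <- function(v) {
  stopifnot(inherits(v, "cp_volume"))
  d <- dim(v$data)
  if (any(d < 3L)) stop("volume must have at least 3 voxels per axis", call. = FALSE)
  g <- cp_sobel(as.numeric(v$data), as.integer(d))
  ch <- c(list(intensity = v$data),
          lapply(g, function(x) array(x, dim = d)))
  names(ch) <- CHANNEL_NAMES
  structure(list(channels = ch, spacing = v$spacing, origin = v$origin, dim = d),
            class = "cp_channels")
}

#' @export
print.cp_channels <- function(x, ...) {
  cat(sprintf("<channel stack> %s, %d x %d x %d voxels\n",
              paste(names(x$channels), collapse = ", "),
              x$dim[1], x$dim[2], x$dim[3]))
  invisible(x)
}

as_channels <- function(x) {
  if (inherits(x, "cp_channels")) x else compute_channels(x)
}

#' Binary node test
#'
#' A forest node test compares the difference of two channel values at two
#' in-patch offsets against a threshold: it fires iff
#' `channel[center + offset_a] - channel[center + offset_b] > threshold`.
#'
#' @param channel channel index, 1-based into the channel stack.
#' @param offset_a,offset_b integer voxel offsets (length 3) within the patch.
#' @param threshold numeric threshold.
#' @return Object of class `cp_binary_test`.
#' @export
binary_test <- function(channel, offset_a, offset_b, threshold = 0) {
  structure(list(channel = as.integer(channel),
                 offset_a = as.integer(offset_a),
                 offset_b = as.integer(offset_b),
                 threshold = as.numeric(threshold)),
            class = "cp_binary_test")
}

channel_value <- function(cs, channel, idx0) {
  # clamped 0-based lookup
  i <- pmin(pmax(idx0, 0L), cs$dim - 1L)
  cs$channels[[channel]][i[1] + 1L, i[2] + 1L, i[3] + 1L]
}

#' Evaluate a binary test at a voxel
#'
#' Out-of-volume reads clamp to the nearest edge voxel.
#'
#' @param cs a `cp_channels` stack.
#' @param center 0-based voxel index (length 3).
#' @param t a [binary_test()].
#' @return 0 or 1.
#' @export
eval_binary_test <- function(cs, center, t) {
  stopifnot(inherits(cs, "cp_channels"), inherits(t, "cp_binary_test"))
  center <- as.integer(center)
  a <- channel_value(cs, t$channel, center + t$offset_a)
  b <- channel_value(cs, t$channel, center + t$offset_b)
  as.integer(a - b > t$threshold)
}
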