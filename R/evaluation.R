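# Error metrics, the 10 degree / 5 mm clinical success criterion, and
# Bland-Altman agreement statistics.

#' Euclidean landmark distance error
#'
#' @param detected,truth world points, mm.
#' @return Distance in mm.
#' @export
point_error <- function(detected, truth) norm3(vec3(detected) - vec3(truth))

#' Plane extraction error against ground truth
#'
#' Angle component: folded dihedral angle between the normals. Distance
#' component: the anchor (operationally the midpoint of the ground-truth
#' long axis, the "LV center") is projected onto the truth plane and its
#' distance to the predicted plane measured. Success requires angle
#' strictly below 10 degrees and distance strictly below 5 mm.
#'
#' @param pred,truth `cp_plane`s.
#' @param anchor LV center, world mm (typically `axis$base +
#'   axis$length/2 * axis$direction` of the ground-truth axis).
#' @param angle_max_deg,dist_max_mm clinical limits.
#' @return List of class `cp_plane_error`: `angle_deg`, `distance_mm`,
#'   `success`.
#' @export
plane_error <- function(pred, truth, anchor, angle_max_deg = 10,
                        dist_max_mm = 5) {
  angle <- angle_between_planes(pred, truth)
  foot <- project_onto_plane(vec3(anchor), truth)
  dist <- point_plane_distance(foot, pred)
  structure(list(angle_deg = angle, distance_mm = dist,
                 success = angle < angle_max_deg && dist < dist_max_mm),
            class = "cp_plane_error")
}

#' Angle error between two long axes
#'
#' Folded to `[0, 90]` degrees (direction sign is immaterial).
#'
#' @param pred,truth `cp_long_axis` objects.
#' @return Degrees.
#' @export
long_axis_angle_error <- function(pred, truth) {
  d <- min(1, abs(sum(pred$direction * truth$direction)))
  acos(d) * 180 / pi
}

#' Mitral-annulus diameter and LV length from landmarks
#'
#' MA diameter is the septal-to-lateral distance; LV length the distance
#' from the apex to the MA midpoint.
#'
#' @param lm a [landmark_set()].
#' @return mm.
#' @export
ma_diameter <- function(lm) norm3(lm$septal_ma - lm$lateral_ma)

#' @rdname ma_diameter
#' @export
lv_length <- function(lm) norm3(lm$apex - (lm$septal_ma + lm$lateral_ma) / 2)

#' Bland-Altman agreement statistics
#'
#' Differences `d = m1 - m2`; bias is their mean and the limits of
#' agreement `bias +/- 1.96 * SD(d)` (sample SD, n-1 denominator).
#'
#' @param m1,m2 equal-length numeric vectors (n >= 2).
#' @return List of class `cp_bland_altman`: `bias`, `lo`, `hi`, `sd`,
#'   `means`, `diffs`.
#' @export
bland_altman <- function(m1, m2) {
  m1 <- as.numeric(m1); m2 <- as.numeric(m2)
  if (length(m1) != length(m2)) stop("measurement vectors differ in length", call. = FALSE)
  if (length(m1) < 2L) stop("need at least two paired measurements", call. = FALSE)
  d <- m1 - m2
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, lo = bias - 1.96 * s, hi = bias + 1.96 * s,
                 sd = s, means = (m1 + m2) / 2, diffs = d),
            class = "cp_bland_altman")
}

#' @export
print.cp_bland_altman <- function(x, ...) {
  cat(sprintf("<Bland-Altman> bias %.3f, limits of agreement [%.3f, %.3f] (n = %d)\n",
              x$bias, x$lo, x$hi, length(x$diffs)))
  invisible(x)
}

#' Summarize plane-extraction errors
#'
#' @param errors a data.frame with columns `plane`, `angle_deg`,
#'   `distance_mm`, `success` (as produced by [evaluate_planes()]), or a
#'   plain numeric vector (summarized as one row).
#' @return A data.frame with per-plane and pooled rows: n, mean and sample
#'   SD of both error components, and the success rate.
#' @export
summarize_errors <- function(errors) {
  if (is.numeric(errors)) {
    if (length(errors) == 0L) stop("empty error list", call. = FALSE)
    return(data.frame(plane = "all", n = length(errors), mean = mean(errors),
                      sd = if (length(errors) > 1L) stats::sd(errors) else 0))
  }
  if (nrow(errors) == 0L) stop("empty error table", call. = FALSE)
  one <- function(df, label) {
    data.frame(plane = label, n = nrow(df),
               angle_mean = mean(df$angle_deg),
               angle_sd = if (nrow(df) > 1L) stats::sd(df$angle_deg) else 0,
               dist_mean = mean(df$distance_mm),
               dist_sd = if (nrow(df) > 1L) stats::sd(df$distance_mm) else 0,
               success_rate = mean(df$success))
  }
  parts <- lapply(split(errors, errors$plane), function(df)
    one(df, df$plane[1]))
  out <- do.call(rbind, c(parts, list(one(errors, "pooled"))))
  rownames(out) <- NULL
  out
}

#' Evaluate a predicted plane set against ground truth
#'
#' @param pred named list of `cp_plane`s (or a `cp_plane_set`).
#' @param truth_planes named list of ground-truth `cp_plane`s.
#' @param truth_axis the ground-truth `cp_long_axis` (its midpoint anchors
#'   the distance error).
#' @param volume_id optional identifier column.
#' @return data.frame with one row per plane: `volume_id`, `plane`,
#'   `angle_deg`, `distance_mm`, `success`.
#' @export
evaluate_planes <- function(pred, truth_planes, truth_axis, volume_id = NA) {
  if (inherits(pred, "cp_plane_set")) pred <- pred$planes
  anchor <- truth_axis$base + truth_axis$length / 2 * truth_axis$direction
  rows <- lapply(intersect(PLANE_NAMES, names(pred)), function(nm) {
    pe <- plane_error(pred[[nm]], truth_planes[[nm]], anchor)
    data.frame(volume_id = volume_id, plane = nm, angle_deg = pe$angle_deg,
               distance_mm = pe$distance_mm, success = pe$success)
  })
  do.call(rbind, rows)
}
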