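#' @useDynLib cardioplane, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# All geometry is in world millimetres. Volumes are axis-aligned:
# world = origin + 0-based voxel index * spacing (no direction cosines).

.AREA_EPS <- 1        # mm^2, degeneracy threshold for landmark triangles
.AXIS_EPS <- 1        # mm, minimum long-axis length

vec3 <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x)))
    stop("expected a finite 3-vector", call. = FALSE)
  x
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- norm3(v)
  if (n < 1e-12) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

degenerate_geometry <- function(msg) {
  stop(errorCondition(msg, class = c("cardioplane_degenerate", "cardioplane_error")))
}

#' Oriented plane in world coordinates
#'
#' A plane is stored as an arbitrary on-plane point plus a unit normal.
#' For error metrics the normal sign is treated as an artifact (angles are
#' folded); construction functions fix the sign by the right-hand rule so
#' that rotation round-trips are well defined.
#'
#' @param point numeric 3-vector, any point on the plane (mm).
#' @param normal numeric 3-vector; normalized internally, must be non-zero.
#' @return An object of class `cp_plane` with fields `point` and `normal`.
#' @export
plane <- function(point, normal) {
  structure(list(point = vec3(point), normal = unit3(vec3(normal))),
            class = "cp_plane")
}

#' @export
print.cp_plane <- function(x, ...) {
  cat(sprintf("<plane> point (%.2f, %.2f, %.2f) mm, normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Left-ventricular long axis
#'
#' Directed axis from the mitral-annulus midpoint (`base`) toward the apex.
#'
#' @param base numeric 3-vector, MA midpoint (mm).
#' @param direction numeric 3-vector pointing from base to apex; normalized.
#' @param length positive axis length (mm).
#' @return Object of class `cp_long_axis` with `base`, `direction`, `length`.
#' @export
long_axis <- function(base, direction, length) {
  length <- as.numeric(length)
  if (!is.finite(length) || length <= 0)
    degenerate_geometry("long axis length must be positive")
  structure(list(base = vec3(base), direction = unit3(vec3(direction)),
                 length = length),
            class = "cp_long_axis")
}

#' @export
print.cp_long_axis <- function(x, ...) {
  cat(sprintf("<long axis> base (%.2f, %.2f, %.2f), direction (%.4f, %.4f, %.4f), length %.2f mm\n",
              x$base[1], x$base[2], x$base[3],
              x$direction[1], x$direction[2], x$direction[3], x$length))
  invisible(x)
}

#' Anatomical landmark triple
#'
#' The three feature points that anchor the apical four-chamber view: LV
#' apex and the septal/lateral extremes of the mitral annulus. The triple
#' must span a triangle of area > 1 mm^2.
#'
#' @param apex,septal_ma,lateral_ma numeric 3-vectors (mm).
#' @return Object of class `cp_landmarks`.
#' @export
landmark_set <- function(apex, septal_ma, lateral_ma) {
  apex <- vec3(apex); septal_ma <- vec3(septal_ma); lateral_ma <- vec3(lateral_ma)
  area <- 0.5 * norm3(cross3(septal_ma - apex, lateral_ma - apex))
  if (area <= .AREA_EPS)
    degenerate_geometry(sprintf(
      "landmarks are (nearly) collinear: triangle area %.3g mm^2", area))
  structure(list(apex = apex, septal_ma = septal_ma, lateral_ma = lateral_ma),
            class = "cp_landmarks")
}

#' @export
print.cp_landmarks <- function(x, ...) {
  for (nm in c("apex", "septal_ma", "lateral_ma"))
    cat(sprintf("  %-10s (%8.2f, %8.2f, %8.2f) mm\n", nm,
                x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

#' Plane through three points
#'
#' Normal orientation follows the right-hand rule on (b - a, c - a).
#'
#' @param a,b,c numeric 3-vectors (mm), non-collinear (triangle area > 1 mm^2).
#' @return A `cp_plane` containing all three points.
#' @export
plane_from_points <- function(a, b, c) {
  a <- vec3(a); b <- vec3(b); c <- vec3(c)
  n <- cross3(b - a, c - a)
  # scale-relative collinearity test so the construction works at any scale;
  # anatomical landmark triples additionally enforce the absolute 1 mm^2
  # threshold in landmark_set()
  scale2 <- max(sum((b - a)^2), sum((c - a)^2), sum((c - b)^2))
  if (scale2 <= 0 || 0.5 * norm3(n) <= 1e-9 * scale2)
    degenerate_geometry("points are (nearly) collinear; no unique plane")
  plane(a, n)
}

#' Long axis from the landmark triple
#'
#' The axis runs from the midpoint of the two mitral-annulus points toward
#' the apex.
#'
#' @param lm a [landmark_set()].
#' @return A `cp_long_axis`.
#' @export
long_axis_from_landmarks <- function(lm) {
  stopifnot(inherits(lm, "cp_landmarks"))
  base <- (lm$septal_ma + lm$lateral_ma) / 2
  d <- lm$apex - base
  len <- norm3(d)
  if (len <= .AXIS_EPS)
    degenerate_geometry("apex coincides with the mitral-annulus midpoint")
  long_axis(base, d / len, len)
}

#' Rodrigues rotation of a vector about a unit axis
#'
#' @param v numeric 3-vector.
#' @param axis_dir unit 3-vector.
#' @param angle_deg rotation angle, degrees, right-handed about `axis_dir`.
#' @return Rotated 3-vector.
#' @export
rodrigues_rotate <- function(v, axis_dir, angle_deg) {
  v <- vec3(v); k <- unit3(vec3(axis_dir))
  th <- angle_deg * pi / 180
  v * cos(th) + cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

.plane_contains_axis <- function(p, axis, tol = 1e-6) {
  d1 <- abs(sum((axis$base - p$point) * p$normal))
  d2 <- abs(sum((axis$base + axis$direction * axis$length - p$point) * p$normal))
  d1 <= tol && d2 <= tol
}

#' Rotate a plane about the long axis
#'
#' The plane must contain the axis; the rotated plane contains it too.
#' Rotation is right-handed about `axis$direction`.
#'
#' @param p a `cp_plane` containing `axis`.
#' @param axis a `cp_long_axis`.
#' @param angle_deg rotation angle in degrees.
#' @return The rotated `cp_plane` (anchored at `axis$base`).
#' @export
rotate_plane_about_axis <- function(p, axis, angle_deg) {
  stopifnot(inherits(p, "cp_plane"), inherits(axis, "cp_long_axis"))
  if (!.plane_contains_axis(p, axis))
    stop("plane does not contain the axis", call. = FALSE)
  plane(axis$base, rodrigues_rotate(p$normal, axis$direction, angle_deg))
}

#' Plane perpendicular to the long axis at a fractional position
#'
#' @param axis a `cp_long_axis`.
#' @param fraction position along the axis in `[0, 1]`, measured from the
#'   base (MA midpoint) toward the apex.
#' @return A `cp_plane` with normal `axis$direction`.
#' @export
plane_perpendicular_to_axis <- function(axis, fraction) {
  stopifnot(inherits(axis, "cp_long_axis"))
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  plane(axis$base + fraction * axis$length * axis$direction, axis$direction)
}

#' Rotation angle about the axis carrying one plane onto another
#'
#' Inverse of [rotate_plane_about_axis()]: both planes must contain the
#' axis; the result is the right-handed rotation in `[0, 360)` degrees such
#' that rotating `p1` by it recovers `p2` (up to normal sign).
#'
#' @param p1,p2 `cp_plane`s containing `axis`.
#' @param axis a `cp_long_axis`.
#' @return Angle in degrees, `[0, 360)`.
#' @export
rotation_about_axis <- function(p1, p2, axis) {
  stopifnot(inherits(p1, "cp_plane"), inherits(p2, "cp_plane"),
            inherits(axis, "cp_long_axis"))
  if (!.plane_contains_axis(p1, axis) || !.plane_contains_axis(p2, axis))
    stop("both planes must contain the axis", call. = FALSE)
  k <- axis$direction
  # normals of axis-containing planes are perpendicular to the axis
  s <- sum(cross3(p1$normal, p2$normal) * k)
  co <- sum(p1$normal * p2$normal)
  ang <- atan2(s, co) * 180 / pi
  (ang + 360) %% 360
}

#' Unsigned point-to-plane distance
#'
#' @param pt numeric 3-vector (mm).
#' @param p a `cp_plane`.
#' @return Non-negative distance in mm.
#' @export
point_plane_distance <- function(pt, p) {
  stopifnot(inherits(p, "cp_plane"))
  abs(sum((vec3(pt) - p$point) * p$normal))
}

#' Folded dihedral angle between two planes
#'
#' Normal sign is an orientation artifact for error metrics, so the angle
#' is folded into `[0, 90]` degrees via `acos(|n1 . n2|)`.
#'
#' @param p1,p2 `cp_plane`s.
#' @return Angle in degrees, `[0, 90]`.
#' @export
angle_between_planes <- function(p1, p2) {
  stopifnot(inherits(p1, "cp_plane"), inherits(p2, "cp_plane"))
  d <- min(1, abs(sum(p1$normal * p2$normal)))
  acos(d) * 180 / pi
}

#' Project a point onto a plane
#'
#' @param pt numeric 3-vector.
#' @param p a `cp_plane`.
#' @return The foot of the perpendicular from `pt` on `p`.
#' @export
project_onto_plane <- function(pt, p) {
  pt <- vec3(pt)
  pt - sum((pt - p$point) * p$normal) * p$normal
}
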