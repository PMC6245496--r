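# Guideline plane initialization: the A4C plane through the three
# landmarks, the long axis from apex and MA midpoint, A3C/A2C rotated about
# the axis at fixed angles, and three short-axis planes at fixed fractions.

PLANE_NAMES <- c("A4C", "A3C", "A2C", "PSX_MV", "PSX_PM", "PSX_AP")
LONG_AXIS_PLANES <- c("A4C", "A3C", "A2C")
SHORT_AXIS_PLANES <- c("PSX_MV", "PSX_PM", "PSX_AP")

#' Plane-initialization configuration
#'
#' The apical three- and two-chamber planes intersect the four-chamber plane
#' at fixed rotations about the long axis; the short-axis planes sit at
#' fixed fractions along the axis from the MA midpoint toward the apex
#' (mitral valve basal, apex level apical).
#'
#' @param a3c_angle_deg rotation A4C -> A3C about the axis, degrees.
#' @param a2c_angle_deg rotation A4C -> A2C about the axis, degrees.
#' @param sax_fractions strictly increasing fractions in (0,1) for
#'   PSX_MV, PSX_PM, PSX_AP.
#' @param rotation_sense +1 for right-handed rotation about the base-to-apex
#'   direction, -1 to flip the convention.
#' @return List of class `cp_init_config`.
#' @export
init_config <- function(a3c_angle_deg = 53, a2c_angle_deg = 129,
                        sax_fractions = c(1, 3, 5) / 6, rotation_sense = 1) {
  stopifnot(a3c_angle_deg > 0, a3c_angle_deg < 360,
            a2c_angle_deg > 0, a2c_angle_deg < 360,
            length(sax_fractions) == 3L,
            all(diff(sax_fractions) > 0),
            all(sax_fractions > 0), all(sax_fractions < 1),
            rotation_sense %in% c(-1, 1))
  structure(list(a3c_angle_deg = a3c_angle_deg, a2c_angle_deg = a2c_angle_deg,
                 sax_fractions = sax_fractions, rotation_sense = rotation_sense),
            class = "cp_init_config")
}

#' Named set of the six standard planes plus the long axis
#'
#' @param planes named list of `cp_plane`s (names `A4C`, `A3C`, `A2C`,
#'   `PSX_MV`, `PSX_PM`, `PSX_AP`).
#' @param axis the shared `cp_long_axis`.
#' @return Object of class `cp_plane_set`. Construction validates that the
#'   apical planes contain the axis and that the short-axis normals align
#'   with the axis direction.
#' @export
plane_set <- function(planes, axis) {
  stopifnot(setequal(names(planes), PLANE_NAMES), inherits(axis, "cp_long_axis"))
  for (nm in LONG_AXIS_PLANES)
    if (!.plane_contains_axis(planes[[nm]], axis))
      stop(sprintf("plane %s does not contain the long axis", nm), call. = FALSE)
  for (nm in SHORT_AXIS_PLANES)
    if (abs(abs(sum(planes[[nm]]$normal * axis$direction)) - 1) > 1e-9)
      stop(sprintf("plane %s is not perpendicular to the long axis", nm),
           call. = FALSE)
  structure(list(planes = planes[PLANE_NAMES], axis = axis),
            class = "cp_plane_set")
}

#' @export
print.cp_plane_set <- function(x, ...) {
  cat("<plane set>\n")
  for (nm in PLANE_NAMES) {
    p <- x$planes[[nm]]
    cat(sprintf("  %-7s point (%7.2f, %7.2f, %7.2f)  normal (%7.4f, %7.4f, %7.4f)\n",
                nm, p$point[1], p$point[2], p$point[3],
                p$normal[1], p$normal[2], p$normal[3]))
  }
  print(x$axis)
  invisible(x)
}

#' Initialize the six standard planes from the landmark triple
#'
#' A4C passes through apex, septal MA and lateral MA; the long axis runs
#' from the MA midpoint to the apex; A3C and A2C are A4C rotated about the
#' axis by the configured angles; the short-axis planes are perpendicular to
#' the axis at the configured fractions (measured from the MA midpoint
#' toward the apex).
#'
#' @param lm a [landmark_set()].
#' @param cfg an [init_config()].
#' @return A `cp_plane_set`.
#' @export
init_planes <- function(lm, cfg = init_config()) {
  stopifnot(inherits(lm, "cp_landmarks"), inherits(cfg, "cp_init_config"))
  a4c <- plane_from_points(lm$apex, lm$septal_ma, lm$lateral_ma)
  axis <- long_axis_from_landmarks(lm)
  a4c <- plane(axis$base, a4c$normal)   # anchor on the axis
  s <- cfg$rotation_sense
  planes <- list(
    A4C = a4c,
    A3C = rotate_plane_about_axis(a4c, axis, s * cfg$a3c_angle_deg),
    A2C = rotate_plane_about_axis(a4c, axis, s * cfg$a2c_angle_deg),
    PSX_MV = plane_perpendicular_to_axis(axis, cfg$sax_fractions[1]),
    PSX_PM = plane_perpendicular_to_axis(axis, cfg$sax_fractions[2]),
    PSX_AP = plane_perpendicular_to_axis(axis, cfg$sax_fractions[3]))
  plane_set(planes, axis)
}

# --- landmark / plane JSON schema -------------------------------------------

#' Read or write landmark and plane annotations (JSON)
#'
#' Schema: `{"landmarks": {"apex": [x,y,z], "septal_ma": [..],
#' "lateral_ma": [..]}, "planes": {"A4C": {"point": [..], "normal": [..]},
#' ...}, "units": "mm"}`. Either section may be absent.
#'
#' @param path JSON file path.
#' @return `read_annotation`: list with `landmarks` (a `cp_landmarks` or
#'   NULL) and `planes` (named list of `cp_plane`s or NULL).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such annotation file: %s", path))
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) format_error(
                    sprintf("invalid JSON in %s: %s", path, conditionMessage(e))))
  lm <- NULL
  if (!is.null(obj$landmarks))
    lm <- landmark_set(obj$landmarks$apex, obj$landmarks$septal_ma,
                       obj$landmarks$lateral_ma)
  planes <- NULL
  if (!is.null(obj$planes))
    planes <- lapply(obj$planes, function(p) plane(p$point, p$normal))
  list(landmarks = lm, planes = planes)
}

#' @rdname read_annotation
#' @param landmarks a `cp_landmarks` or NULL.
#' @param planes a named list of `cp_plane`s, a `cp_plane_set`, or NULL.
#' @export
write_annotation <- function(path, landmarks = NULL, planes = NULL) {
  if (inherits(planes, "cp_plane_set")) planes <- planes$planes
  obj <- list(units = "mm")
  if (!is.null(landmarks))
    obj$landmarks <- list(apex = landmarks$apex, septal_ma = landmarks$septal_ma,
                          lateral_ma = landmarks$lateral_ma)
  if (!is.null(planes))
    obj$planes <- lapply(planes, function(p) list(point = p$point, normal = p$normal))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
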