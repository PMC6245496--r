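# Synthetic left-ventricle phantom: a truncated-ellipsoid myocardial shell
# (bright) around a dark blood pool on mid-gray background, with a brighter
# mitral-annulus ring at the base. Ground-truth landmarks and planes are
# recorded exactly, so the whole pipeline can train and validate with no
# external data.

#' Phantom specification
#'
#' Defaults model an adult LV at desk scale: 128^3 grid at 1 mm, 80 mm
#' base-to-apex length, ~31 mm mitral-annulus diameter.
#'
#' @param shape grid dimensions (voxels).
#' @param spacing voxel spacing, mm.
#' @param short_axis_mm,long_axis_mm inner (endocardial) ellipsoid half-axes.
#' @param wall_mm myocardial wall thickness.
#' @param base_frac base truncation at `w = -base_frac * long_axis_mm` below
#'   the ellipsoid center (the mitral-annulus level).
#' @param tilt_deg tilt of the LV long axis away from the grid z axis,
#'   about the x axis.
#' @param ring_radius_mm tube radius of the bright MA ring.
#' @param pap_radius_mm radius of the two papillary-muscle protrusions on
#'   the endocardial wall (0 disables them).
#' @param pap_frac axial position of the papillary muscles as a fraction of
#'   the base-to-apex length.
#' @param pap_azimuths_deg azimuths of the two papillary muscles about the
#'   long axis, measured from the A4C direction.
#' @param band_amp,band_period_mm deterministic axial intensity banding of
#'   the myocardium (relative amplitude and period), emulating the layered
#'   trabeculated texture of real myocardium; without some axial structure
#'   a short-axis plane position would be unobservable in principle.
#' @param levels named intensities: `background`, `blood`, `myocardium`,
#'   `ma_ring`.
#' @param speckle multiplicative Gaussian texture amplitude (0 = none).
#' @param jitter_theta_deg,jitter_gamma_mm half-widths of the uniform
#'   per-plane ground-truth perturbations emulating individual variation
#'   (angle for long-axis planes, axial shift for short-axis planes); set to
#'   0 for guideline-exact truth.
#' @param seed integer seed making the phantom fully deterministic.
#' @return List of class `cp_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 128L), spacing = 1,
                         short_axis_mm = 25, long_axis_mm = 45, wall_mm = 8,
                         base_frac = 0.78, tilt_deg = 8, ring_radius_mm = 2.5,
                         pap_radius_mm = 5, pap_frac = 0.45,
                         pap_azimuths_deg = c(100, 260),
                         band_amp = 0.15, band_period_mm = 22,
                         levels = c(background = 90, blood = 30,
                                    myocardium = 200, ma_ring = 240),
                         speckle = 0.15, jitter_theta_deg = 8,
                         jitter_gamma_mm = 4, seed = 1L) {
  spec <- list(shape = as.integer(rep_len(shape, 3L)),
               spacing = rep_len(as.numeric(spacing), 3L),
               short_axis_mm = short_axis_mm, long_axis_mm = long_axis_mm,
               wall_mm = wall_mm, base_frac = base_frac, tilt_deg = tilt_deg,
               ring_radius_mm = ring_radius_mm,
               pap_radius_mm = pap_radius_mm, pap_frac = pap_frac,
               pap_azimuths_deg = pap_azimuths_deg,
               band_amp = band_amp, band_period_mm = band_period_mm,
               levels = levels,
               speckle = speckle, jitter_theta_deg = jitter_theta_deg,
               jitter_gamma_mm = jitter_gamma_mm, seed = as.integer(seed))
  stopifnot(all(spec$shape >= 16L), all(spec$spacing > 0),
            short_axis_mm > 0, long_axis_mm > 0, wall_mm > 0,
            base_frac > 0, base_frac < 1,
            all(c("background", "blood", "myocardium", "ma_ring") %in% names(levels)))
  # the LV (plus wall) must fit inside the grid with a margin
  extent <- min(spec$shape * spec$spacing)
  need <- 2 * (max(short_axis_mm, long_axis_mm) + wall_mm) + 8
  if (need > extent)
    stop(sprintf("LV (%.0f mm + margin) exceeds the %.0f mm grid", need, extent),
         call. = FALSE)
  class(spec) <- "cp_phantom_spec"
  spec
}

phantom_frame <- function(spec) {
  w_hat <- rodrigues_rotate(c(0, 0, 1), c(1, 0, 0), spec$tilt_deg)
  u_hat <- unit3(c(1, 0, 0) - sum(c(1, 0, 0) * w_hat) * w_hat)
  list(w = w_hat, u = u_hat, v = cross3(w_hat, u_hat))
}

phantom_truth_geometry <- function(spec, center) {
  fr <- phantom_frame(spec)
  a <- spec$short_axis_mm; cl <- spec$long_axis_mm
  wb <- -spec$base_frac * cl
  r_ma <- a * sqrt(1 - (wb / cl)^2)
  base_center <- center + wb * fr$w
  landmark_set(apex = center + cl * fr$w,
               septal_ma = base_center + r_ma * fr$u,
               lateral_ma = base_center - r_ma * fr$u)
}

#' Generate a phantom volume with exact ground truth
#'
#' @param spec a [phantom_spec()].
#' @return List of class `cp_phantom`: `volume` (a `cp_volume`) and `truth`
#'   (class `cp_phantom_truth`: `landmarks`, `planes` named plane list,
#'   `axis`, and the per-plane `jitter` actually applied).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "cp_phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  sp <- spec$spacing
  v <- volume(array(spec$levels[["background"]], dim = d), spacing = sp)
  center <- volume_center(v)
  fr <- phantom_frame(spec)
  a <- spec$short_axis_mm; cl <- spec$long_axis_mm; th <- spec$wall_mm
  wb <- -spec$base_frac * cl
  r_ma <- a * sqrt(1 - (wb / cl)^2)

  xs <- v$origin[1] + (seq_len(d[1]) - 1) * sp[1] - center[1]
  ys <- v$origin[2] + (seq_len(d[2]) - 1) * sp[2] - center[2]
  zs <- v$origin[3] + (seq_len(d[3]) - 1) * sp[3] - center[3]
  # per-voxel LV-frame coordinates via separable outer sums
  lin <- function(e) {
    outer(outer(xs * e[1], ys * e[2], `+`), zs * e[3], `+`)
  }
  w <- lin(fr$w); u <- lin(fr$u); vv <- lin(fr$v)
  rho2 <- u^2 + vv^2
  q_in <- rho2 / a^2 + w^2 / cl^2
  q_out <- rho2 / (a + th)^2 + w^2 / (cl + th)^2
  vals <- v$data
  myo <- q_out <= 1 & q_in > 1 & w > wb
  vals[myo] <- spec$levels[["myocardium"]]
  if (spec$band_amp > 0)  # axial layering of the myocardial texture
    vals[myo] <- vals[myo] *
      (1 + spec$band_amp * sin(2 * pi * w[myo] / spec$band_period_mm))
  vals[q_in <= 1 & w > wb] <- spec$levels[["blood"]]
  if (spec$pap_radius_mm > 0) {
    # two papillary-muscle protrusions on the endocardial wall: myocardial
    # tissue bulging into the blood pool at mid-cavity level
    L <- cl - wb
    w_pap <- wb + spec$pap_frac * L
    r_endo <- a * sqrt(max(0, 1 - (w_pap / cl)^2))
    for (az in spec$pap_azimuths_deg) {
      t <- az * pi / 180
      cu <- (r_endo - 2) * cos(t)
      cv <- (r_endo - 2) * sin(t)
      pap <- (u - cu)^2 + (vv - cv)^2 + (w - w_pap)^2 <= spec$pap_radius_mm^2
      vals[pap & q_in <= 1 & w > wb] <- spec$levels[["myocardium"]]
    }
  }
  ring <- (sqrt(rho2) - r_ma)^2 + (w - wb)^2 <= spec$ring_radius_mm^2
  vals[ring] <- spec$levels[["ma_ring"]]
  if (spec$speckle > 0) {
    vals <- vals * (1 + spec$speckle * stats::rnorm(length(vals)))
    vals[vals < 0] <- 0
  }
  v$data <- array(vals, dim = d)

  lm <- phantom_truth_geometry(spec, center)
  ps <- init_planes(lm)
  jitter <- lapply(PLANE_NAMES, function(nm) c(theta = 0, gamma = 0))
  names(jitter) <- PLANE_NAMES
  if (spec$jitter_theta_deg > 0 || spec$jitter_gamma_mm > 0) {
    planes <- ps$planes
    for (nm in LONG_AXIS_PLANES) {
      jt <- stats::runif(1, -spec$jitter_theta_deg, spec$jitter_theta_deg)
      jitter[[nm]]["theta"] <- jt
      planes[[nm]] <- rotate_plane_about_axis(planes[[nm]], ps$axis, jt)
    }
    for (nm in SHORT_AXIS_PLANES) {
      jg <- stats::runif(1, -spec$jitter_gamma_mm, spec$jitter_gamma_mm)
      jitter[[nm]]["gamma"] <- jg
      planes[[nm]] <- plane(planes[[nm]]$point + jg * ps$axis$direction,
                            planes[[nm]]$normal)
    }
    ps <- plane_set(planes, ps$axis)
  }
  truth <- structure(list(landmarks = lm, planes = ps$planes, axis = ps$axis,
                          jitter = jitter),
                     class = "cp_phantom_truth")
  structure(list(volume = v, truth = truth, spec = spec), class = "cp_phantom")
}

#' Rotation + anisotropic scale augmentation
#'
#' Each pattern draws independent per-axis rotation angles and scale
#' factors, resamples the volume trilinearly about its center, maps the
#' landmarks exactly, and rebuilds the truth planes by the guideline
#' construction on the transformed landmarks with the original per-plane
#' jitter re-applied (an affine image of a plane does not generally keep
#' the axis constraints under anisotropic scaling).
#'
#' @param phantom a `cp_phantom` (or list with `volume` and `truth`).
#' @param n_patterns number of augmented copies.
#' @param seed integer seed.
#' @param angle_range rotation range per axis, degrees.
#' @param scale_range scale range per axis.
#' @return List of `cp_phantom`-like lists (`volume`, `truth`, `transform`).
#' @export
augment <- function(phantom, n_patterns = 5L, seed = 1L,
                    angle_range = c(-20, 20), scale_range = c(0.8, 1.2)) {
  stopifnot(n_patterns >= 1L)
  set.seed(seed)
  v <- phantom$volume
  ctr <- volume_center(v)
  out <- vector("list", n_patterns)
  for (i in seq_len(n_patterns)) {
    ang <- stats::runif(3, angle_range[1], angle_range[2])
    sc <- stats::runif(3, scale_range[1], scale_range[2])
    R <- rot3(ang)
    A <- function(x) ctr + as.numeric(R %*% (sc * (x - ctr)))
    Ainv_mat <- diag(1 / sc) %*% t(R)
    newdata <- resample_trilinear(v, function(world) {
      sweep(world, 2, ctr) %*% t(Ainv_mat) + matrix(ctr, nrow(world), 3, byrow = TRUE)
    })
    lm0 <- phantom$truth$landmarks
    lm <- landmark_set(A(lm0$apex), A(lm0$septal_ma), A(lm0$lateral_ma))
    ps <- init_planes(lm)
    planes <- ps$planes
    for (nm in LONG_AXIS_PLANES) {
      jt <- phantom$truth$jitter[[nm]]["theta"]
      if (jt != 0) planes[[nm]] <- rotate_plane_about_axis(planes[[nm]], ps$axis, jt)
    }
    for (nm in SHORT_AXIS_PLANES) {
      jg <- phantom$truth$jitter[[nm]]["gamma"]
      if (jg != 0) planes[[nm]] <- plane(planes[[nm]]$point + jg * ps$axis$direction,
                                         planes[[nm]]$normal)
    }
    truth <- structure(list(landmarks = lm, planes = planes, axis = ps$axis,
                            jitter = phantom$truth$jitter),
                       class = "cp_phantom_truth")
    out[[i]] <- list(volume = volume(newdata, v$spacing, v$origin),
                     truth = truth,
                     transform = list(angles_deg = ang, scales = sc, center = ctr))
  }
  out
}

# rotation matrix Rx(ax) %*% Ry(ay) %*% Rz(az), angles in degrees
rot3 <- function(angles_deg) {
  a <- angles_deg * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3)
  ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3)
  rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3)
  rx %*% ry %*% rz
}

# trilinear resampling: fn maps an n x 3 matrix of output world coordinates
# to source world coordinates; out-of-volume reads clamp to the edge
resample_trilinear <- function(v, fn) {
  d <- dim(v$data)
  lat <- as.matrix(expand.grid(x = seq_len(d[1]) - 1L, y = seq_len(d[2]) - 1L,
                               z = seq_len(d[3]) - 1L, KEEP.OUT.ATTRS = FALSE))
  world <- voxel_to_world(v, lat)
  src <- world_to_voxel(v, fn(world))
  f <- pmin(pmax(src, 0), matrix(d - 1, nrow(src), 3, byrow = TRUE))
  i0 <- floor(f)
  fr <- f - i0
  i1 <- pmin(i0 + 1, matrix(d - 1, nrow(src), 3, byrow = TRUE))
  g <- function(ix, iy, iz)
    v$data[cbind(ix + 1, iy + 1, iz + 1)]
  val <-
    g(i0[, 1], i0[, 2], i0[, 3]) * (1 - fr[, 1]) * (1 - fr[, 2]) * (1 - fr[, 3]) +
    g(i1[, 1], i0[, 2], i0[, 3]) * fr[, 1] * (1 - fr[, 2]) * (1 - fr[, 3]) +
    g(i0[, 1], i1[, 2], i0[, 3]) * (1 - fr[, 1]) * fr[, 2] * (1 - fr[, 3]) +
    g(i1[, 1], i1[, 2], i0[, 3]) * fr[, 1] * fr[, 2] * (1 - fr[, 3]) +
    g(i0[, 1], i0[, 2], i1[, 3]) * (1 - fr[, 1]) * (1 - fr[, 2]) * fr[, 3] +
    g(i1[, 1], i0[, 2], i1[, 3]) * fr[, 1] * (1 - fr[, 2]) * fr[, 3] +
    g(i0[, 1], i1[, 2], i1[, 3]) * (1 - fr[, 1]) * fr[, 2] * fr[, 3] +
    g(i1[, 1], i1[, 2], i1[, 3]) * fr[, 1] * fr[, 2] * fr[, 3]
  array(val, dim = d)
}

#' Add relative-amplitude Gaussian noise
#'
#' The base noise field is zero-mean Gaussian with variance 0.01 (sd 0.1)
#' on range-normalized intensity, i.e. a relative amplitude of 10%; the
#' level scales it linearly, so the added noise has
#' `sd = (level_percent/100) * (max - min)`. A 10% level therefore adds
#' noise whose variance on the normalized scale is exactly 0.01.
#'
#' @param v a `cp_volume`.
#' @param level_percent non-negative noise level; 0 returns the input
#'   unchanged.
#' @param seed optional integer seed.
#' @return The noisy `cp_volume`.
#' @export
add_noise <- function(v, level_percent, seed = NULL) {
  stopifnot(inherits(v, "cp_volume"))
  if (!is.finite(level_percent) || level_percent < 0)
    stop("noise level must be non-negative", call. = FALSE)
  if (level_percent == 0) return(v)
  if (!is.null(seed)) set.seed(seed)
  amp <- diff(range(v$data))
  v$data <- v$data + (level_percent / 10) * amp *
    array(stats::rnorm(length(v$data), sd = 0.1), dim = dim(v$data))
  v
}

#' Write a phantom dataset to disk
#'
#' Generates `n` phantoms (per-phantom seeds derived from `seed` by fixed
#' increments, spec fields optionally jittered within `spec_ranges`), writes
#' NIfTI volumes plus truth JSON, and a tab-separated manifest with columns
#' `file`, `truth`, `seed`, `fold`, `noise_level`.
#'
#' @param n number of phantoms.
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed.
#' @param spec a base [phantom_spec()].
#' @param spec_ranges named list of `c(min, max)` ranges for scalar spec
#'   fields to vary per phantom (e.g. `list(tilt_deg = c(0, 15))`).
#' @param n_folds number of cross-validation folds in the manifest.
#' @param noise_levels vector of noise percents; each phantom is written at
#'   every level.
#' @return The manifest as a data.frame, invisibly; also written as
#'   `manifest.tsv`.
#' @export
make_dataset <- function(n, out_dir, seed = 1L, spec = phantom_spec(),
                         spec_ranges = list(), n_folds = min(5L, n),
                         noise_levels = 0) {
  stopifnot(n >= 1L)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop(sprintf("cannot create output directory %s", out_dir), call. = FALSE)
  rows <- list()
  for (i in seq_len(n)) {
    si <- spec
    si$seed <- as.integer(seed + i)
    set.seed(si$seed)
    for (nm in names(spec_ranges)) {
      r <- spec_ranges[[nm]]
      si[[nm]] <- stats::runif(1, r[1], r[2])
    }
    ph <- generate_phantom(si)
    truth_file <- sprintf("phantom_%03d.json", i)
    write_annotation(file.path(out_dir, truth_file),
                     landmarks = ph$truth$landmarks, planes = ph$truth$planes)
    for (lev in noise_levels) {
      vol_file <- if (lev == 0) sprintf("phantom_%03d.nii.gz", i)
      else sprintf("phantom_%03d_noise%02d.nii.gz", i, as.integer(lev))
      vi <- add_noise(ph$volume, lev, seed = si$seed + 10000L)
      write_volume(vi, file.path(out_dir, vol_file))
      rows[[length(rows) + 1L]] <-
        data.frame(file = vol_file, truth = truth_file, seed = si$seed,
                   fold = ((i - 1L) %% n_folds) + 1L, noise_level = lev)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
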