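# Constrained regression-forest plane refinement. Long-axis planes (A4C,
# A3C, A2C) move only by a rotation angle theta about the fixed long axis;
# short-axis planes only by a signed translation gamma along it. Leaves
# store the object fraction C_L and the offsets phi of object patches; a
# voxel at frame-relative parameter phi_p reaching a leaf votes
# phi_t = phi_p - phi_i for every stored phi_i, and the refined parameter is
# the weighted mean phi_t_bar = sum(phi_t * C_L) / N over all N votes.

#' Refinement-forest configuration
#'
#' `theta_tau` / `gamma_tau` are the clinical maximum permissible errors
#' (10 degrees, 5 mm): positive patches come from inside those bands around
#' the ground-truth plane, negatives from the surrounding
#' `(tau, 2*tau]` band, and the test-time refinement region spans
#' `(-2*tau, 2*tau)` around the initial plane.
#'
#' @param theta_tau positive-band half-width for long-axis planes, degrees.
#' @param gamma_tau positive-band half-width for short-axis planes, mm.
#' @param n_trees,max_depth,leaf_tau,min_samples,n_tests,n_thresholds,
#'   patch_half forest parameters as in [hough_config()].
#' @param stride voxel stride inside the refinement band at test time.
#' @param n_pos,n_neg patches per volume per tree.
#' @param roi_radius_mm voxels farther than this from the axis line are
#'   ignored (the LV fits well inside by construction of the axis).
#' @param roi_axis_lo,roi_axis_hi axial extent of the region of interest as
#'   fractions of the axis length (0 = base, 1 = apex).
#' @param axis_eps_mm voxels closer than this to the axis line have no
#'   well-defined long-axis sampling plane and are excluded.
#' @return List of class `cp_refine_config`.
#' @export
refine_config <- function(theta_tau = 10, gamma_tau = 5, n_trees = 10L,
                          max_depth = 15L, leaf_tau = 0.95, patch_half = 10L,
                          min_samples = 12L, n_tests = 300L,
                          n_thresholds = 10L, stride = 2L, n_pos = 150L,
                          n_neg = 150L, roi_radius_mm = 40,
                          roi_axis_lo = -0.1, roi_axis_hi = 1.05,
                          axis_eps_mm = 2) {
  stopifnot(theta_tau > 0, gamma_tau > 0)
  structure(list(theta_tau = theta_tau, gamma_tau = gamma_tau,
                 n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 leaf_tau = leaf_tau, patch_half = as.integer(patch_half),
                 min_samples = as.integer(min_samples),
                 n_tests = as.integer(n_tests),
                 n_thresholds = as.integer(n_thresholds),
                 stride = as.integer(stride), n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), roi_radius_mm = roi_radius_mm,
                 roi_axis_lo = roi_axis_lo, roi_axis_hi = roi_axis_hi,
                 axis_eps_mm = axis_eps_mm),
            class = "cp_refine_config")
}

#' Refinement reference frame
#'
#' The volume center is the frame origin O and the x-z plane through O the
#' reference plane; for angle refinement the working reference is the plane
#' through the long axis closest to the x-z plane (their angles differ by a
#' constant, which cancels in the vote differences).
#'
#' @param v a `cp_volume` (or `cp_channels`).
#' @param axis the fixed `cp_long_axis`.
#' @return Object of class `cp_refine_frame` with `origin`, `ref_normal`,
#'   `axis` and the axis-constrained reference plane `axis_ref`.
#' @export
refine_frame <- function(v, axis) {
  stopifnot(inherits(axis, "cp_long_axis"))
  origin <- if (inherits(v, "cp_volume")) voxel_to_world(v, (dim(v$data) - 1) / 2)
  else if (inherits(v, "cp_channels")) voxel_to_world(v, (v$dim - 1) / 2)
  else vec3(v)
  ref_normal <- c(0, 1, 0)
  n_perp <- ref_normal - sum(ref_normal * axis$direction) * axis$direction
  if (norm3(n_perp) < 1e-9)
    degenerate_geometry("long axis is parallel to the reference-plane normal")
  structure(list(origin = vec3(origin), ref_normal = ref_normal,
                 axis = axis, axis_ref = plane(axis$base, n_perp)),
            class = "cp_refine_frame")
}

fold180 <- function(theta, center = 0) {
  ((theta - center + 90) %% 180) - 90 + center
}

#' Sampling plane of a voxel
#'
#' For long-axis refinement the sampling plane passes through the voxel and
#' the long axis; for short-axis refinement it is the plane through the
#' voxel perpendicular to the axis.
#'
#' @param p voxel position, world mm.
#' @param axis a `cp_long_axis`.
#' @param kind `"long"` or `"short"`.
#' @return A `cp_plane`.
#' @export
sampling_plane_of_voxel <- function(p, axis, kind = c("long", "short")) {
  kind <- match.arg(kind)
  p <- vec3(p)
  if (kind == "short") return(plane(p, axis$direction))
  u <- p - axis$base
  u_perp <- u - sum(u * axis$direction) * axis$direction
  if (norm3(u_perp) < 1e-9)
    degenerate_geometry("voxel lies on the long axis; sampling plane undefined")
  plane(axis$base, cross3(axis$direction, u_perp))
}

# signed angle (degrees, folded to (-90, 90]) from plane `ref` to plane `p`,
# both containing the axis
signed_plane_angle <- function(ref, p, axis) {
  k <- axis$direction
  s <- sum(cross3(ref$normal, p$normal) * k)
  co <- sum(ref$normal * p$normal)
  fold180(atan2(s, co) * 180 / pi)
}

#' Offset parameter between a sampling plane and a target plane
#'
#' Long kind: `theta` is the signed rotation about the axis from the target
#' to the sampling plane (degrees, folded to `(-90, 90]`), `gamma = 0`.
#' Short kind: `gamma` is the signed distance along the axis direction from
#' the target to the sampling plane (mm), `theta = 0`.
#'
#' @param sampling,target `cp_plane`s consistent with `kind`.
#' @param frame a [refine_frame()].
#' @param kind `"long"` or `"short"`.
#' @return Named numeric vector `c(theta = , gamma = )`.
#' @export
phi_between <- function(sampling, target, frame, kind = c("long", "short")) {
  kind <- match.arg(kind)
  axis <- frame$axis
  if (kind == "long") {
    if (!.plane_contains_axis(sampling, axis) || !.plane_contains_axis(target, axis))
      stop("long-kind planes must contain the axis", call. = FALSE)
    c(theta = signed_plane_angle(target, sampling, axis), gamma = 0)
  } else {
    for (p in list(sampling, target))
      if (abs(abs(sum(p$normal * axis$direction)) - 1) > 1e-6)
        stop("short-kind planes must be perpendicular to the axis", call. = FALSE)
    c(theta = 0,
      gamma = sum((sampling$point - target$point) * axis$direction))
  }
}

# --- vectorized per-voxel parameters ----------------------------------------

voxel_lattice <- function(cs, stride = 1L) {
  d <- cs$dim
  gx <- seq.int(0L, d[1] - 1L, by = stride)
  gy <- seq.int(0L, d[2] - 1L, by = stride)
  gz <- seq.int(0L, d[3] - 1L, by = stride)
  idx <- as.matrix(expand.grid(x = gx, y = gy, z = gz, KEEP.OUT.ATTRS = FALSE))
  storage.mode(idx) <- "integer"
  list(idx = idx, world = voxel_to_world(cs, idx))
}

# theta (folded signed angle, deg) of each point's long-kind sampling plane
# relative to `ref` (an axis-containing plane), plus distance rho to the axis
# line and axial fraction w/length
point_params_long <- function(world, axis, ref) {
  u <- sweep(world, 2, axis$base)
  upar <- as.numeric(u %*% axis$direction)
  uperp <- u - outer(upar, axis$direction)
  rho <- sqrt(rowSums(uperp^2))
  g <- cross3(axis$direction, ref$normal)  # in-plane direction of ref
  g <- g / norm3(g)
  co <- as.numeric(uperp %*% g)
  # s = dot(cross(g, uperp), dir)
  s <- as.numeric((cbind(g[2] * uperp[, 3] - g[3] * uperp[, 2],
                         g[3] * uperp[, 1] - g[1] * uperp[, 3],
                         g[1] * uperp[, 2] - g[2] * uperp[, 1])) %*% axis$direction)
  theta <- fold180(atan2(s, co) * 180 / pi)
  list(theta = theta, rho = rho, frac = upar / axis$length)
}

point_params_short <- function(world, axis, ref_point) {
  u <- sweep(world, 2, axis$base)
  upar <- as.numeric(u %*% axis$direction)
  uperp2 <- rowSums(u^2) - upar^2
  gamma <- as.numeric(sweep(world, 2, vec3(ref_point)) %*% axis$direction)
  list(gamma = gamma, rho = sqrt(pmax(uperp2, 0)), frac = upar / axis$length)
}

roi_mask <- function(pp, cfg) {
  pp$rho <= cfg$roi_radius_mm & pp$frac >= cfg$roi_axis_lo &
    pp$frac <= cfg$roi_axis_hi
}

#' Sample refinement training patches for one volume
#'
#' Positive centers are voxels whose sampling plane lies within the
#' `theta_tau` (long) or `gamma_tau` (short) band of the ground-truth plane;
#' negatives come from the surrounding `(tau, 2*tau]` band. Each patch
#' stores its exact offset parameter phi.
#'
#' @param x a `cp_volume` or `cp_channels`.
#' @param gt_plane ground-truth `cp_plane`.
#' @param frame a [refine_frame()].
#' @param kind `"long"` or `"short"`.
#' @param cfg a [refine_config()].
#' @param n_pos,n_neg patch counts (defaults from `cfg`).
#' @param seed optional integer seed.
#' @return A `cp_patches` with 1-column `offsets` holding phi (degrees for
#'   long, mm for short).
#' @export
sample_refine_patches <- function(x, gt_plane, frame, kind = c("long", "short"),
                                  cfg = refine_config(), n_pos = cfg$n_pos,
                                  n_neg = cfg$n_neg, seed = NULL) {
  kind <- match.arg(kind)
  cs <- as_channels(x)
  if (!is.null(seed)) set.seed(seed)
  cand <- refine_band_candidates(cs, gt_plane, frame, kind, cfg)
  sample_from_band(cand, n_pos, n_neg)
}

# voxel lattice indices and exact phi for the positive band and the
# surrounding negative band of one ground-truth plane; computed once per
# (volume, plane) and reused across trees
refine_band_candidates <- function(cs, gt_plane, frame, kind, cfg) {
  lat <- voxel_lattice(cs, 1L)
  axis <- frame$axis
  if (kind == "long") {
    pp <- point_params_long(lat$world, axis, gt_plane)
    phi <- pp$theta
    tau <- cfg$theta_tau
    ok <- roi_mask(pp, cfg) & pp$rho > cfg$axis_eps_mm
  } else {
    pp <- point_params_short(lat$world, axis, gt_plane$point)
    phi <- pp$gamma
    tau <- cfg$gamma_tau
    ok <- roi_mask(pp, cfg)
  }
  pos_ok <- which(ok & abs(phi) < tau)
  neg_ok <- which(ok & abs(phi) > tau & abs(phi) <= 2 * tau)
  if (length(pos_ok) == 0L || length(neg_ok) == 0L)
    stop("empty sampling band: ground-truth plane barely intersects the volume",
         call. = FALSE)
  list(idx = lat$idx, phi = phi, pos_ok = pos_ok, neg_ok = neg_ok)
}

sample_from_band <- function(cand, n_pos, n_neg) {
  ip <- cand$pos_ok[ceiling(stats::runif(n_pos) * length(cand$pos_ok))]
  ineg <- cand$neg_ok[ceiling(stats::runif(n_neg) * length(cand$neg_ok))]
  sel <- c(ip, ineg)
  structure(list(centers = cand$idx[sel, , drop = FALSE],
                 labels = c(rep(1L, n_pos), rep(0L, n_neg)),
                 offsets = matrix(cand$phi[sel], ncol = 1),
                 vol_id = rep(1L, n_pos + n_neg)),
            class = "cp_patches")
}

#' Class-label and offset uncertainties of a refinement patch set
#'
#' `V1` has the same form as the detection class uncertainty; `V2` is the
#' summed squared deviation of phi from the object-patch mean (object
#' patches only).
#'
#' @param patches a `cp_patches` (1-column offsets).
#' @return Named numeric vector `c(V1 = , V2 = )`.
#' @export
refine_uncertainties <- function(patches) {
  c(V1 = class_uncertainty(patches), V2 = offset_uncertainty(patches))
}

#' Train a constrained refinement forest for one standard plane
#'
#' Trees are grown exactly as detection trees but on refinement patches:
#' candidate tests are scored by V1 or V2 (random choice per node) and
#' leaves store `C_L` plus the phi list of object patches.
#'
#' @param volumes list of `cp_volume` or `cp_channels`.
#' @param gt_planes list of ground-truth `cp_plane`s, one per volume.
#' @param frames list of [refine_frame()]s (volume center + that volume's
#'   ground-truth axis).
#' @param kind `"long"` or `"short"`.
#' @param cfg a [refine_config()].
#' @param seed master integer seed.
#' @return Object of class `cp_refine_forest`.
#' @export
train_refine_forest <- function(volumes, gt_planes, frames,
                                kind = c("long", "short"),
                                cfg = refine_config(), seed = 1L) {
  kind <- match.arg(kind)
  if (length(volumes) == 0L) stop("empty training set", call. = FALSE)
  stopifnot(length(volumes) == length(gt_planes),
            length(volumes) == length(frames))
  stacks <- lapply(volumes, as_channels)
  sc <- stacks_for_cpp(stacks)
  bands <- lapply(seq_along(stacks), function(i)
    refine_band_candidates(stacks[[i]], gt_planes[[i]], frames[[i]], kind, cfg))
  trees <- vector("list", cfg$n_trees)
  for (t in seq_len(cfg$n_trees)) {
    set.seed(seed + t)
    pl <- lapply(bands, sample_from_band, n_pos = cfg$n_pos, n_neg = cfg$n_neg)
    patches <- combine_patches(pl)
    tree <- cp_grow_tree(sc$ch, sc$dims, patches$vol_id - 1L, patches$centers,
                         patches$labels, patches$offsets, cfg$patch_half,
                         cfg$max_depth, cfg$min_samples, cfg$n_tests,
                         cfg$n_thresholds)
    trees[[t]] <- structure(tree, class = "cp_tree")
  }
  structure(list(trees = trees, config = cfg, kind = kind,
                 spacing = stacks[[1]]$spacing, k = 1L,
                 patch_half = cfg$patch_half),
            class = "cp_refine_forest")
}

#' @export
print.cp_refine_forest <- function(x, ...) {
  cat(sprintf("<refinement forest> kind %s, %d trees\n", x$kind, length(x$trees)))
  invisible(x)
}

refine_no_votes <- function(msg) {
  warning(warningCondition(msg, class = c("cardioplane_no_votes",
                                          "cardioplane_warning")))
}

#' Refine one plane with a constrained regression forest
#'
#' Voxels whose sampling plane lies within `(-2*tau, 2*tau)` of the initial
#' plane are routed through the forest; each reached leaf with
#' `C_L >= leaf_tau` emits one vote `phi_t = phi_p - phi_i` per stored
#' `phi_i`, weighted `C_L`, and the refined frame-relative parameter is the
#' C_L-weighted mean of the votes (which therefore always lies within the
#' emitted vote range). With zero votes the initial plane is returned with
#' a warning.
#'
#' @param x a `cp_volume` or `cp_channels`.
#' @param init_plane the initial `cp_plane`.
#' @param frame a [refine_frame()] (with the fixed axis).
#' @param forest a `cp_refine_forest`.
#' @param cfg optional [refine_config()] override.
#' @return The refined `cp_plane` (attribute `n_votes` carries N).
#' @export
refine_plane <- function(x, init_plane, frame, forest, cfg = forest$config) {
  stopifnot(inherits(forest, "cp_refine_forest"))
  kind <- forest$kind
  cs <- as_channels(x)
  axis <- frame$axis
  lat <- voxel_lattice(cs, cfg$stride)
  if (kind == "long") {
    # frame-relative theta of every voxel, on the branch centered at the
    # initial plane's own theta so the +/-90 fold cannot split the band
    theta_init <- signed_plane_angle(frame$axis_ref, init_plane, axis)
    pp <- point_params_long(lat$world, axis, frame$axis_ref)
    phip <- fold180(pp$theta, center = theta_init)
    rel <- phip - theta_init
    tau <- cfg$theta_tau
    ok <- roi_mask(pp, cfg) & pp$rho > cfg$axis_eps_mm
  } else {
    gamma_init <- sum((init_plane$point - frame$origin) * axis$direction)
    pp <- point_params_short(lat$world, axis, frame$origin)
    phip <- pp$gamma
    rel <- phip - gamma_init
    tau <- cfg$gamma_tau
    ok <- roi_mask(pp, cfg)
  }
  sel <- which(ok & abs(rel) < 2 * tau)
  S <- 0; W <- 0; N <- 0
  if (length(sel)) {
    centers <- lat$idx[sel, , drop = FALSE]
    phis <- phip[sel]
    chans <- lapply(cs$channels, as.numeric)
    for (tree in forest$trees) {
      nodes <- cp_route(chans, as.integer(cs$dim), tree, centers)
      nl <- tree$off_count[nodes]
      cl <- tree$cl[nodes]
      use <- cl >= cfg$leaf_tau & nl > 0
      if (!any(use)) next
      # per-node sum of stored phi values
      node_ids <- which(tree$is_leaf == 1L & tree$off_count > 0L)
      sums <- vapply(node_ids, function(nd)
        sum(tree$leaf_off[tree$off_start[nd] + seq_len(tree$off_count[nd]), 1]),
        numeric(1))
      sum_by_node <- numeric(length(tree$is_leaf))
      sum_by_node[node_ids] <- sums
      S <- S + sum(cl[use] * (nl[use] * phis[use] - sum_by_node[nodes[use]]))
      W <- W + sum(cl[use] * nl[use])
      N <- N + sum(nl[use])
    }
  }
  if (N == 0) {
    refine_no_votes(sprintf("no refinement votes for %s-kind plane; returning the initial plane", kind))
    out <- init_plane
    attr(out, "n_votes") <- 0
    return(out)
  }
  phit <- S / W
  out <- if (kind == "long")
    rotate_plane_about_axis(frame$axis_ref, axis, phit)
  else
    plane(frame$origin + phit * axis$direction, axis$direction)
  attr(out, "n_votes") <- N
  out
}

#' Refine all six standard planes
#'
#' Long-axis planes are refined in angle about the fixed axis, short-axis
#' planes in signed distance along it; the axis itself is never changed. A
#' failing plane is passed through unrefined with a warning.
#'
#' @param x a `cp_volume` or `cp_channels`.
#' @param planes a `cp_plane_set` (initialized planes + axis).
#' @param frame a [refine_frame()] built on the same axis.
#' @param models named list of `cp_refine_forest`s, one per plane name.
#' @return The refined `cp_plane_set`.
#' @export
refine_all <- function(x, planes, frame, models) {
  stopifnot(inherits(planes, "cp_plane_set"))
  cs <- as_channels(x)
  out <- planes$planes
  for (nm in PLANE_NAMES) {
    if (is.null(models[[nm]])) {
      warning(sprintf("no refinement model for %s; plane left at its initial location", nm))
      next
    }
    out[[nm]] <- tryCatch(
      refine_plane(cs, planes$planes[[nm]], frame, models[[nm]]),
      error = function(e) {
        warning(sprintf("refinement of %s failed (%s); plane left at its initial location",
                        nm, conditionMessage(e)))
        planes$planes[[nm]]
      })
    attr(out[[nm]], "n_votes") <- NULL
  }
  plane_set(out, planes$axis)
}
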