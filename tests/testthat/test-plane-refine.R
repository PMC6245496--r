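# Unit-level checks of the constrained refinement machinery on tiny
# volumes; the parameter-recovery experiments live in test-acceptance.R.

axis_z <- function() long_axis(c(0, 0, 0), c(0, 0, 1), 80)

frame_for <- function(v, axis = axis_z()) refine_frame(v, axis)

test_that("sampling planes pass through the voxel and respect the kind constraint", {
  ax <- axis_z()
  s <- sampling_plane_of_voxel(c(10, 0, 30), ax, "short")
  expect_equal(s$normal, c(0, 0, 1))
  expect_equal(point_plane_distance(c(10, 0, 30), s), 0)

  l <- sampling_plane_of_voxel(c(10, 5, 30), ax, "long")
  expect_lt(point_plane_distance(ax$base, l), 1e-9)
  expect_lt(point_plane_distance(ax$base + 80 * ax$direction, l), 1e-9)
  expect_lt(point_plane_distance(c(10, 5, 30), l), 1e-9)
  expect_error(sampling_plane_of_voxel(c(0, 0, 30), ax, "long"),
               class = "cardioplane_degenerate")

  # agreement with the three-point construction
  set.seed(71)
  for (i in 1:50) {
    p <- random_point(40)
    if (sqrt(sum(p[1:2]^2)) < 1) next
    l1 <- sampling_plane_of_voxel(p, ax, "long")
    l2 <- plane_from_points(ax$base, ax$base + ax$direction * 10, p)
    expect_equal(abs(sum(l1$normal * l2$normal)), 1, tolerance = 1e-9)
  }
})

test_that("phi between planes is signed, antisymmetric and kind-consistent", {
  v <- volume(array(0, dim = c(32, 32, 32)), spacing = 2)
  fr <- frame_for(v)
  ax <- fr$axis
  # short: planes 7 mm apart along the axis
  a <- plane(c(0, 0, 30), ax$direction)
  b <- plane(c(0, 0, 37), ax$direction)
  expect_equal(phi_between(b, a, fr, "short"), c(theta = 0, gamma = 7))
  expect_equal(phi_between(a, b, fr, "short"), c(theta = 0, gamma = -7))
  expect_equal(phi_between(a, a, fr, "short"), c(theta = 0, gamma = 0))
  # long: rotations about the axis
  p0 <- plane(ax$base, c(0, 1, 0))
  p1 <- rotate_plane_about_axis(p0, ax, 12)
  ph <- phi_between(p1, p0, fr, "long")
  expect_equal(unname(ph["theta"]), 12, tolerance = 1e-9)
  expect_equal(unname(ph["gamma"]), 0)
  expect_equal(phi_between(p0, p1, fr, "long")["theta"], c(theta = -12),
               tolerance = 1e-9)
  # kind mismatch errors
  expect_error(phi_between(a, p0, fr, "long"), "axis")
  expect_error(phi_between(p0, a, fr, "short"), "perpendicular")
})

test_that("refinement uncertainties reproduce direct formula evaluation", {
  mk <- function(phis, labels) structure(list(
    centers = matrix(0L, length(labels), 3), labels = as.integer(labels),
    offsets = matrix(phis, ncol = 1), vol_id = rep(1L, length(labels))),
    class = "cp_patches")
  pure <- mk(c(1, 2, 3), c(1, 1, 1))
  expect_equal(unname(refine_uncertainties(pure)["V1"]), 0)
  two <- mk(c(-2, 2), c(1, 1))
  expect_equal(unname(refine_uncertainties(two)["V2"]), 8)
  # background patches do not affect V2
  mixed <- mk(c(-2, 2, 17, -40), c(1, 1, 0, 0))
  expect_equal(unname(refine_uncertainties(mixed)["V2"]), 8)
  expect_equal(unname(refine_uncertainties(mixed)["V1"]), 4 * log(2))
})

# small phantom used by band-sampling and end-to-end refinement checks
refine_phantom <- function(seed = 3) {
  generate_phantom(phantom_spec(shape = c(48, 48, 48), spacing = 2,
                                short_axis_mm = 20, long_axis_mm = 34,
                                wall_mm = 7, jitter_theta_deg = 0,
                                jitter_gamma_mm = 0, seed = seed))
}

test_that("refinement patches respect the positive and negative bands", {
  ph <- refine_phantom()
  fr <- refine_frame(ph$volume, ph$truth$axis)
  cfg <- refine_config(n_pos = 60, n_neg = 60, roi_radius_mm = 35)
  for (kind in c("long", "short")) {
    gt <- if (kind == "long") ph$truth$planes$A4C else ph$truth$planes$PSX_PM
    ps <- sample_refine_patches(ph$volume, gt, fr, kind, cfg, seed = 5)
    tau <- if (kind == "long") cfg$theta_tau else cfg$gamma_tau
    phis <- ps$offsets[, 1]
    expect_true(all(abs(phis[ps$labels == 1]) < tau))
    expect_true(all(abs(phis[ps$labels == 0]) > tau &
                      abs(phis[ps$labels == 0]) <= 2 * tau))
    # stored phi equals the recomputed offset of the voxel's sampling plane
    for (i in sample(seq_along(phis), 10)) {
      world <- voxel_to_world(ph$volume, ps$centers[i, ])
      sp <- sampling_plane_of_voxel(world, fr$axis, kind)
      ref <- phi_between(sp, gt, fr, kind)
      comp <- if (kind == "long") "theta" else "gamma"
      expect_equal(abs(unname(ref[comp])), abs(phis[i]), tolerance = 1e-6)
    }
    # determinism
    ps2 <- sample_refine_patches(ph$volume, gt, fr, kind, cfg, seed = 5)
    expect_identical(ps, ps2)
  }
})

test_that("refinement training replays leaf phi lists and is seed-deterministic", {
  ph <- refine_phantom()
  cs <- compute_channels(ph$volume)
  fr <- refine_frame(ph$volume, ph$truth$axis)
  cfg <- refine_config(n_trees = 2, max_depth = 8, n_pos = 40, n_neg = 40,
                       min_samples = 6, n_tests = 60, roi_radius_mm = 35)
  f1 <- train_refine_forest(list(cs), list(ph$truth$planes$PSX_PM), list(fr),
                            "short", cfg, seed = 21)
  f2 <- train_refine_forest(list(cs), list(ph$truth$planes$PSX_PM), list(fr),
                            "short", cfg, seed = 21)
  expect_identical(f1$trees, f2$trees)
  cfg1 <- cfg; cfg1$n_trees <- 1L
  fa <- train_refine_forest(list(cs), list(ph$truth$planes$PSX_PM), list(fr),
                            "short", cfg1, seed = 21)
  expect_identical(fa$trees[[1]], f1$trees[[1]])

  # replay: resample the same patches and route them down the built tree
  set.seed(21 + 1)
  band <- cardioplane:::refine_band_candidates(cs, ph$truth$planes$PSX_PM, fr,
                                               "short", cfg)
  patches <- cardioplane:::sample_from_band(band, cfg$n_pos, cfg$n_neg)
  tree <- f1$trees[[1]]
  leaf_of <- vapply(seq_len(nrow(patches$centers)), function(i)
    route_patch(cs, patches$centers[i, ], tree), 1L)
  for (nd in unique(leaf_of)) {
    here <- leaf_of == nd
    expect_equal(tree$cl[nd], mean(patches$labels[here]))
    stored <- sort(tree$leaf_off[tree$off_start[nd] + seq_len(tree$off_count[nd]), 1])
    expect_equal(stored, sort(patches$offsets[here & patches$labels == 1L, 1]))
  }
})

test_that("the refined parameter is the weighted mean of emitted votes", {
  # hand-built forest: every voxel reaches a single leaf with two stored
  # phi values; votes are phi_p - phi_i, so offsets {-4, -8} from voxels at
  # phi_p = 0 give votes {4, 8} and a refined angle of 6 degrees
  ph <- refine_phantom()
  fr <- refine_frame(ph$volume, ph$truth$axis)
  tree <- structure(list(
    channel = -1L, ax = 0L, ay = 0L, az = 0L, bx = 0L, by = 0L, bz = 0L,
    threshold = 0, left = 0L, right = 0L, is_leaf = 1L, cl = 1.0,
    n_samples = 2L, off_start = 0L, off_count = 2L,
    leaf_off = matrix(c(-4, -8), 2)), class = "cp_tree")
  cfg <- refine_config(n_trees = 1, stride = 4, roi_radius_mm = 35)
  forest <- structure(list(trees = list(tree), config = cfg, kind = "long",
                           spacing = ph$volume$spacing, k = 1L,
                           patch_half = cfg$patch_half),
                      class = "cp_refine_forest")
  init <- fr$axis_ref   # theta_init = 0; votes are (voxel theta) - phi_i
  out <- refine_plane(ph$volume, init, fr, forest)
  got <- unname(phi_between(out, fr$axis_ref, fr, "long")["theta"])
  # the voting band is symmetric about theta = 0 up to voxel discretization,
  # so the mean vote is 6 degrees plus a sub-0.1-degree band asymmetry
  expect_equal(got, 6, tolerance = 0.02)
  # boundedness: the weighted mean lies inside the emitted vote range
  # (votes span theta_p - phi_i with |theta_p| < 20)
  expect_gte(got, 4 - 20)
  expect_lte(got, 8 + 20)

  # leaves storing phi_i = 0 reproduce the initial plane (band-center
  # symmetry), again up to discretization
  tree0 <- tree; tree0$leaf_off <- matrix(c(0, 0), 2)
  forest0 <- forest; forest0$trees <- list(structure(tree0, class = "cp_tree"))
  out0 <- refine_plane(ph$volume, init, fr, forest0)
  expect_equal(angle_between_planes(out0, init), 0, tolerance = 0.05)
})

test_that("constraint preservation and no-vote passthrough hold in refine_all", {
  ph <- refine_phantom()
  cs <- compute_channels(ph$volume)
  fr <- refine_frame(ph$volume, ph$truth$axis)
  cfg <- refine_config(n_trees = 1, max_depth = 6, n_pos = 30, n_neg = 30,
                       min_samples = 6, n_tests = 40, roi_radius_mm = 35)
  models <- list()
  for (nm in c("A4C", "A3C", "A2C"))
    models[[nm]] <- train_refine_forest(list(cs), list(ph$truth$planes[[nm]]),
                                        list(fr), "long", cfg, seed = 31)
  for (nm in c("PSX_MV", "PSX_PM", "PSX_AP"))
    models[[nm]] <- train_refine_forest(list(cs), list(ph$truth$planes[[nm]]),
                                        list(fr), "short", cfg, seed = 32)
  init <- init_planes(ph$truth$landmarks)
  out <- refine_all(cs, init, fr, models)
  ax <- out$axis
  expect_identical(ax, init$axis)   # the long axis is never refined
  for (nm in c("A4C", "A3C", "A2C")) {
    expect_lt(point_plane_distance(ax$base, out$planes[[nm]]), 1e-6)
    expect_lt(point_plane_distance(ax$base + ax$length * ax$direction,
                                   out$planes[[nm]]), 1e-6)
  }
  for (nm in c("PSX_MV", "PSX_PM", "PSX_AP"))
    expect_equal(abs(sum(out$planes[[nm]]$normal * ax$direction)), 1,
                 tolerance = 1e-12)

  # a forest whose leaves never pass the threshold yields a no-vote warning
  # and returns the initial plane unchanged
  dead_tree <- structure(list(
    channel = -1L, ax = 0L, ay = 0L, az = 0L, bx = 0L, by = 0L, bz = 0L,
    threshold = 0, left = 0L, right = 0L, is_leaf = 1L, cl = 0.1,
    n_samples = 2L, off_start = 0L, off_count = 1L,
    leaf_off = matrix(0, 1)), class = "cp_tree")
  dead <- structure(list(trees = list(dead_tree), config = cfg, kind = "long",
                         spacing = ph$volume$spacing, k = 1L,
                         patch_half = cfg$patch_half),
                    class = "cp_refine_forest")
  expect_warning(out2 <- refine_plane(cs, init$planes$A4C, fr, dead),
                 class = "cardioplane_no_votes")
  expect_equal(out2$normal, init$planes$A4C$normal)
})
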