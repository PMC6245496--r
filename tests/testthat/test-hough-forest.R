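# Tiny volumes and forests: the compiled training/voting paths are checked
# against independent R oracles (direct formula evaluation, replayed
# routing, exhaustive vote accumulation).

# two-cluster toy volume: bright blob of radius 2 at `at`, dark elsewhere
toy_volume <- function(d = c(16, 16, 16), at = c(8, 8, 8)) {
  a <- array(0, dim = d)
  idx <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  r2 <- rowSums(sweep(idx, 2, at + 1)^2)
  a[idx[r2 <= 4, , drop = FALSE]] <- 1
  volume(a)
}

test_that("class uncertainty matches direct evaluation of the entropy formula", {
  expect_equal(class_uncertainty(rep(1L, 5)), 0)
  expect_equal(class_uncertainty(c(1L, 1L, 0L, 0L)), 4 * log(2))
  expect_equal(class_uncertainty(c(1L, 1L, 1L, 0L)),
               -4 * (0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_equal(class_uncertainty(c(1L, 1L, 1L, 0L)), 2.249341, tolerance = 1e-6)
  expect_error(class_uncertainty(integer(0)), "empty")
  # brute-force oracle on seeded random label sets
  set.seed(61)
  for (i in 1:200) {
    lab <- rbinom(sample(2:20, 1), 1, runif(1))
    p1 <- mean(lab); p0 <- 1 - p1
    ent <- 0
    if (p1 > 0) ent <- ent + p1 * log(p1)
    if (p0 > 0) ent <- ent + p0 * log(p0)
    expect_equal(class_uncertainty(lab), -length(lab) * ent)
  }
})

test_that("offset uncertainty sums squared deviations of object patches only", {
  expect_equal(offset_uncertainty(matrix(c(0, 0, 0), 1)), 0)
  expect_equal(offset_uncertainty(rbind(c(0, 0, 0), c(2, 0, 0))), 2)
  # background patches do not change the value
  off <- rbind(c(0, 0, 0), c(2, 0, 0), c(50, 50, 50), c(-9, 4, 1))
  lab <- c(1L, 1L, 0L, 0L)
  expect_equal(offset_uncertainty(off, lab), 2)
  expect_error(offset_uncertainty(off, c(0L, 0L, 0L, 0L)), "object")
  set.seed(62)
  for (i in 1:100) {
    n <- sample(2:15, 1)
    off <- matrix(rnorm(3 * n), ncol = 3)
    lab <- c(1L, rbinom(n - 1, 1, 0.5))
    obj <- off[lab == 1, , drop = FALSE]
    oracle <- sum(sweep(obj, 2, colMeans(obj))^2)
    expect_equal(offset_uncertainty(off, lab), oracle)
  }
})

test_that("detection patch sampling is deterministic, labeled and box-consistent", {
  v <- toy_volume()
  truth <- c(8, 8, 8)   # world == voxel (unit spacing)
  p1 <- sample_detection_patches(v, truth, bbox_half_mm = 3, n_pos = 30,
                                 n_neg = 20, seed = 99)
  p2 <- sample_detection_patches(v, truth, bbox_half_mm = 3, n_pos = 30,
                                 n_neg = 20, seed = 99)
  expect_identical(p1, p2)
  expect_equal(p1$labels, c(rep(1L, 30), rep(0L, 20)))
  # positive patches: center - d = truth; negatives outside the box
  pos <- p1$centers[1:30, ] - p1$offsets[1:30, ]
  expect_true(all(abs(sweep(pos, 2, truth)) < 1e-9))
  expect_true(all(abs(p1$centers[1:30, ] - 8) <= 3))
  neg <- p1$centers[31:50, ]
  expect_true(all(apply(abs(sweep(neg, 2, c(8, 8, 8))), 1, max) > 3))
  # n_neg = 0: all labels positive
  p0 <- sample_detection_patches(v, truth, 3, 10, 0, seed = 1)
  expect_true(all(p0$labels == 1L))
  expect_warning(sample_detection_patches(v, c(1, 1, 1), 5, 5, 5, seed = 1),
                 "clipped")
})

test_that("a linearly separable toy set grows a shallow pure tree", {
  v <- toy_volume()
  cs <- compute_channels(v)
  # object patches on the bright blob, background in the dark corner
  centers <- rbind(matrix(rep(c(8, 8, 8), 10), ncol = 3, byrow = TRUE),
                   matrix(rep(c(2, 2, 2), 10), ncol = 3, byrow = TRUE))
  patches <- structure(list(
    centers = matrix(as.integer(centers), ncol = 3),
    labels = c(rep(1L, 10), rep(0L, 10)),
    offsets = matrix(0, 20, 3), vol_id = rep(1L, 20)), class = "cp_patches")
  tree <- grow_tree(list(cs), patches, hough_config(min_samples = 4), seed = 5)
  leaves1 <- vapply(1:10, function(i) route_patch(cs, centers[i, ], tree), 1L)
  leaves0 <- vapply(11:20, function(i) route_patch(cs, centers[i, ], tree), 1L)
  expect_true(all(tree$cl[leaves1] == 1))
  expect_true(all(tree$cl[leaves0] == 0))
  # identical-appearance patches: no test separates them, root stays a leaf
  same <- structure(list(
    centers = matrix(rep(c(2L, 2L, 2L), 8), ncol = 3, byrow = TRUE),
    labels = rep(c(1L, 0L), 4), offsets = matrix(0, 8, 3),
    vol_id = rep(1L, 8)), class = "cp_patches")
  t2 <- grow_tree(list(cs), same, hough_config(min_samples = 2), seed = 6)
  expect_equal(length(t2$is_leaf), 1L)
  expect_equal(t2$cl[1], 0.5)
})

test_that("leaf statistics replay exactly when training patches are rerouted", {
  set.seed(63)
  v <- random_volume(c(14, 14, 14))
  cs <- compute_channels(v)
  patches <- sample_detection_patches(cs, c(7, 7, 7), 3, 40, 40, seed = 7)
  tree <- grow_tree(list(cs), patches, hough_config(min_samples = 6), seed = 8)
  leaf_of <- vapply(seq_len(nrow(patches$centers)), function(i)
    route_patch(cs, patches$centers[i, ], tree), 1L)
  for (nd in unique(leaf_of)) {
    here <- leaf_of == nd
    expect_equal(tree$cl[nd], mean(patches$labels[here]))
    expect_equal(tree$n_samples[nd], sum(here))
    # stored offsets are exactly the object-patch offsets routed here
    stored <- tree$leaf_off[tree$off_start[nd] + seq_len(tree$off_count[nd]), ,
                            drop = FALSE]
    mine <- patches$offsets[here & patches$labels == 1L, , drop = FALSE]
    expect_equal(stored[order(stored[, 1], stored[, 2], stored[, 3]), , drop = FALSE],
                 unname(mine[order(mine[, 1], mine[, 2], mine[, 3]), , drop = FALSE]))
  }
})

test_that("the chosen split never increases the node uncertainty", {
  # U1 and U2 are both within-partition sums minimized over candidates, so
  # any kept split must not exceed the unsplit value; verify by replaying
  # internal nodes of a grown tree
  set.seed(64)
  v <- random_volume(c(14, 14, 14))
  cs <- compute_channels(v)
  patches <- sample_detection_patches(cs, c(7, 7, 7), 3, 50, 50, seed = 9)
  tree <- grow_tree(list(cs), patches, hough_config(min_samples = 6), seed = 10)
  leaf_of <- vapply(seq_len(nrow(patches$centers)), function(i)
    route_patch(cs, patches$centers[i, ], tree), 1L)
  # walk each patch's root path to collect node membership
  membership <- vector("list", length(tree$is_leaf))
  for (i in seq_len(nrow(patches$centers))) {
    nd <- 1L
    repeat {
      membership[[nd]] <- c(membership[[nd]], i)
      if (tree$is_leaf[nd]) break
      a <- cardioplane:::channel_value(cs, tree$channel[nd] + 1L,
                                       patches$centers[i, ] + c(tree$ax[nd], tree$ay[nd], tree$az[nd]))
      b <- cardioplane:::channel_value(cs, tree$channel[nd] + 1L,
                                       patches$centers[i, ] + c(tree$bx[nd], tree$by[nd], tree$bz[nd]))
      nd <- if (a - b > tree$threshold[nd]) tree$right[nd] else tree$left[nd]
    }
  }
  for (nd in which(tree$is_leaf == 0L)) {
    ids <- membership[[nd]]
    l <- membership[[tree$left[nd]]]
    r <- membership[[tree$right[nd]]]
    u1 <- function(ii) if (length(ii)) class_uncertainty(patches$labels[ii]) else 0
    expect_lte(u1(l) + u1(r), u1(ids) + 1e-9)
  }
})

test_that("vote accumulation matches the exhaustive double-loop oracle", {
  set.seed(65)
  v <- toy_volume(c(12, 12, 12), at = c(6, 6, 6))
  cs <- compute_channels(v)
  patches <- sample_detection_patches(cs, c(6, 6, 6), 2, 25, 25, seed = 11)
  cfg <- hough_config(n_trees = 2, min_samples = 5, leaf_tau = 0.95,
                      smooth_sigma = 0, bbox_half_mm = 2, n_pos = 25,
                      n_neg = 25)
  forest <- train_forest(list(cs), list(c(6, 6, 6)), cfg, seed = 12)
  m <- cast_votes(cs, forest, stride = 1, smooth = FALSE)
  # brute force: loop every voxel through every tree in R
  acc <- array(0, dim = c(12, 12, 12))
  for (x in 0:11) for (y in 0:11) for (z in 0:11) {
    for (tree in forest$trees) {
      nd <- route_patch(cs, c(x, y, z), tree)
      if (tree$cl[nd] < cfg$leaf_tau || tree$off_count[nd] == 0) next
      w <- tree$cl[nd] / tree$off_count[nd]
      offs <- tree$leaf_off[tree$off_start[nd] + seq_len(tree$off_count[nd]), ,
                            drop = FALSE]
      for (j in seq_len(nrow(offs))) {
        q <- round(c(x, y, z) - offs[j, ])
        if (all(q >= 0) && all(q <= 11))
          acc[q[1] + 1, q[2] + 1, q[3] + 1] <- acc[q[1] + 1, q[2] + 1, q[3] + 1] + w
      }
    }
  }
  expect_equal(array(m$acc, dim = dim(acc)), acc, tolerance = 1e-12)
  # vote-mass conservation: border-kept votes sum to the C_L totals
  expect_equal(sum(m$acc), sum(acc))
})

test_that("sub-threshold leaves contribute nothing", {
  # hand-built single-node trees: one above, one below the leaf threshold
  mk_tree <- function(cl) structure(list(
    channel = -1L, ax = 0L, ay = 0L, az = 0L, bx = 0L, by = 0L, bz = 0L,
    threshold = 0, left = 0L, right = 0L, is_leaf = 1L, cl = cl,
    n_samples = 10L, off_start = 0L, off_count = 1L,
    leaf_off = matrix(c(-1, 0, 0), 1)), class = "cp_tree")
  cs <- compute_channels(volume(array(0, dim = c(6, 6, 6))))
  cfg <- hough_config(n_trees = 1, smooth_sigma = 0)
  f_hi <- structure(list(trees = list(mk_tree(1.0)), config = cfg,
                         level = "fine", spacing = c(1, 1, 1), k = 3L,
                         patch_half = 7L), class = "cp_forest")
  f_lo <- structure(list(trees = list(mk_tree(0.5)), config = cfg,
                         level = "fine", spacing = c(1, 1, 1), k = 3L,
                         patch_half = 7L), class = "cp_forest")
  # stride 6 leaves a single voting voxel p = (0,0,0); the leaf offset
  # d = (-1,0,0) sends its one vote (weight C_L = 1) to p - d = (1,0,0)
  m_hi <- cast_votes(cs, f_hi, stride = 6, smooth = FALSE)
  m_lo <- cast_votes(cs, f_lo, stride = 6, smooth = FALSE)
  expect_equal(sum(m_hi$acc), 1)
  expect_equal(detect_point(m_hi), c(1, 0, 0))
  expect_equal(sum(m_lo$acc), 0)
  expect_error(detect_point(m_lo), class = "cardioplane_no_detection")
  # votes landing outside the region are dropped
  m_drop <- cast_votes(cs, f_hi, region = list(lo = c(2, 2, 2), hi = c(2, 2, 2)),
                       stride = 1, smooth = FALSE)
  expect_equal(sum(m_drop$acc), 0)
})

test_that("vote-map argmax picks the first voxel in storage order on ties", {
  m <- structure(list(acc = array(0, dim = c(4, 4, 4)), origin = c(0, 0, 0),
                      spacing = c(1, 1, 1), lo = c(0L, 0L, 0L),
                      examined = 64, raw_mass = 2), class = "cp_vote_map")
  m$acc[2, 3, 1] <- 5; m$acc[4, 3, 2] <- 5
  expect_equal(detect_point(m), c(1, 2, 0))
  m$acc[1, 1, 4] <- 7
  expect_equal(detect_point(m), c(0, 0, 3))
})

test_that("training is deterministic and serialization reproduces identical votes", {
  set.seed(66)
  v <- toy_volume(c(14, 14, 14), at = c(7, 7, 7))
  cfg <- hough_config(n_trees = 2, max_depth = 8, n_pos = 25, n_neg = 25,
                      min_samples = 5, bbox_half_mm = 3)
  f1 <- train_forest(list(v), list(c(7, 7, 7)), cfg, seed = 31)
  f2 <- train_forest(list(v), list(c(7, 7, 7)), cfg, seed = 31)
  expect_identical(f1$trees, f2$trees)
  f3 <- train_forest(list(v), list(c(7, 7, 7)), cfg, seed = 32)
  expect_false(identical(f1$trees, f3$trees))
  # single-tree forest equals the one grown with the same derived seed
  cfg1 <- cfg; cfg1$n_trees <- 1L
  fa <- train_forest(list(v), list(c(7, 7, 7)), cfg1, seed = 31)
  expect_identical(fa$trees[[1]], f1$trees[[1]])

  path <- withr::local_tempfile(fileext = ".rds")
  write_model(f1, path)
  fr <- read_model(path)
  m1 <- cast_votes(v, f1, smooth = FALSE)
  m2 <- cast_votes(v, fr, smooth = FALSE)
  expect_identical(m1$acc, m2$acc)
  expect_error(read_model("nope.rds"), class = "cardioplane_model")
  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), junk)
  expect_error(read_model(junk), class = "cardioplane_model")
})

test_that("hierarchical search equals plain detection when the neighborhood covers everything", {
  set.seed(67)
  v <- toy_volume(c(16, 16, 16), at = c(9, 8, 8))
  cfg <- hough_config(n_trees = 3, max_depth = 8, n_pos = 30, n_neg = 30,
                      min_samples = 5, bbox_half_mm = 3, downsample_factor = 2,
                      patch_half_coarse = 3, neighborhood_mm = 100,
                      stride_fine = 1)
  truth <- list(c(9, 8, 8))
  co <- train_forest(list(v), truth, cfg, seed = 41, level = "coarse")
  fi <- train_forest(list(v), truth, cfg, seed = 42, level = "fine")
  pt_h <- hierarchical_detect(v, co, fi, cfg)
  pt_s <- detect_single_scale(v, fi)
  expect_equal(as.numeric(pt_h), as.numeric(pt_s))
  expect_lte(attr(pt_h, "examined_fine"), 16^3)
  # repeat runs are bit-identical
  pt_h2 <- hierarchical_detect(v, co, fi, cfg)
  expect_identical(as.numeric(pt_h), as.numeric(pt_h2))
})

test_that("fine-level voxel count respects the neighborhood bound", {
  set.seed(68)
  v <- toy_volume(c(16, 16, 16), at = c(8, 8, 8))
  cfg <- hough_config(n_trees = 2, max_depth = 6, n_pos = 20, n_neg = 20,
                      min_samples = 5, bbox_half_mm = 3, downsample_factor = 2,
                      patch_half_coarse = 3, neighborhood_mm = 3,
                      stride_fine = 1)
  co <- train_forest(list(v), list(c(8, 8, 8)), cfg, seed = 43, level = "coarse")
  fi <- train_forest(list(v), list(c(8, 8, 8)), cfg, seed = 44, level = "fine")
  pt <- hierarchical_detect(v, co, fi, cfg)
  expect_lte(attr(pt, "examined_fine"), (2 * 3 + 2)^3)
})
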