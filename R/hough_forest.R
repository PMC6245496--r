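# 3-D Hough forests: per-landmark randomized trees whose leaves store the
# fraction of object patches C_L and the offsets D_L from patch centers to
# the landmark; detection is the argmax of a probabilistic vote map, run
# coarse-to-fine.

#' Hough-forest configuration
#'
#' Defaults follow the reference operating point (10 trees, depth 15, leaf
#' threshold 0.95); the sampling/voting knobs are desk-scale choices and all
#' configurable.
#'
#' @param n_trees number of trees per forest.
#' @param max_depth maximum tree depth.
#' @param leaf_tau minimum object fraction C_L for a leaf to vote.
#' @param patch_half_fine,patch_half_coarse patch half-width in voxels at the
#'   two pyramid levels (patch extent `2*half + 1` per axis).
#' @param min_samples nodes with fewer patches become leaves.
#' @param n_tests,n_thresholds candidate binary tests per node and thresholds
#'   per test.
#' @param downsample_factor integer pyramid factor for the coarse level.
#' @param smooth_sigma Gaussian smoothing of vote maps, voxels (0 = off).
#' @param stride_coarse,stride_fine voting stride at the two levels.
#' @param n_pos,n_neg patches sampled per volume per tree.
#' @param bbox_half_mm half-width of the positive bounding box around the
#'   ground-truth landmark, mm.
#' @param neighborhood_mm half-width of the fine-level search cube around the
#'   coarse detection, mm.
#' @return A list of class `cp_hough_config`.
#' @export
hough_config <- function(n_trees = 10L, max_depth = 15L, leaf_tau = 0.95,
                         patch_half_fine = 7L, patch_half_coarse = 4L,
                         min_samples = 20L, n_tests = 200L, n_thresholds = 10L,
                         downsample_factor = 4L, smooth_sigma = 2,
                         stride_coarse = 1L, stride_fine = 2L,
                         n_pos = 50L, n_neg = 50L, bbox_half_mm = 10,
                         neighborhood_mm = 16) {
  cfg <- list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
              leaf_tau = leaf_tau, patch_half_fine = as.integer(patch_half_fine),
              patch_half_coarse = as.integer(patch_half_coarse),
              min_samples = as.integer(min_samples),
              n_tests = as.integer(n_tests),
              n_thresholds = as.integer(n_thresholds),
              downsample_factor = as.integer(downsample_factor),
              smooth_sigma = smooth_sigma,
              stride_coarse = as.integer(stride_coarse),
              stride_fine = as.integer(stride_fine),
              n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              bbox_half_mm = bbox_half_mm, neighborhood_mm = neighborhood_mm)
  stopifnot(cfg$n_trees >= 1L, cfg$max_depth >= 1L,
            cfg$leaf_tau >= 0, cfg$leaf_tau <= 1, cfg$downsample_factor >= 2L)
  class(cfg) <- "cp_hough_config"
  cfg
}

patch_half_for <- function(config, level) {
  if (level == "coarse") config$patch_half_coarse else config$patch_half_fine
}

#' Sample detection training patches for one volume
#'
#' Positive patch centers are drawn uniformly from the bounding box around
#' the ground-truth landmark and carry the offset of the patch from the
#' landmark, `d = center - truth` (voxel units), so that a test voxel `p`
#' reaching a leaf votes for the landmark at `p - d`; negative centers are
#' drawn uniformly from the rest of the volume with label 0. A box
#' extending beyond the volume is clipped with a warning.
#'
#' @param x a `cp_volume` or `cp_channels`.
#' @param truth ground-truth landmark, world mm.
#' @param bbox_half_mm positive-region half-width in mm.
#' @param n_pos,n_neg number of positive/negative patches.
#' @param seed integer seed (`set.seed` is called when non-NULL).
#' @return A list of class `cp_patches` with `centers` (n x 3, 0-based
#'   voxels), `labels`, `offsets` (n x 3, voxels) and `vol_id`.
#' @export
sample_detection_patches <- function(x, truth, bbox_half_mm, n_pos, n_neg,
                                     seed = NULL) {
  cs <- as_channels(x)
  if (!is.null(seed)) set.seed(seed)
  d <- cs$dim
  tv <- world_to_voxel(cs, vec3(truth))
  if (any(tv < 0) || any(tv > d - 1))
    stop("ground-truth landmark lies outside the volume", call. = FALSE)
  half <- bbox_half_mm / cs$spacing
  lo <- ceiling(tv - half)
  hi <- floor(tv + half)
  if (any(lo < 0) || any(hi > d - 1)) {
    warning("positive bounding box clipped to the volume extent")
    lo <- pmax(lo, 0)
    hi <- pmin(hi, d - 1)
  }
  if (n_neg > 0 && prod(hi - lo + 1) >= prod(d))
    stop("negative region is empty: the positive box covers the whole volume",
         call. = FALSE)
  rint <- function(n, a, b) a + floor(stats::runif(n) * (b - a + 1))
  pos <- cbind(rint(n_pos, lo[1], hi[1]), rint(n_pos, lo[2], hi[2]),
               rint(n_pos, lo[3], hi[3]))
  neg <- matrix(0, 0, 3)
  while (nrow(neg) < n_neg) {
    m <- max(16L, 2L * (n_neg - nrow(neg)))
    cand <- cbind(rint(m, 0, d[1] - 1), rint(m, 0, d[2] - 1),
                  rint(m, 0, d[3] - 1))
    inside <- cand[, 1] >= lo[1] & cand[, 1] <= hi[1] &
      cand[, 2] >= lo[2] & cand[, 2] <= hi[2] &
      cand[, 3] >= lo[3] & cand[, 3] <= hi[3]
    neg <- rbind(neg, cand[!inside, , drop = FALSE])
  }
  neg <- neg[seq_len(n_neg), , drop = FALSE]
  centers <- rbind(pos, neg)
  offsets <- centers - matrix(rep(tv, each = nrow(centers)), ncol = 3)
  offsets[seq_len(n_neg) + n_pos, ] <- 0   # stored but never voted
  structure(list(centers = matrix(as.integer(centers), ncol = 3),
                 labels = c(rep(1L, n_pos), rep(0L, n_neg)),
                 offsets = offsets,
                 vol_id = rep(1L, n_pos + n_neg)),
            class = "cp_patches")
}

patch_labels <- function(patches) {
  if (inherits(patches, "cp_patches")) patches$labels else as.integer(patches)
}

#' Class-label uncertainty of a patch set
#'
#' `U1(A) = -|A| * sum_c p(c|A) log p(c|A)` with `0 log 0 = 0`.
#'
#' @param patches a `cp_patches` object or an integer label vector.
#' @return Non-negative scalar.
#' @export
class_uncertainty <- function(patches) {
  lab <- patch_labels(patches)
  if (length(lab) == 0L) stop("empty patch set", call. = FALSE)
  p <- table(lab) / length(lab)
  -length(lab) * sum(ifelse(p > 0, p * log(p), 0))
}

#' Offset uncertainty of a patch set
#'
#' Sum over object patches of the squared Euclidean deviation of the offset
#' from the object-patch mean; background patches are ignored.
#'
#' @param patches a `cp_patches` object, or a numeric offset matrix when
#'   `labels` is given.
#' @param labels optional label vector matching the rows of `patches`.
#' @return Non-negative scalar.
#' @export
offset_uncertainty <- function(patches, labels = NULL) {
  if (inherits(patches, "cp_patches")) {
    off <- patches$offsets
    lab <- patches$labels
  } else {
    off <- as.matrix(patches)
    lab <- if (is.null(labels)) rep(1L, nrow(off)) else as.integer(labels)
  }
  obj <- off[lab == 1L, , drop = FALSE]
  if (nrow(obj) == 0L) stop("no object patches", call. = FALSE)
  ctr <- colMeans(obj)
  sum(sweep(obj, 2, ctr)^2)
}

combine_patches <- function(patch_list) {
  centers <- do.call(rbind, lapply(patch_list, `[[`, "centers"))
  offsets <- do.call(rbind, lapply(patch_list, `[[`, "offsets"))
  labels <- unlist(lapply(patch_list, `[[`, "labels"))
  vol_id <- unlist(lapply(seq_along(patch_list),
                          function(i) rep(i, length(patch_list[[i]]$labels))))
  structure(list(centers = centers, labels = as.integer(labels),
                 offsets = offsets, vol_id = as.integer(vol_id)),
            class = "cp_patches")
}

stacks_for_cpp <- function(stacks) {
  list(ch = lapply(stacks, function(s) lapply(s$channels, as.numeric)),
       dims = do.call(rbind, lapply(stacks, function(s) as.integer(s$dim))))
}

#' Grow a single randomized tree
#'
#' At each node a pool of candidate binary tests (random channel, two random
#' in-patch offsets, random thresholds spanning the empirical difference
#' range) is scored by the split uncertainty; whether the class-label or the
#' offset uncertainty is minimized is chosen uniformly at random per node
#' (class-label forced when fewer than two object patches are present).
#' Leaves store the object fraction `C_L` and the object-patch offsets.
#'
#' @param stacks list of `cp_channels`, one per training volume.
#' @param patches a combined `cp_patches` with `vol_id` indexing `stacks`.
#' @param config a [hough_config()].
#' @param seed integer seed, or NULL to continue the current RNG stream.
#' @param level `"fine"` or `"coarse"` (selects the patch extent).
#' @return A flattened tree (list of node arrays) of class `cp_tree`.
#' @export
grow_tree <- function(stacks, patches, config = hough_config(), seed = NULL,
                      level = "fine") {
  if (!is.null(seed)) set.seed(seed)
  sc <- stacks_for_cpp(stacks)
  tree <- cp_grow_tree(sc$ch, sc$dims, patches$vol_id - 1L, patches$centers,
                       patches$labels, patches$offsets,
                       patch_half_for(config, level), config$max_depth,
                       config$min_samples, config$n_tests, config$n_thresholds)
  structure(tree, class = "cp_tree")
}

#' Route a patch center through a tree (reference path)
#'
#' Pure-R routing used for replay checks; mirrors the compiled router.
#'
#' @param cs a `cp_channels`.
#' @param center 0-based voxel index.
#' @param tree a `cp_tree`.
#' @return 1-based node index of the reached leaf.
#' @export
route_patch <- function(cs, center, tree) {
  node <- 1L
  while (!tree$is_leaf[node]) {
    a <- channel_value(cs, tree$channel[node] + 1L,
                       center + c(tree$ax[node], tree$ay[node], tree$az[node]))
    b <- channel_value(cs, tree$channel[node] + 1L,
                       center + c(tree$bx[node], tree$by[node], tree$bz[node]))
    node <- if (a - b > tree$threshold[node]) tree$right[node] else tree$left[node]
  }
  node
}

#' Train a Hough forest for one landmark at one pyramid level
#'
#' Each tree is grown on an independent, freshly sampled patch set (per-tree
#' seeds derived from `seed` by fixed increments).
#'
#' @param volumes list of `cp_volume` (full resolution) or `cp_channels`
#'   already at the target level's resolution.
#' @param truths list of ground-truth landmark positions, world mm.
#' @param config a [hough_config()].
#' @param seed master integer seed.
#' @param level `"fine"` (original resolution) or `"coarse"` (volumes are
#'   block-mean downsampled by `config$downsample_factor` first).
#' @return Object of class `cp_forest`.
#' @export
train_forest <- function(volumes, truths, config = hough_config(), seed = 1L,
                         level = c("fine", "coarse")) {
  level <- match.arg(level)
  if (length(volumes) == 0L) stop("empty training set", call. = FALSE)
  stopifnot(length(volumes) == length(truths))
  stacks <- lapply(volumes, function(v) {
    if (inherits(v, "cp_channels")) return(v)
    if (level == "coarse") v <- downsample(v, config$downsample_factor)
    compute_channels(v)
  })
  trees <- vector("list", config$n_trees)
  for (t in seq_len(config$n_trees)) {
    set.seed(seed + t)
    pl <- lapply(seq_along(stacks), function(i)
      sample_detection_patches(stacks[[i]], truths[[i]], config$bbox_half_mm,
                               config$n_pos, config$n_neg, seed = NULL))
    trees[[t]] <- grow_tree(stacks, combine_patches(pl), config, seed = NULL,
                            level = level)
  }
  structure(list(trees = trees, config = config, level = level,
                 spacing = stacks[[1]]$spacing, k = 3L,
                 patch_half = patch_half_for(config, level)),
            class = "cp_forest")
}

#' @export
print.cp_forest <- function(x, ...) {
  cat(sprintf("<hough forest> %d trees, level %s, %d--%d nodes\n",
              length(x$trees), x$level,
              min(vapply(x$trees, function(t) length(t$is_leaf), 1L)),
              max(vapply(x$trees, function(t) length(t$is_leaf), 1L))))
  invisible(x)
}

#' Cast probabilistic Hough votes over a region
#'
#' Every voxel on the stride lattice inside `region` is routed through every
#' tree; each reached leaf with `C_L >= leaf_tau` deposits weight
#' `C_L / |D_L|` at `p - d` for every stored offset `d` (votes landing
#' outside the region are dropped). The accumulator is optionally Gaussian
#' smoothed.
#'
#' @param x a `cp_volume` or `cp_channels`.
#' @param forest a `cp_forest`.
#' @param region list with 0-based inclusive voxel bounds `lo`, `hi`
#'   (default: the whole volume).
#' @param stride voting stride in voxels (default from the forest's level).
#' @param smooth apply `gaussian_smooth3` with `config$smooth_sigma`.
#' @return Object of class `cp_vote_map`: accumulator array plus world
#'   geometry and the number of voxels examined.
#' @export
cast_votes <- function(x, forest, region = NULL, stride = NULL, smooth = TRUE) {
  cs <- as_channels(x)
  cfg <- forest$config
  if (max(abs(cs$spacing - forest$spacing)) > 1e-6)
    warning("volume spacing differs from the forest's training spacing")
  if (is.null(region)) region <- list(lo = c(0L, 0L, 0L), hi = cs$dim - 1L)
  lo <- as.integer(region$lo); hi <- as.integer(region$hi)
  if (any(hi < lo) || any(lo < 0) || any(hi > cs$dim - 1L))
    stop("empty or out-of-bounds voting region", call. = FALSE)
  if (is.null(stride))
    stride <- if (forest$level == "coarse") cfg$stride_coarse else cfg$stride_fine
  res <- cp_cast_votes(lapply(cs$channels, as.numeric), as.integer(cs$dim),
                       forest$trees, lo, hi, as.integer(stride), cfg$leaf_tau)
  acc <- array(res$acc, dim = hi - lo + 1L)
  raw_mass <- sum(acc)
  if (smooth && cfg$smooth_sigma > 0) acc <- gaussian_smooth3(acc, cfg$smooth_sigma)
  structure(list(acc = acc, origin = voxel_to_world(cs, lo),
                 spacing = cs$spacing, lo = lo, examined = res$examined,
                 raw_mass = raw_mass),
            class = "cp_vote_map")
}

no_detection <- function(msg) {
  stop(errorCondition(msg, class = c("cardioplane_no_detection", "cardioplane_error")))
}

#' Detected point of a vote map
#'
#' The world coordinate of the accumulator argmax; ties break to the first
#' voxel in array storage order (x fastest).
#'
#' @param m a `cp_vote_map`.
#' @return Length-3 world coordinate (mm).
#' @export
detect_point <- function(m) {
  stopifnot(inherits(m, "cp_vote_map"))
  if (all(m$acc == 0)) no_detection("vote map is identically zero")
  i <- which.max(m$acc) - 1L
  d <- dim(m$acc)
  idx <- c(i %% d[1], (i %/% d[1]) %% d[2], i %/% (d[1] * d[2]))
  m$origin + idx * m$spacing
}

#' Precompute fine and coarse channel stacks for a volume
#'
#' @param v a `cp_volume`.
#' @param config a [hough_config()].
#' @return List of class `cp_multires` with `fine` and `coarse` stacks.
#' @export
prepare_volume <- function(v, config = hough_config()) {
  structure(list(fine = compute_channels(v),
                 coarse = compute_channels(downsample(v, config$downsample_factor))),
            class = "cp_multires")
}

as_multires <- function(x, config) {
  if (inherits(x, "cp_multires")) x else prepare_volume(x, config)
}

#' Hierarchical coarse-to-fine landmark detection
#'
#' A coarse forest votes over the whole downsampled volume; the fine forest
#' then votes only inside a cubic neighborhood of the coarse detection at
#' full resolution.
#'
#' @param x a `cp_volume` or a [prepare_volume()] result.
#' @param coarse_forest,fine_forest `cp_forest`s trained at the two levels.
#' @param config a [hough_config()]; `neighborhood_mm` sets the fine search
#'   cube half-width.
#' @return World coordinate of the detected point, with attributes
#'   `examined_fine`, `examined_coarse` and `coarse_point`.
#' @export
hierarchical_detect <- function(x, coarse_forest, fine_forest,
                                config = fine_forest$config) {
  prep <- as_multires(x, config)
  cm <- cast_votes(prep$coarse, coarse_forest)
  p0 <- detect_point(cm)
  cs <- prep$fine
  half <- config$neighborhood_mm / cs$spacing
  v0 <- world_to_voxel(cs, p0)
  lo <- pmax(floor(v0 - half), 0)
  hi <- pmin(ceiling(v0 + half), cs$dim - 1)
  fm <- cast_votes(cs, fine_forest, region = list(lo = lo, hi = hi))
  pt <- detect_point(fm)
  attr(pt, "examined_fine") <- fm$examined
  attr(pt, "examined_coarse") <- cm$examined
  attr(pt, "coarse_point") <- p0
  pt
}

#' Single-scale full-resolution detection (reference baseline)
#'
#' Votes with the fine-level forest over the whole volume at stride 1; used
#' to quantify what the hierarchical search saves.
#'
#' @param x a `cp_volume`, `cp_channels` or `cp_multires`.
#' @param fine_forest a fine-level `cp_forest`.
#' @return Detected world point with attribute `examined`.
#' @export
detect_single_scale <- function(x, fine_forest) {
  cs <- if (inherits(x, "cp_multires")) x$fine else as_channels(x)
  m <- cast_votes(cs, fine_forest, stride = 1L)
  pt <- detect_point(m)
  attr(pt, "examined") <- m$examined
  pt
}

LANDMARK_NAMES <- c("apex", "septal_ma", "lateral_ma")

#' Detect the three anatomical landmarks
#'
#' Runs [hierarchical_detect()] serially for the apex, septal MA and lateral
#' MA using per-landmark coarse+fine forests.
#'
#' @param x a `cp_volume` or [prepare_volume()] result.
#' @param models named list with one entry per landmark, each a list with
#'   elements `coarse` and `fine` (`cp_forest`s).
#' @param config optional [hough_config()] override.
#' @return A [landmark_set()], with per-landmark `examined_fine` counts in
#'   attribute `examined`.
#' @export
detect_landmarks <- function(x, models, config = NULL) {
  missing <- setdiff(LANDMARK_NAMES, names(models))
  if (length(missing))
    stop(sprintf("missing detector model(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  cfg <- if (is.null(config)) models[[1]]$fine$config else config
  prep <- as_multires(x, cfg)
  pts <- list()
  examined <- c()
  for (nm in LANDMARK_NAMES) {
    pts[[nm]] <- tryCatch(
      hierarchical_detect(prep, models[[nm]]$coarse, models[[nm]]$fine,
                          if (is.null(config)) models[[nm]]$fine$config else config),
      cardioplane_no_detection = function(e)
        stop(sprintf("landmark '%s' not detected: %s", nm, conditionMessage(e)),
             call. = FALSE))
    examined[nm] <- attr(pts[[nm]], "examined_fine")
  }
  lm <- landmark_set(as.numeric(pts$apex), as.numeric(pts$septal_ma),
                     as.numeric(pts$lateral_ma))
  attr(lm, "examined") <- examined
  lm
}

# --- model persistence -------------------------------------------------------

MODEL_FORMAT <- "cardioplane-model"
MODEL_VERSION <- 1L

model_error <- function(msg) {
  stop(errorCondition(msg, class = c("cardioplane_model", "cardioplane_error")))
}

#' Write or read a trained model
#'
#' Single-file serialization with a format tag and version; the payload
#' holds the config block and the flattened per-tree node arrays.
#'
#' @param model any trained model object (`cp_forest`, refinement forest, or
#'   a named list of them).
#' @param path file path (conventionally `.rds`).
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  saveRDS(list(format = MODEL_FORMAT, version = MODEL_VERSION,
               class = class(model), model = model),
          path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) model_error(sprintf("no such model file: %s", path))
  obj <- tryCatch(readRDS(path), error = function(e)
    model_error(sprintf("unreadable model file %s: %s", path, conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT))
    model_error(sprintf("%s is not a cardioplane model file", path))
  if (obj$version > MODEL_VERSION)
    model_error(sprintf("model version %d is newer than supported (%d)",
                        obj$version, MODEL_VERSION))
  obj$model
}
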