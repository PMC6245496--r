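# End-to-end pipeline: landmark detection -> guideline initialization ->
# constrained refinement, plus a convenience trainer that builds every
# model from a list of annotated volumes (e.g. phantoms).

#' Train all detection and refinement models
#'
#' Trains one coarse + one fine Hough forest per landmark and one
#' refinement forest per standard plane from annotated volumes.
#'
#' @param volumes list of `cp_volume`.
#' @param truths list of truths; each needs `landmarks` (a `cp_landmarks`)
#'   and, for refiner training, `planes` (named plane list) and `axis`.
#' @param hough_cfg a [hough_config()].
#' @param refine_cfg a [refine_config()]; NULL skips refiner training.
#' @param seed master seed; per-model seeds are derived by fixed increments.
#' @param verbose print per-stage progress.
#' @return List with `detectors` (per landmark: `coarse`, `fine`),
#'   `refiners` (per plane) and `init_cfg`.
#' @export
train_pipeline <- function(volumes, truths, hough_cfg = hough_config(),
                           refine_cfg = refine_config(), seed = 1L,
                           verbose = FALSE) {
  stopifnot(length(volumes) == length(truths), length(volumes) >= 1L)
  say <- function(...) if (verbose) message(sprintf(...))
  fine_stacks <- lapply(volumes, as_channels)
  coarse_stacks <- lapply(volumes, function(v)
    compute_channels(downsample(v, hough_cfg$downsample_factor)))
  detectors <- list()
  for (i in seq_along(LANDMARK_NAMES)) {
    nm <- LANDMARK_NAMES[i]
    pts <- lapply(truths, function(tr) tr$landmarks[[nm]])
    say("training detector %s (coarse)", nm)
    co <- train_forest(coarse_stacks, pts, hough_cfg,
                       seed = seed + 100L * i, level = "coarse")
    say("training detector %s (fine)", nm)
    fi <- train_forest(fine_stacks, pts, hough_cfg,
                       seed = seed + 100L * i + 50L, level = "fine")
    detectors[[nm]] <- list(coarse = co, fine = fi)
  }
  refiners <- NULL
  if (!is.null(refine_cfg)) {
    frames <- lapply(seq_along(volumes), function(i)
      refine_frame(volumes[[i]], truths[[i]]$axis))
    refiners <- list()
    for (j in seq_along(PLANE_NAMES)) {
      nm <- PLANE_NAMES[j]
      kind <- if (nm %in% LONG_AXIS_PLANES) "long" else "short"
      gts <- lapply(truths, function(tr) tr$planes[[nm]])
      say("training refiner %s (%s)", nm, kind)
      refiners[[nm]] <- train_refine_forest(fine_stacks, gts, frames, kind,
                                            refine_cfg, seed = seed + 1000L * j)
    }
  }
  list(detectors = detectors, refiners = refiners, init_cfg = init_config())
}

#' Extract the six standard planes from a volume
#'
#' Runs the three pipeline stages in order: hierarchical landmark
#' detection, guideline plane initialization, and (optionally) constrained
#' regression-forest refinement with the long axis fixed.
#'
#' @param v a `cp_volume`.
#' @param models a [train_pipeline()] result (or equivalently structured
#'   list; `refiners` may be NULL).
#' @param refine run the refinement stage (requires `models$refiners`).
#' @param init_cfg an [init_config()].
#' @return List of class `cp_extraction`: `landmarks`, `planes` (a
#'   `cp_plane_set`), and a per-stage `report` (wall times in seconds, fine
#'   voxels examined per landmark, refinement vote counts).
#' @export
extract_planes <- function(v, models, refine = TRUE,
                           init_cfg = models$init_cfg %||% init_config()) {
  stopifnot(inherits(v, "cp_volume"))
  report <- list()
  t0 <- proc.time()[["elapsed"]]
  cfg <- models$detectors[[1]]$fine$config
  prep <- prepare_volume(v, cfg)
  lm <- detect_landmarks(prep, models$detectors)
  report$detect <- list(seconds = proc.time()[["elapsed"]] - t0,
                        examined_fine = attr(lm, "examined"))
  t1 <- proc.time()[["elapsed"]]
  planes <- init_planes(lm, init_cfg)
  report$init <- list(seconds = proc.time()[["elapsed"]] - t1)
  if (refine) {
    if (is.null(models$refiners))
      stop("refine = TRUE but the model set has no refiners", call. = FALSE)
    t2 <- proc.time()[["elapsed"]]
    frame <- refine_frame(v, planes$axis)
    planes <- refine_all(prep$fine, planes, frame, models$refiners)
    report$refine <- list(seconds = proc.time()[["elapsed"]] - t2)
  }
  structure(list(landmarks = lm, planes = planes, report = report),
            class = "cp_extraction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cp_extraction <- function(x, ...) {
  cat("<extraction>\n landmarks:\n")
  print(x$landmarks)
  print(x$planes)
  secs <- vapply(x$report, function(s) s$seconds, numeric(1))
  cat(sprintf(" stages: %s\n",
              paste(sprintf("%s %.2fs", names(secs), secs), collapse = ", ")))
  invisible(x)
}
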