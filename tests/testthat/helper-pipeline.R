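# Small shared end-to-end fixture: a handful of 48^3 phantoms and a
# reduced-size model set, trained once per test session.

.pipeline_cache <- new.env(parent = emptyenv())

mini_phantom_spec <- function(seed) {
  phantom_spec(shape = c(48, 48, 48), spacing = 2, short_axis_mm = 20,
               long_axis_mm = 34, wall_mm = 7,
               jitter_theta_deg = 4, jitter_gamma_mm = 2, seed = seed)
}

mini_hough_config <- function() {
  hough_config(n_trees = 4L, max_depth = 10L, n_pos = 40L, n_neg = 40L,
               min_samples = 8L, n_tests = 100L, downsample_factor = 4L,
               patch_half_coarse = 3L)
}

mini_refine_config <- function() {
  refine_config(n_trees = 4L, max_depth = 10L, n_pos = 60L, n_neg = 60L,
                min_samples = 8L, n_tests = 100L, roi_radius_mm = 35)
}

mini_models <- function() {
  if (is.null(.pipeline_cache$models)) {
    phantoms <- lapply(1:4, function(i) generate_phantom(mini_phantom_spec(i)))
    .pipeline_cache$phantoms <- phantoms
    .pipeline_cache$models <- train_pipeline(
      lapply(phantoms, `[[`, "volume"), lapply(phantoms, `[[`, "truth"),
      hough_cfg = mini_hough_config(), refine_cfg = mini_refine_config(),
      seed = 7)
  }
  list(models = .pipeline_cache$models, phantoms = .pipeline_cache$phantoms)
}
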