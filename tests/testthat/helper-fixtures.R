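# Shared fixtures: hand-built slab grids for solver harness tests, a
# reduced-resolution run configuration for pipeline-level tests, and a
# one-time cache of the full 5-subject training build.

# A layered slab voxel_grid built directly (no electrode layout needed for
# full-face harness tests).
make_slab_grid <- function(sigma_layers, thickness_mm, cells_per_layer,
                           nx = 6, ny = 6, dx_mm = 1) {
  dz <- numeric(0); layer_index <- integer(0)
  for (i in seq_along(thickness_mm)) {
    dz <- c(dz, rep(thickness_mm[i] / cells_per_layer[i], cells_per_layer[i]))
    layer_index <- c(layer_index, rep(i, cells_per_layer[i]))
  }
  zedge <- cumsum(c(0, dz))
  zc <- (zedge[-1] + zedge[-length(zedge)]) / 2
  nz <- length(zc)
  xc <- (seq_len(nx) - (nx + 1) / 2) * dx_mm
  yc <- (seq_len(ny) - (ny + 1) / 2) * dx_mm
  sigma <- array(rep(sigma_layers[layer_index], each = nx * ny),
                 dim = c(nx, ny, nz))
  structure(
    list(xc = xc, yc = yc, zc = zc, dx = dx_mm, dy = dx_mm, dz = dz,
         layer_index = layer_index, sigma = sigma, layout = NULL,
         config = NULL, subject = NULL, frequency_hz = 5000),
    class = "voxel_grid")
}

# Reduced-resolution configuration for fast pipeline-level tests.
quick_run_config <- function() {
  cfg <- default_run_config()
  cfg$solver$dx_mm <- 1.4
  cfg$solver$layer_cells <- c(2L, 2L, 3L, 4L)
  cfg$fiber$n_nodes <- 9L
  cfg$waveform$window_us <- 400
  cfg
}

# Table-driven training cohort (packaged descriptor CSV).
training_subjects <- function() {
  read_subjects_csv(system.file("extdata", "training_subjects.csv",
                                package = "pcsrank"))
}

# One-time cache of expensive artifacts shared across test files.
.test_cache <- new.env(parent = emptyenv())

cached_training_samples <- function() {
  if (is.null(.test_cache$samples))
    .test_cache$samples <- build_training_set(training_subjects(),
                                              feature_pipeline())
  .test_cache$samples
}

cached_cv_report <- function() {
  if (is.null(.test_cache$cv))
    .test_cache$cv <- cross_validate_models(cached_training_samples(),
                                            seed = 7)
  .test_cache$cv
}

# Synthetic regression benchmark with the 9 named feature columns.
make_benchmark_samples <- function(n, y_fun, seed = 42) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * 9), n, 9)
  colnames(X) <- pcsrank:::FEATURE_NAMES
  df <- as.data.frame(X)
  df$subject_id <- paste0("B", rep(seq_len(max(1, n %/% 36)),
                                   length.out = n))
  df$config_label <- rep(config_table()$label, length.out = n)
  df$pcs_calc <- y_fun(df)
  df
}
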