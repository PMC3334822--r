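#' Full run configuration
#'
#' Bundles every sub-configuration of an end-to-end experiment (stimulus
#' generation, retinal front end, learning, normalization, evaluation) into a
#' single serializable object, so that a run directory always carries enough
#' metadata to regenerate itself exactly.
#'
#' @param synthetic a [synthetic_image_spec()] (used when no image paths are
#'   given).
#' @param image_paths optional character vector of image files (.pgm/.csv)
#'   used instead of the synthetic generator.
#' @param dog a [dog_params()].
#' @param learning a [learning_config()].
#' @param norm a [norm_params()] (used in NBCM mode).
#' @param grid_size patch side length in pixels.
#' @param crop border crop after DoG filtering, pixels.
#' @param n_patches training patches to draw.
#' @param n_eval_patches evaluation patches for the coding metrics.
#' @param tol singular-value tolerance for rank/pseudo-inverse.
#' @param seed master seed for patch extraction and evaluation draws.
#' @return an object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_image_spec(),
                       image_paths = NULL,
                       dog = dog_params(),
                       learning = learning_config(),
                       norm = norm_params(),
                       grid_size = 16L, crop = 10L,
                       n_patches = 10000L, n_eval_patches = 1000L,
                       tol = 2.5, seed = 1L) {
  stopifnot(inherits(synthetic, "synthetic_image_spec"),
            inherits(dog, "dog_params"),
            inherits(learning, "learning_config"),
            inherits(norm, "norm_params"),
            grid_size >= 4, n_patches >= 1, n_eval_patches >= 1)
  structure(list(synthetic = synthetic, image_paths = image_paths,
                 dog = dog, learning = learning, norm = norm,
                 grid_size = as.integer(grid_size), crop = as.integer(crop),
                 n_patches = as.integer(n_patches),
                 n_eval_patches = as.integer(n_eval_patches),
                 tol = tol, seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / restore a run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  payload <- lapply(unclass(config), function(x) {
    if (is.object(x)) unclass(x) else x
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  lc <- p$learning
  cfg <- do.call(learning_config, lc[names(lc) != "mode"])
  cfg$mode <- lc$mode
  run_config(
    synthetic = do.call(synthetic_image_spec, as.list(p$synthetic)),
    image_paths = p$image_paths,
    dog = dog_params(p$dog$sigma_center, p$dog$sigma_surround,
                     p$dog$kernel_halfwidth),
    learning = cfg,
    norm = norm_params(p$norm$alpha, p$norm$beta),
    grid_size = p$grid_size, crop = p$crop,
    n_patches = p$n_patches, n_eval_patches = p$n_eval_patches,
    tol = p$tol, seed = p$seed)
}

load_ensemble <- function(config) {
  if (!is.null(config$image_paths) && length(config$image_paths)) {
    image_ensemble(lapply(config$image_paths, read_image))
  } else {
    pink_noise_ensemble(config$synthetic)
  }
}

#' Generate and archive the stimulus ensemble
#'
#' @param config a [run_config()].
#' @param outdir output directory (created).
#' @return the output directory, invisibly.
#' @export
cmd_generate <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ens <- load_ensemble(config)
  for (i in seq_along(ens$images)) {
    write_image(ens$images[[i]], file.path(outdir, sprintf("image_%03d.csv", i)))
  }
  write_run_config(config, file.path(outdir, "config.json"))
  message(sprintf("wrote %d image(s) to %s", length(ens$images), outdir))
  invisible(outdir)
}

#' Train a network end to end
#'
#' Runs stimulus generation (or image loading), the retinal front end, and
#' the (N)BCM learning loop; archives the trained state, a progress log
#' (iteration, learning rate, mean threshold, mean absolute weight), and the
#' full configuration under `outdir`.
#'
#' @param config a [run_config()]; `config$learning$mode` selects BCM/NBCM
#'   unless overridden.
#' @param outdir output directory.
#' @param mode optional override of the learning mode ("bcm"/"nbcm").
#' @param dry_run validate the configuration and input pipeline without
#'   training.
#' @param progress_every progress-log stride in iterations (default 1e4).
#' @return the trained `network_state` (invisibly; `NULL` on dry runs).
#' @export
cmd_train <- function(config, outdir, mode = NULL, dry_run = FALSE,
                      progress_every = 1e4) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(mode)) config$learning$mode <- match.arg(mode, c("bcm", "nbcm"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(outdir, "config.json"))
  if (dry_run) {
    message("dry run: configuration valid")
    return(invisible(NULL))
  }
  ens <- load_ensemble(config)
  patches <- retina_pipeline(ens, dog = config$dog, crop = config$crop,
                             grid_size = config$grid_size,
                             n_patches = config$n_patches,
                             seed = config$seed)
  stride <- max(1, min(progress_every, config$learning$n_iterations))
  state <- train_network(patches, config$learning, norm = config$norm,
                         record_every = as.integer(stride))
  save_network(state, outdir, stem = config$learning$mode)
  tr <- state$trace
  if (length(tr$iteration)) {
    log_df <- data.frame(iteration = tr$iteration, eta = tr$eta,
                         mean_abs_weight = tr$mean_abs_weight,
                         mean_threshold = colMeans(tr$thresholds))
    utils::write.csv(log_df, file.path(outdir, "progress.csv"),
                     row.names = FALSE)
  }
  message(sprintf("trained %s network (%g iterations) -> %s",
                  config$learning$mode, state$iteration, outdir))
  invisible(state)
}

#' Analyze a trained network
#'
#' Reconstructs receptive fields, measures tuning, draws fresh evaluation
#' patches (log-transformed, not DoG-filtered), and writes a coding report
#' (JSON), a tuning table (CSV), and, where a PNG device is available, a
#' field montage and a coverage error map.
#'
#' @param state_dir directory holding a state saved by [cmd_train()] (or a
#'   `network_state` directly).
#' @param outdir output directory (defaults to `state_dir`).
#' @param config a [run_config()]; read from `state_dir/config.json` when
#'   omitted.
#' @param stem file-name stem of the saved state (defaults to the configured
#'   learning mode).
#' @param figures attempt PNG figure output (default `TRUE`).
#' @return list with `report` (a `coding_report`) and `tuning` (data.frame),
#'   invisibly.
#' @export
cmd_analyze <- function(state_dir, outdir = NULL, config = NULL, stem = NULL,
                        figures = TRUE) {
  if (inherits(state_dir, "network_state")) {
    state <- state_dir
    if (is.null(outdir)) stop("outdir required when passing a state object")
    if (is.null(config)) stop("config required when passing a state object")
  } else {
    if (!dir.exists(state_dir)) stop("state directory not found: ", state_dir)
    if (is.null(config)) {
      config <- read_run_config(file.path(state_dir, "config.json"))
    }
    if (is.null(stem)) stem <- config$learning$mode
    state <- load_network(state_dir, stem = stem)
    if (is.null(outdir)) outdir <- state_dir
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  rf <- reconstruct_fields(state, dog = config$dog)
  tuning <- tuning_table(rf)
  ens <- load_ensemble(config)
  eval_patches <- extract_patches(log_transform(ens),
                                  grid_size = config$grid_size,
                                  n_patches = config$n_eval_patches,
                                  seed = config$seed + 1000L)
  report <- coding_report(rf, eval_patches, tol = config$tol)

  utils::write.csv(tuning, file.path(outdir, "tuning.csv"), row.names = FALSE)
  jsonlite::write_json(
    report[c("reconstruction_error", "coverage", "orthogonality", "rank",
             "lifetime_sparseness", "population_sparseness", "dispersal",
             "dispersal_raw", "n_neurons", "n_stimuli", "tol")],
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  if (figures) {
    try(plot_field_montage(rf, file.path(outdir, "fields.png")), silent = TRUE)
    try(plot_coverage_map(report$coverage_detail, config$grid_size,
                          file.path(outdir, "coverage_map.png")),
        silent = TRUE)
  }
  invisible(list(report = report, tuning = tuning))
}

#' Compare two analyzed runs side by side
#'
#' @param dir_a,dir_b run directories containing `report.json` files written
#'   by [cmd_analyze()].
#' @param labels column labels.
#' @param outfile optional CSV destination for the comparison table.
#' @return a data.frame (metrics in rows, runs in columns).
#' @export
cmd_compare <- function(dir_a, dir_b, labels = c("bcm", "nbcm"),
                        outfile = NULL) {
  read_report <- function(d) {
    jsonlite::read_json(file.path(d, "report.json"), simplifyVector = TRUE)
  }
  ra <- read_report(dir_a); rb <- read_report(dir_b)
  metrics <- c("reconstruction_error", "coverage", "orthogonality", "rank",
               "lifetime_sparseness", "population_sparseness", "dispersal")
  out <- data.frame(metric = metrics,
                    a = unlist(ra[metrics]), b = unlist(rb[metrics]),
                    row.names = NULL)
  names(out)[2:3] <- labels
  if (!is.null(outfile)) utils::write.csv(out, outfile, row.names = FALSE)
  out
}

# Grid-of-fields montage, one gray box per receptive field.
plot_field_montage <- function(rf, path, ncol_grid = NULL) {
  if (!capabilities("png")) return(invisible(NULL))
  fields <- if (inherits(rf, "rf_set")) rf$fields else rf
  J <- nrow(fields)
  g <- as.integer(round(sqrt(ncol(fields))))
  if (is.null(ncol_grid)) ncol_grid <- ceiling(sqrt(J))
  nrow_grid <- ceiling(J / ncol_grid)
  big <- matrix(0, nrow_grid * (g + 1) - 1, ncol_grid * (g + 1) - 1)
  for (j in seq_len(J)) {
    r <- (j - 1) %/% ncol_grid; cc <- (j - 1) %% ncol_grid
    fm <- matrix(fields[j, ], g, g)
    big[r * (g + 1) + seq_len(g), cc * (g + 1) + seq_len(g)] <-
      (fm - min(fm)) / max(1e-12, diff(range(fm)))
  }
  grDevices::png(path, width = 4 * ncol(big), height = 4 * nrow(big))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(big[nrow(big):1, ]), col = grDevices::gray.colors(256),
                  axes = FALSE, useRaster = TRUE)
  invisible(path)
}

# DC-centered per-frequency decode error map (dark = poor reconstruction).
plot_coverage_map <- function(cov, g, path) {
  if (!capabilities("png")) return(invisible(NULL))
  map <- coverage_map(cov, g)
  grDevices::png(path, width = 320, height = 320)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(2, 2, 2, 1))
  graphics::image(attr(map, "fx"), attr(map, "fy"), 1 - t(map),
                  col = grDevices::gray.colors(256), zlim = c(0, 1),
                  xlab = "fx (cyc/px)", ylab = "fy (cyc/px)",
                  main = "decode quality (1 - error)", useRaster = TRUE)
  invisible(path)
}
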