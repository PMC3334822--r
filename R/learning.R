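#' Learning configuration for the (N)BCM network
#'
#' Bundles every constant of the learning dynamics.  Defaults are the
#' paper-scale values: a steep asymmetric output sigmoid (`k1 = 25`,
#' `k2 = 1`), threshold time constant `tau = 1000` presentations, initial
#' learning rate `eta0 = 1e-5` annealed by 0.1% once every 1000 iterations,
#' 256 neurons trained for 1e6 iterations.
#'
#' @param k1 positive sigmoid ceiling for positive linear activations.
#' @param k2 positive sigmoid floor magnitude for negative activations.
#' @param tau threshold time constant, in stimulus presentations.
#' @param eta0 initial learning rate.
#' @param anneal_factor multiplier applied to the learning rate once every
#'   1000 iterations (0.999 = a 0.1% decrement); must be in (0, 1].
#' @param n_iterations total number of stimulus presentations.
#' @param n_neurons number of cortical neurons J.
#' @param mode `"bcm"` (independent neurons) or `"nbcm"` (divisive contrast
#'   normalization couples the population before the updates).
#' @param linear_output bypass the sigmoid (`s(r) = r`); test mode in which
#'   the analytic BCM two-pattern fixed point is exact.  Default off.
#' @param norm_drives_threshold in NBCM mode, use the normalized response in
#'   the threshold update as well as in the weight update (default `TRUE`);
#'   `FALSE` lets the raw sigmoid output drive the threshold instead.
#' @param seed integer seed controlling weight initialization and the patch
#'   presentation schedule.
#' @return an object of class `learning_config`.
#' @export
learning_config <- function(k1 = 25, k2 = 1, tau = 1000, eta0 = 1e-5,
                            anneal_factor = 0.999, n_iterations = 1e6,
                            n_neurons = 256L, mode = c("bcm", "nbcm"),
                            linear_output = FALSE,
                            norm_drives_threshold = TRUE,
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(k1 > 0, k2 > 0, tau > 0, eta0 >= 0,
            anneal_factor > 0, anneal_factor <= 1,
            n_iterations >= 0, n_neurons >= 1)
  structure(list(k1 = k1, k2 = k2, tau = tau, eta0 = eta0,
                 anneal_factor = anneal_factor,
                 n_iterations = as.numeric(n_iterations),
                 n_neurons = as.integer(n_neurons), mode = mode,
                 linear_output = isTRUE(linear_output),
                 norm_drives_threshold = isTRUE(norm_drives_threshold),
                 seed = as.integer(seed)),
            class = "learning_config")
}

#' Divisive normalization parameters
#'
#' `alpha` plays the role of the semi-saturation constant in
#' contrast/response functions (Naka-Rushton form); `beta` scales the
#' normalized output.  Their ratio relative to the pooled squared population
#' activity sets the normalization regime.  The two parameter pairings studied
#' at paper scale are (1, 2) and (2, 4).
#'
#' @param alpha positive semi-saturation constant.
#' @param beta positive output gain.
#' @return an object of class `norm_params`.
#' @export
norm_params <- function(alpha = 1, beta = 2) {
  stopifnot(alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta), class = "norm_params")
}

#' Initialize a network state
#'
#' Weights are drawn uniformly from \[-1, 1\] (seeded); modification
#' thresholds start at zero, which keeps them inside \[0, k1^2\] for all time
#' under the threshold dynamics.
#'
#' @param config a [learning_config()].
#' @param n_inputs number of retinal inputs per neuron (grid_size^2).
#' @return an object of class `network_state`: weights (J x n_inputs),
#'   thresholds (length J), current `eta`, `iteration` count, and the config.
#' @export
init_network <- function(config, n_inputs) {
  w <- with_seed(config$seed,
                 matrix(runif(config$n_neurons * n_inputs, -1, 1),
                        config$n_neurons, n_inputs))
  structure(list(weights = w,
                 thresholds = rep(0, config$n_neurons),
                 eta = config$eta0,
                 iteration = 0,
                 config = config,
                 norm = NULL,
                 trace = NULL),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf(
    "<network_state: %d neurons x %d inputs, %s mode, iteration %g, eta %.3g>\n",
    nrow(x$weights), ncol(x$weights), x$config$mode, x$iteration, x$eta))
  cat(sprintf("  mean |weight| %.4f, mean threshold %.4f\n",
              mean(abs(x$weights)), mean(x$thresholds)))
  invisible(x)
}

#' BCM activation of the population for one patch
#'
#' Linear stage `r_j = sum_i m_ij d_i` followed by the asymmetric saturating
#' output `c_j = k1 tanh(r_j)` for `r_j > 0` and `k2 tanh(r_j)` for
#' `r_j < 0` (zero at zero).  In sigmoid mode the output is confined to
#' (-k2, k1).
#'
#' @param weights J x n_inputs weight matrix (or a `network_state`).
#' @param patch input vector `d` of length n_inputs (or a matrix with patches
#'   in rows, in which case a J x n_patches output matrix is returned per
#'   component).
#' @param k1,k2 sigmoid constants (ignored when `weights` is a
#'   `network_state`, whose config wins).
#' @param linear_output bypass the sigmoid.
#' @return list with `linear` (r) and `output` (c).
#' @export
bcm_activation <- function(weights, patch, k1 = 25, k2 = 1,
                           linear_output = FALSE) {
  if (inherits(weights, "network_state")) {
    cfg <- weights$config
    k1 <- cfg$k1; k2 <- cfg$k2; linear_output <- cfg$linear_output
    weights <- weights$weights
  }
  if (!all(is.finite(weights))) stop("non-finite weights")
  r <- if (is.matrix(patch)) weights %*% t(patch) else drop(weights %*% patch)
  c_out <- if (linear_output) r else {
    out <- tanh(r)
    out[r > 0] <- k1 * out[r > 0]
    out[r < 0] <- k2 * out[r < 0]
    out
  }
  list(linear = r, output = c_out)
}

#' Divisive contrast normalization of a population response
#'
#' `c'_j = beta * c_j / (alpha + sum_i c_i^2)`, where the pool runs over the
#' raw (un-normalized) outputs of all neurons including neuron j itself.  The
#' denominator is at least `alpha > 0`, so the operation is always defined and
#' `|c'_j| <= beta * k1 / alpha` in sigmoid mode.
#'
#' @param c_out numeric vector of population outputs to one stimulus (or a
#'   J x N matrix, normalized per column/stimulus).
#' @param params a [norm_params()].
#' @return normalized responses with the shape of `c_out`.
#' @export
contrast_normalize <- function(c_out, params = norm_params()) {
  if (is.matrix(c_out)) {
    pool <- params$alpha + colSums(c_out^2)
    return(sweep(c_out, 2L, params$beta / pool, `*`))
  }
  params$beta * c_out / (params$alpha + sum(c_out^2))
}

#' One BCM weight update
#'
#' `delta m_ij = eta * c_j * (c_j - theta_j) * d_i`: Hebbian when the
#' (effective) response exceeds the modification threshold, anti-Hebbian when
#' it is positive but subthreshold.
#'
#' @param c_eff effective response vector driving learning (raw `c` in BCM,
#'   normalized `c'` in NBCM).
#' @param theta modification threshold vector.
#' @param patch input vector `d`.
#' @param eta learning rate.
#' @return the J x n_inputs weight increment.
#' @export
weight_delta <- function(c_eff, theta, patch, eta) {
  eta * (c_eff * (c_eff - theta)) %o% patch
}

#' One sliding-threshold update
#'
#' `delta theta_j = (c_j^2 - theta_j) / tau`: an exponential tracker of the
#' expected squared response with time constant `tau` presentations.
#'
#' @inheritParams weight_delta
#' @param tau threshold time constant.
#' @return the threshold increment vector.
#' @export
threshold_delta <- function(c_eff, theta, tau) {
  (c_eff^2 - theta) / tau
}

#' Annealed learning rate
#'
#' Stepwise schedule: `eta(k) = eta0 * anneal_factor^floor(k / 1000)`; the
#' rate drops by 0.1% once every 1000 iterations under the default factor.
#'
#' @param eta0 initial learning rate.
#' @param iteration global iteration count (0-based).
#' @param anneal_factor per-1000-iterations multiplier.
#' @return the learning rate in force at `iteration`.
#' @export
anneal_eta <- function(eta0, iteration, anneal_factor = 0.999) {
  eta0 * anneal_factor^floor(iteration / 1000)
}

#' Train a (N)BCM network on a patch stream
#'
#' Runs the full learning loop (in compiled code): per presentation, draw a
#' patch, compute the sigmoid activation, in NBCM mode apply divisive
#' normalization, update the weights and the sliding threshold, and anneal the
#' learning rate.  The run is bit-reproducible given the config seed, and a
#' run interrupted at any iteration and resumed via `state` reproduces the
#' uninterrupted run exactly (the presentation schedule is regenerated from
#' the seed and sliced).
#'
#' @param patches a `patch_set` or an N x n_inputs matrix of standardized
#'   patches.
#' @param config a [learning_config()].
#' @param norm a [norm_params()] (required in NBCM mode).
#' @param state resume from this `network_state` instead of initializing.
#' @param n_steps number of presentations to run now (default: all remaining
#'   up to `config$n_iterations`).
#' @param schedule optional integer vector of patch row indices of length
#'   `config$n_iterations`, overriding the uniform random schedule (used for
#'   non-uniform stimulus environments).
#' @param record_every if positive, snapshot thresholds / eta / mean absolute
#'   weight every that many presentations into `state$trace`.
#' @param freeze_weights run only the threshold dynamics (analysis mode).
#' @return the final `network_state`.
#' @export
train_network <- function(patches, config, norm = NULL, state = NULL,
                          n_steps = NULL, schedule = NULL, record_every = 0L,
                          freeze_weights = FALSE) {
  mat <- if (inherits(patches, "patch_set")) patches$data else patches
  if (!is.matrix(mat) || nrow(mat) == 0L) stop("empty patch set")
  if (config$mode == "nbcm" && is.null(norm)) {
    stop("NBCM mode requires norm_params")
  }
  if (is.null(state)) state <- init_network(config, ncol(mat))
  if (ncol(state$weights) != ncol(mat)) {
    stop("patch length does not match network inputs")
  }
  done <- state$iteration
  if (is.null(n_steps)) n_steps <- config$n_iterations - done
  n_steps <- as.numeric(n_steps)
  if (n_steps <= 0) return(state)

  # Full-length schedule regenerated from the seed so resumed runs replay the
  # identical stimulus sequence.
  if (is.null(schedule)) {
    total <- max(config$n_iterations, done + n_steps)
    schedule <- with_seed(config$seed + 1L,
                          sample.int(nrow(mat), total, replace = TRUE))
  }
  if (length(schedule) < done + n_steps) {
    stop("schedule shorter than the requested number of iterations")
  }
  chunk <- schedule[(done + 1):(done + n_steps)]

  res <- .train_core(state$weights, state$thresholds, mat,
                     as.integer(chunk) - 1L,
                     config$k1, config$k2, config$linear_output,
                     config$tau, config$eta0, config$anneal_factor,
                     if (config$mode == "nbcm") 1L else 0L,
                     if (is.null(norm)) 1 else norm$alpha,
                     if (is.null(norm)) 1 else norm$beta,
                     config$norm_drives_threshold,
                     isTRUE(freeze_weights),
                     done, as.integer(record_every))

  out <- structure(list(weights = res$weights,
                        thresholds = drop(res$thresholds),
                        eta = res$eta,
                        iteration = done + res$iterations_run,
                        config = config,
                        norm = norm,
                        trace = res$trace),
                   class = "network_state")
  if (isTRUE(res$diverged)) {
    stop(errorCondition(
      sprintf("training diverged (non-finite weights) at iteration %g",
              out$iteration),
      state = out, class = c("nbcm_divergence", "error", "condition")))
  }
  out
}

#' Population responses to a set of patches
#'
#' Sigmoid (or linear, per config) outputs of every neuron to every patch.
#'
#' @param state a `network_state` (or a weight matrix, with `config` given).
#' @param patches `patch_set` or matrix with patches in rows.
#' @param config needed only when `state` is a bare weight matrix.
#' @return a J x N response matrix.
#' @export
network_responses <- function(state, patches, config = NULL) {
  mat <- if (inherits(patches, "patch_set")) patches$data else patches
  if (inherits(state, "network_state")) {
    bcm_activation(state, mat)$output
  } else {
    if (is.null(config)) stop("config required with a bare weight matrix")
    bcm_activation(state, mat, k1 = config$k1, k2 = config$k2,
                   linear_output = config$linear_output)$output
  }
}

#' Save / load a network checkpoint as text
#'
#' Weights and thresholds go to headerless CSV files, the configuration and
#' run position to a JSON file, all under `dir` with the given stem.
#'
#' @param state a `network_state`.
#' @param dir destination directory (created if missing).
#' @param stem file-name stem (default `"network"`).
#' @return the metadata path, invisibly.
#' @export
save_network <- function(state, dir, stem = "network") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(state$weights, file.path(dir, paste0(stem, "_weights.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(state$thresholds,
                     file.path(dir, paste0(stem, "_thresholds.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(eta = state$eta, iteration = state$iteration,
               config = unclass(state$config),
               norm = if (is.null(state$norm)) NULL else unclass(state$norm))
  path <- file.path(dir, paste0(stem, "_meta.json"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_network
#' @param stem file-name stem used when saving.
#' @export
load_network <- function(dir, stem = "network") {
  w <- as.matrix(utils::read.csv(file.path(dir, paste0(stem, "_weights.csv")),
                                 header = FALSE))
  dimnames(w) <- NULL
  th <- utils::read.csv(file.path(dir, paste0(stem, "_thresholds.csv")),
                        header = FALSE)[[1]]
  meta <- jsonlite::read_json(file.path(dir, paste0(stem, "_meta.json")),
                              simplifyVector = TRUE)
  cfg <- do.call(learning_config, meta$config[names(meta$config) != "mode"])
  cfg$mode <- meta$config$mode
  nrm <- if (!is.null(meta$norm)) norm_params(meta$norm$alpha, meta$norm$beta)
  structure(list(weights = w, thresholds = th, eta = meta$eta,
                 iteration = meta$iteration, config = cfg, norm = nrm,
                 trace = NULL),
            class = "network_state")
}
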