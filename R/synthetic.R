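#' Specification of a synthetic natural-image ensemble
#'
#' Describes the stand-in for calibrated landscape photographs: random-phase
#' images with an approximately 1/f amplitude spectrum and an adjustable
#' excess of vertical/horizontal orientation energy (natural scenes carry more
#' energy along the cardinal axes than along obliques).
#'
#' @param n_images number of images.
#' @param size image side length in pixels (default 256, the paper-scale
#'   photograph size).
#' @param spectral_slope amplitude-spectrum exponent (default -1, i.e. 1/f).
#' @param orientation_bias target ratio of vertical+horizontal band energy to
#'   oblique band energy (default 2; 1 disables the bias).
#' @param rotation degrees by which the finished images are rotated (for
#'   rotated-environment control experiments; default 0).
#' @param log_contrast standard deviation of the log-luminance image before
#'   exponentiation (default 0.5, a realistic natural-scene log contrast).
#' @param luminance_floor positive offset added after exponentiation so
#'   pixels are bounded away from zero (default 1e-6).
#' @param seed integer seed.
#' @return an object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(n_images = 8L, size = 256L,
                                 spectral_slope = -1, orientation_bias = 2,
                                 rotation = 0, log_contrast = 0.5,
                                 luminance_floor = 1e-6, seed = 1L) {
  stopifnot(n_images >= 1, size >= 8, luminance_floor > 0,
            orientation_bias > 0, log_contrast > 0)
  structure(list(n_images = as.integer(n_images), size = as.integer(size),
                 spectral_slope = spectral_slope,
                 orientation_bias = orientation_bias,
                 rotation = rotation, log_contrast = log_contrast,
                 luminance_floor = luminance_floor, seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

# Centered frequency coordinate matrices for an n x n FFT grid in natural
# (unshifted) order: entry (i, j) holds (fy, fx) of fft bin (i, j).
fft_freq_grids <- function(n) {
  f <- (0:(n - 1)) / n
  f[f >= 0.5] <- f[f >= 0.5] - 1
  list(fx = matrix(f, n, n, byrow = TRUE), fy = matrix(f, n, n))
}

# Radial band on which the orientation-bias contract is defined and
# measured: an annulus with complete angular coverage.  The lowest-frequency
# bins are excluded because on a discrete square grid they sit exactly on the
# axes with enormous 1/f^2 energy (a discretization artifact, not an
# orientation preference), and the corner region beyond the Nyquist radius is
# excluded because only oblique frequencies exist there.
.bias_band <- c(0.02, 0.5)

# Smooth orientation gain: amplitude multiplier sqrt(1 + a cos^2(2 phi)),
# peaking on the cardinal axes for a > 0.  `a` is calibrated on the actual
# discrete grid so the expected cardinal/oblique band-energy ratio (22.5-deg
# bands around 0/90 vs 45/135 degrees, baseline f^(2 slope) energy, radial
# band `.bias_band`) equals `bias` exactly.
orientation_gain_exponent <- function(n, slope, bias) {
  gr <- fft_freq_grids(n)
  f <- sqrt(gr$fx^2 + gr$fy^2)
  phi <- atan2(gr$fy, gr$fx)
  in_band <- f >= .bias_band[1] & f <= .bias_band[2]
  base <- ifelse(f > 0, f^(2 * slope), 0)
  c2 <- cos(2 * phi)^2
  # distance of phi to the nearest cardinal axis, in (0, 45] degrees
  dcard <- abs(((phi * 180 / pi) %% 90 + 45) %% 90 - 45)
  in_vh <- in_band & dcard <= 22.5
  in_ob <- in_band & dcard > 22.5
  ratio <- function(a) {
    sum(base[in_vh] * (1 + a * c2[in_vh])) /
      sum(base[in_ob] * (1 + a * c2[in_ob])) - bias
  }
  if (ratio(1e4) < 0 || ratio(-0.999) > 0) {
    lo <- ratio(-0.999) + bias; hi <- ratio(1e4) + bias
    stop(sprintf(paste0("orientation_bias = %g is outside the range (%.3f, ",
                        "%.3f) achievable by the cos^2-lobed gain"),
                 bias, lo, hi))
  }
  uniroot(ratio, c(-0.999, 1e4), tol = 1e-12)$root
}

#' Generate a 1/f random-phase image ensemble
#'
#' Each image is built in the frequency domain: the FFT of white Gaussian
#' noise is multiplied by a radial amplitude envelope `f^slope` (DC removed)
#' and by a smooth `cos^2(2 phi)`-lobed orientation gain calibrated so that
#' the vertical+horizontal band carries `orientation_bias` times the energy of
#' the oblique band.  The inverse transform is scaled to the requested
#' log-contrast, treated as a log-luminance image, exponentiated, and offset
#' by `luminance_floor`, so all pixels are strictly positive and the retinal
#' log transform recovers an approximately Gaussian 1/f image.
#'
#' @param spec a [synthetic_image_spec()].
#' @return an [image_ensemble()] of strictly positive luminance images.
#' @export
pink_noise_ensemble <- function(spec = synthetic_image_spec()) {
  n <- spec$size
  gr <- fft_freq_grids(n)
  f <- sqrt(gr$fx^2 + gr$fy^2)
  phi <- atan2(gr$fy, gr$fx)
  amp <- ifelse(f > 0, f^spec$spectral_slope, 0)
  if (spec$orientation_bias != 1) {
    a <- orientation_gain_exponent(n, spec$spectral_slope,
                                   spec$orientation_bias)
    amp <- amp * sqrt(1 + a * cos(2 * phi)^2)
  }
  imgs <- with_seed(spec$seed, lapply(seq_len(spec$n_images), function(i) {
    wn <- matrix(rnorm(n * n), n, n)
    shaped <- Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) / (n * n)
    logim <- shaped / sd(shaped) * spec$log_contrast
    exp(logim - mean(logim)) + spec$luminance_floor
  }))
  ens <- image_ensemble(imgs)
  if (spec$rotation != 0) ens <- rotate_ensemble(ens, spec$rotation)
  ens
}

#' Cardinal-to-oblique orientation energy ratio of an ensemble
#'
#' Measurement oracle for the orientation bias: total spectral energy of the
#' log-transformed, mean-removed images within 22.5 degrees of the cardinal
#' axes divided by the energy within 22.5 degrees of the obliques (DC
#' excluded).
#'
#' @param images an [image_ensemble()] of luminance images (log is taken
#'   internally), or of signed images with `log = FALSE`.
#' @param log take the log transform first (default `TRUE`).
#' @param f_range radial band (cycles/pixel) over which energy is summed; the
#'   default is the annulus on which the generator's bias is calibrated
#'   (0.02 to the 0.5 Nyquist radius).  The lowest frequencies are excluded
#'   both for calibration consistency and because their 1/f-dominated bins
#'   would swamp the estimator's variance.
#' @return scalar energy ratio.
#' @export
orientation_energy_ratio <- function(images, log = TRUE,
                                     f_range = .bias_band) {
  imgs <- as_image_list(images)
  n <- nrow(imgs[[1]])
  gr <- fft_freq_grids(n)
  f <- sqrt(gr$fx^2 + gr$fy^2)
  phi <- atan2(gr$fy, gr$fx)
  dcard <- abs(((phi * 180 / pi) %% 90 + 45) %% 90 - 45)
  in_band <- f >= f_range[1] & f <= f_range[2]
  in_vh <- in_band & dcard <= 22.5
  in_ob <- in_band & dcard > 22.5
  e_vh <- 0; e_ob <- 0
  for (im in imgs) {
    z <- if (log) base::log(im) else im
    z <- z - mean(z)
    e <- Mod(stats::fft(z))^2
    e_vh <- e_vh + sum(e[in_vh])
    e_ob <- e_ob + sum(e[in_ob])
  }
  e_vh / e_ob
}

#' Radially averaged amplitude-spectrum slope
#'
#' Fits `log(amplitude) ~ log(f)` over radial-frequency bins (averaged across
#' the ensemble), a diagnostic for the 1/f structure of the generator.
#'
#' @inheritParams orientation_energy_ratio
#' @param f_range radial frequency range used in the fit (cycles/pixel).
#' @return the fitted slope.
#' @export
spectral_slope_estimate <- function(images, log = TRUE,
                                    f_range = c(0.01, 0.35)) {
  imgs <- as_image_list(images)
  n <- nrow(imgs[[1]])
  gr <- fft_freq_grids(n)
  f <- sqrt(gr$fx^2 + gr$fy^2)
  amp <- 0
  for (im in imgs) {
    z <- if (log) base::log(im) else im
    amp <- amp + Mod(stats::fft(z - mean(z)))
  }
  sel <- f >= f_range[1] & f <= f_range[2]
  bins <- cut(f[sel], breaks = 40)
  mf <- tapply(f[sel], bins, mean)
  ma <- tapply(amp[sel], bins, mean)
  ok <- is.finite(mf) & is.finite(ma) & ma > 0
  unname(coef(lm(log(ma[ok]) ~ log(mf[ok])))[2])
}

#' Rotate an image ensemble about its center
#'
#' Bilinear interpolation, followed by a crop to the largest centered square
#' that lies entirely inside the rotated source (so no padding artifacts enter
#' the output).
#'
#' @param images an [image_ensemble()], matrix, or list of matrices.
#' @param angle rotation angle in degrees (counter-clockwise in the x-right /
#'   y-down pixel coordinate frame).
#' @return an `image_ensemble` of rotated, cropped images.
#' @export
rotate_ensemble <- function(images, angle) {
  imgs <- as_image_list(images)
  n <- nrow(imgs[[1]]); m <- ncol(imgs[[1]])
  th <- angle * pi / 180
  scale <- abs(cos(th)) + abs(sin(th))
  half <- floor((min(n, m) / 2 - 1) / scale)
  if (half < 1) stop("images too small to rotate and crop")
  out_side <- 2L * half
  cx <- (m + 1) / 2; cy <- (n + 1) / 2
  xo <- matrix(seq_len(out_side) - half - 0.5, out_side, out_side,
               byrow = TRUE)
  yo <- matrix(seq_len(out_side) - half - 0.5, out_side, out_side)
  # inverse rotation maps output coordinates back into the source
  xs <- cx + cos(th) * xo + sin(th) * yo
  ys <- cy - sin(th) * xo + cos(th) * yo
  x0 <- floor(xs); y0 <- floor(ys)
  tx <- xs - x0; ty <- ys - y0
  if (any(x0 < 1 | x0 + 1 > m | y0 < 1 | y0 + 1 > n)) {
    stop("rotation sampling escaped the source image; crop too large")
  }
  i00 <- cbind(as.vector(y0), as.vector(x0))
  i01 <- cbind(as.vector(y0), as.vector(x0) + 1L)
  i10 <- cbind(as.vector(y0) + 1L, as.vector(x0))
  i11 <- cbind(as.vector(y0) + 1L, as.vector(x0) + 1L)
  tx <- as.vector(tx); ty <- as.vector(ty)
  rot_one <- function(im) {
    vals <- (1 - ty) * ((1 - tx) * im[i00] + tx * im[i01]) +
      ty * ((1 - tx) * im[i10] + tx * im[i11])
    matrix(vals, out_side, out_side)
  }
  image_ensemble(lapply(imgs, rot_one), check_positive = FALSE)
}

#' Two-pattern stimulus environment
#'
#' The classical analytic BCM test harness: a small set of mutually
#' orthogonal unit-norm patterns presented i.i.d. with given probabilities.
#' At the selective BCM fixed point the response to the selected pattern k is
#' `1 / p_k` and the threshold settles at the same value.
#'
#' @param probabilities pattern presentation probabilities (must sum to 1).
#' @param dimension input dimensionality (>= number of patterns).
#' @param n_draws length of the presentation schedule to draw.
#' @param seed integer seed (patterns and schedule).
#' @return list with `patterns` (k x dimension orthonormal rows), `schedule`
#'   (length `n_draws` pattern indices), and `probabilities`.
#' @export
two_pattern_environment <- function(probabilities = c(0.5, 0.5),
                                    dimension = 2L, n_draws = 1e5,
                                    seed = 1L) {
  if (abs(sum(probabilities) - 1) > 1e-12 || any(probabilities <= 0)) {
    stop("probabilities must be positive and sum to 1")
  }
  k <- length(probabilities)
  if (dimension < k) stop("dimension must be >= number of patterns")
  with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(dimension * k), dimension, k)))
    schedule <- sample.int(k, n_draws, replace = TRUE, prob = probabilities)
    list(patterns = t(q), schedule = schedule, probabilities = probabilities)
  })
}

#' Standardized Gabor receptive fields with known ground-truth tuning
#'
#' Oracle fixtures for the tuning estimators: Gabor functions (oriented
#' sinusoidal carrier under a Gaussian envelope) whose preferred frequency and
#' orientation are known by construction.
#'
#' @param params a data.frame with one row per field and columns `x0`, `y0`
#'   (envelope center, pixels, 1-based), `sf` (carrier frequency,
#'   cycles/pixel, must not exceed the 0.5 Nyquist limit), `ori` (carrier
#'   orientation, degrees, package convention as in [grating()]), `sigma_x`,
#'   `sigma_y` (envelope standard deviations along/across the carrier,
#'   pixels, > 0), `phase` (radians).
#' @param g grid side length.
#' @return an `rf_set` of standardized Gabor fields.
#' @export
gabor_field_set <- function(params, g = 16L) {
  g <- as.integer(g)
  needed <- c("x0", "y0", "sf", "ori", "sigma_x", "sigma_y", "phase")
  if (!all(needed %in% names(params))) {
    stop("params must contain columns: ", paste(needed, collapse = ", "))
  }
  if (any(params$sf > 0.5) || any(params$sf <= 0)) {
    stop("carrier frequency must lie in (0, 0.5] cycles/pixel ",
         "(Nyquist limit)")
  }
  if (any(params$sigma_x <= 0) || any(params$sigma_y <= 0)) {
    stop("degenerate envelope: sigma must be > 0")
  }
  x <- matrix(0:(g - 1), g, g, byrow = TRUE)
  y <- matrix(0:(g - 1), g, g)
  fields <- matrix(NA_real_, nrow(params), g * g)
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    th <- p$ori * pi / 180
    xr <- (x - (p$x0 - 1)) * cos(th) + (y - (p$y0 - 1)) * sin(th)
    yr <- -(x - (p$x0 - 1)) * sin(th) + (y - (p$y0 - 1)) * cos(th)
    env <- exp(-xr^2 / (2 * p$sigma_x^2) - yr^2 / (2 * p$sigma_y^2))
    gb <- env * cos(2 * pi * p$sf * xr + p$phase)
    v <- as.vector(gb)
    s <- sd(v)
    if (!is.finite(s) || s == 0) stop("degenerate Gabor at row ", i)
    fields[i, ] <- (v - mean(v)) / s
  }
  structure(list(fields = fields, grid_size = g, pad_factor = 4L),
            class = "rf_set")
}
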