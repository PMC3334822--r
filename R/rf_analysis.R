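#' Reconstruct stimulus-domain receptive fields from RGC weights
#'
#' A learned weight vector acts on DoG-filtered stimuli; the equivalent
#' receptive field acting directly on (log-luminance) stimuli is the
#' convolution of the weights with the DoG kernel.  It is computed in the
#' Fourier domain: each g x g weight array is embedded (centered) in a
#' (pad_factor * g)^2 array of zeros, Fourier transformed, multiplied by the
#' transfer function of the same discrete DoG kernel, inverse transformed,
#' cropped back to the central g x g window, and standardized to zero mean and
#' unit standard deviation.
#'
#' The transfer function is the FFT of the zero-padded *discrete* kernel, not
#' of the analytic Gaussians, so reconstruction is exactly consistent with the
#' spatial filtering of the retina module (the round trip is checked by the
#' test suite: a field's dot product with a raw patch equals the weight
#' vector's dot product with the DoG-filtered patch).
#'
#' @param weights J x g^2 matrix of learned weights (rows are neurons,
#'   column-major flattening), or a `network_state`.
#' @param dog a [dog_params()] object or a kernel matrix from
#'   [build_dog_kernel()].
#' @param pad_factor Fourier padding factor (default 4: 16 -> 64, 32 -> 128).
#' @return an object of class `rf_set`: list with `fields` (J x g^2 matrix of
#'   standardized fields), `grid_size`, and `pad_factor`.
#' @export
reconstruct_fields <- function(weights, dog = dog_params(), pad_factor = 4L) {
  if (inherits(weights, "network_state")) weights <- weights$weights
  if (!is.matrix(weights)) weights <- matrix(weights, nrow = 1L)
  g <- as.integer(round(sqrt(ncol(weights))))
  if (g * g != ncol(weights)) stop("weight rows must have g^2 entries")
  kernel <- if (inherits(dog, "dog_params")) build_dog_kernel(dog) else dog
  h <- (nrow(kernel) - 1L) %/% 2L
  P <- as.integer(pad_factor) * g
  if (2L * h + g > P) {
    stop("pad_factor too small for the kernel support; increase it")
  }
  # kernel embedded with its center at the (1, 1) origin, wrapped circularly,
  # so its FFT is the (real, even) transfer function
  kpad <- matrix(0, P, P)
  idx <- ((-h:h) %% P) + 1L
  kpad[idx, idx] <- kernel
  kf <- stats::fft(kpad)

  off <- (P - g) %/% 2L
  win <- off + seq_len(g)
  J <- nrow(weights)
  fields <- matrix(NA_real_, J, g * g)
  degenerate <- integer(0)
  for (j in seq_len(J)) {
    wpad <- matrix(0, P, P)
    wpad[win, win] <- matrix(weights[j, ], g, g)
    fb <- Re(stats::fft(stats::fft(wpad) * kf, inverse = TRUE)) / (P * P)
    f <- as.vector(fb[win, win])
    s <- sd(f)
    if (!is.finite(s) || s == 0) {
      degenerate <- c(degenerate, j)
    } else {
      fields[j, ] <- (f - mean(f)) / s
    }
  }
  if (length(degenerate) > 0L) {
    stop("degenerate (zero-variance) receptive field(s) at index: ",
         paste(degenerate, collapse = ", "))
  }
  structure(list(fields = fields, grid_size = g,
                 pad_factor = as.integer(pad_factor)),
            class = "rf_set")
}

#' @export
print.rf_set <- function(x, ...) {
  cat(sprintf("<rf_set: %d standardized fields, %d x %d grid>\n",
              nrow(x$fields), x$grid_size, x$grid_size))
  invisible(x)
}

#' Extract one field of an `rf_set` as a matrix
#'
#' @param rf an `rf_set` (or any J x g^2 matrix).
#' @param j field index.
#' @return a g x g matrix.
#' @export
get_field <- function(rf, j) {
  m <- if (inherits(rf, "rf_set")) rf$fields else rf
  g <- as.integer(round(sqrt(ncol(m))))
  matrix(m[j, ], g, g)
}

fftshift2 <- function(m) {
  i <- c((floor(nrow(m) / 2) + 1L):nrow(m), seq_len(floor(nrow(m) / 2)))
  j <- c((floor(ncol(m) / 2) + 1L):ncol(m), seq_len(floor(ncol(m) / 2)))
  m[i, j]
}

#' Fourier amplitude spectrum of a receptive field
#'
#' Modulus of the zero-padded 2-D Fourier transform, DC-centered.  Rows index
#' the vertical frequency `fy`, columns the horizontal frequency `fx`, both in
#' cycles/pixel on a grid of spacing `1 / (pad_factor * g)`.  Real fields give
#' Hermitian-symmetric spectra: the amplitude at (fx, fy) equals the amplitude
#' at (-fx, -fy).
#'
#' @param field g x g matrix (e.g. from [get_field()]).
#' @param pad_factor Fourier padding factor (default 4).
#' @return a P x P matrix of class `rf_spectrum` with attributes `fx`, `fy`
#'   (frequency axes, cycles/pixel) and `pad_factor`.
#' @export
amplitude_spectrum <- function(field, pad_factor = 4L) {
  stopifnot(is.matrix(field), nrow(field) == ncol(field))
  g <- nrow(field)
  P <- as.integer(pad_factor) * g
  pad <- matrix(0, P, P)
  off <- (P - g) %/% 2L
  pad[off + seq_len(g), off + seq_len(g)] <- field
  A <- fftshift2(Mod(stats::fft(pad)))
  f_axis <- (seq_len(P) - 1L - floor(P / 2)) / P
  structure(A, fx = f_axis, fy = f_axis, pad_factor = as.integer(pad_factor),
            class = c("rf_spectrum", "matrix", "array"))
}

# Bilinear interpolation of a DC-centered spectrum at arbitrary frequency
# coordinates; returns 0 outside the sampled square.
interp_spectrum <- function(spec, fx, fy) {
  ax <- attr(spec, "fx"); ay <- attr(spec, "fy")
  P <- length(ax)
  cx <- fx * P + floor(P / 2) + 1  # fractional 1-based column
  cy <- fy * P + floor(P / 2) + 1
  out <- numeric(length(cx))
  x0 <- floor(cx); y0 <- floor(cy)
  ok <- x0 >= 1 & x0 + 1 <= P & y0 >= 1 & y0 + 1 <= P
  if (any(ok)) {
    tx <- cx[ok] - x0[ok]; ty <- cy[ok] - y0[ok]
    i00 <- cbind(y0[ok], x0[ok]); i01 <- cbind(y0[ok], x0[ok] + 1)
    i10 <- cbind(y0[ok] + 1, x0[ok]); i11 <- cbind(y0[ok] + 1, x0[ok] + 1)
    out[ok] <- (1 - ty) * ((1 - tx) * spec[i00] + tx * spec[i01]) +
      ty * ((1 - tx) * spec[i10] + tx * spec[i11])
  }
  out
}

#' Preferred spatial frequency and orientation of a spectrum
#'
#' The single strongest coefficient of the amplitude spectrum, searched over
#' the non-DC half-plane (`fx > 0`, or `fx = 0` and `fy > 0`) restricted to
#' radial frequencies in (0, 0.5\] cycles/pixel.  Orientation is the angle of
#' the spatial-frequency vector, `atan2(fy, fx)` in degrees, reported modulo
#' 180 in (-90, 90\]: 0 degrees means modulation along the horizontal axis
#' (a vertically striped grating drifting horizontally).  Ties (coefficients
#' equal within a relative 1e-9) are broken toward the lowest radial
#' frequency, then the lowest orientation angle.
#'
#' @param spec an `rf_spectrum` from [amplitude_spectrum()].
#' @return list with `preferred_sf` (cycles/pixel), `preferred_ori` (degrees),
#'   `fx`, `fy` (the winning frequency vector) and `amplitude`.
#' @export
preferred_tuning <- function(spec) {
  ax <- attr(spec, "fx"); ay <- attr(spec, "fy")
  FX <- matrix(ax, nrow(spec), ncol(spec), byrow = TRUE)
  FY <- matrix(ay, nrow(spec), ncol(spec))
  f <- sqrt(FX^2 + FY^2)
  half <- (FX > 0) | (FX == 0 & FY > 0)
  cand <- which(half & f > 0 & f <= 0.5)
  if (length(cand) == 0L) stop("no candidate frequencies in the half-plane")
  amp <- spec[cand]
  amax <- max(amp)
  if (amax <= 0) stop("all-zero spectrum: preferred tuning undefined")
  top <- cand[amp >= amax * (1 - 1e-9)]
  ori_all <- atan2(FY[top], FX[top]) * 180 / pi
  ori_all[ori_all <= -90] <- ori_all[ori_all <= -90] + 180
  ord <- order(f[top], ori_all)
  w <- top[ord[1]]
  ori <- atan2(FY[w], FX[w]) * 180 / pi
  if (ori <= -90) ori <- ori + 180
  list(preferred_sf = f[w], preferred_ori = ori,
       fx = FX[w], fy = FY[w], amplitude = spec[w])
}

#' Spatial-frequency bandwidth in octaves
#'
#' Along the radial line through the spectral peak, the outermost radii at
#' which the (linearly interpolated) amplitude still reaches half the peak
#' value are located; the bandwidth is `log2(r_hi / r_lo)`.  When the profile
#' never falls below half-maximum before the grid edge (or before DC), the
#' corresponding limit is censored at the grid and the result carries
#' attribute `censored = c(lo, hi)` marking it as an upper bound.
#'
#' @param spec an `rf_spectrum`.
#' @param peak optional result of [preferred_tuning()] (recomputed if NULL).
#' @return bandwidth in octaves, with attributes `r_lo`, `r_hi`, `censored`.
#' @export
sf_bandwidth <- function(spec, peak = NULL) {
  if (is.null(peak)) peak <- preferred_tuning(spec)
  th <- atan2(peak$fy, peak$fx)
  u <- c(cos(th), sin(th))
  r_max <- 0.5 / max(abs(u))          # grid edge along this ray
  P <- length(attr(spec, "fx"))
  dr <- 1 / (8 * P)
  r <- seq(dr, r_max, by = dr)
  a <- interp_spectrum(spec, r * u[1], r * u[2])
  half <- peak$amplitude / 2
  ip <- which.min(abs(r - peak$preferred_sf))

  cross_out <- function(idx_seq) {
    # first sub-half sample walking away from the peak; linear interpolation
    for (k in seq_along(idx_seq)[-1]) {
      i0 <- idx_seq[k - 1]; i1 <- idx_seq[k]
      if (a[i1] < half) {
        t <- (half - a[i0]) / (a[i1] - a[i0])
        return(list(r = r[i0] + t * (r[i1] - r[i0]), censored = FALSE))
      }
    }
    list(r = r[idx_seq[length(idx_seq)]], censored = TRUE)
  }
  hi <- cross_out(ip:length(r))
  lo <- cross_out(ip:1)
  bw <- log2(hi$r / lo$r)
  attr(bw, "r_lo") <- lo$r
  attr(bw, "r_hi") <- hi$r
  attr(bw, "censored") <- c(lo = lo$censored, hi = hi$censored)
  bw
}

#' Orientation bandwidth in degrees
#'
#' Along the ring of constant radius through the spectral peak, the extreme
#' angles (walking away from the peak in both directions, up to +/- 90
#' degrees) at which the interpolated amplitude still reaches half the peak
#' are located; the bandwidth is their angular separation in degrees.  A
#' profile that never falls below half-maximum is censored at 180 degrees
#' (an unoriented field).
#'
#' @inheritParams sf_bandwidth
#' @return bandwidth in degrees with attribute `censored`.
#' @export
ori_bandwidth <- function(spec, peak = NULL) {
  if (is.null(peak)) peak <- preferred_tuning(spec)
  r0 <- peak$preferred_sf
  th0 <- atan2(peak$fy, peak$fx)
  half <- peak$amplitude / 2
  dphi <- 0.25 * pi / 180
  phis <- seq(0, pi / 2, by = dphi)

  scan_side <- function(sign) {
    prev <- peak$amplitude
    for (k in seq_along(phis)[-1]) {
      th <- th0 + sign * phis[k]
      a <- interp_spectrum(spec, r0 * cos(th), r0 * sin(th))
      if (a < half) {
        t <- (half - prev) / (a - prev)
        return(list(phi = phis[k - 1] + t * dphi, censored = FALSE))
      }
      prev <- a
    }
    list(phi = pi / 2, censored = TRUE)
  }
  up <- scan_side(1); dn <- scan_side(-1)
  bw <- (up$phi + dn$phi) * 180 / pi
  attr(bw, "censored") <- up$censored || dn$censored
  bw
}

#' Tuning parameters for every field of a set
#'
#' @param rf an `rf_set` (or J x g^2 matrix of fields).
#' @param pad_factor Fourier padding factor.
#' @return a data.frame with one row per field: `preferred_sf` (cycles/pixel),
#'   `preferred_ori` (degrees in (-90, 90\]), `sf_bandwidth` (octaves),
#'   `ori_bandwidth` (degrees), and logical censoring flags `sf_censored`,
#'   `ori_censored`.
#' @export
tuning_table <- function(rf, pad_factor = NULL) {
  m <- if (inherits(rf, "rf_set")) rf$fields else rf
  if (is.null(pad_factor)) {
    pad_factor <- if (inherits(rf, "rf_set")) rf$pad_factor else 4L
  }
  J <- nrow(m)
  out <- data.frame(preferred_sf = numeric(J), preferred_ori = numeric(J),
                    sf_bandwidth = numeric(J), ori_bandwidth = numeric(J),
                    sf_censored = logical(J), ori_censored = logical(J))
  for (j in seq_len(J)) {
    spec <- amplitude_spectrum(get_field(m, j), pad_factor = pad_factor)
    pk <- preferred_tuning(spec)
    sfb <- sf_bandwidth(spec, pk)
    orb <- ori_bandwidth(spec, pk)
    out$preferred_sf[j] <- pk$preferred_sf
    out$preferred_ori[j] <- pk$preferred_ori
    out$sf_bandwidth[j] <- as.numeric(sfb)
    out$ori_bandwidth[j] <- as.numeric(orb)
    out$sf_censored[j] <- any(attr(sfb, "censored"))
    out$ori_censored[j] <- isTRUE(attr(orb, "censored"))
  }
  out
}

#' Circular mean of preferred orientations
#'
#' Orientations are axial (a grating at -80 degrees is 10 degrees away from
#' one at 90), so the mean is taken on doubled angles:
#' `0.5 * Arg(mean(exp(2i * theta)))`.
#'
#' @param ori_deg orientations in degrees.
#' @return mean orientation in degrees, in (-90, 90\].
#' @export
mean_orientation <- function(ori_deg) {
  z <- mean(exp(2i * ori_deg * pi / 180))
  out <- Arg(z) * 180 / pi / 2
  if (out <= -90) out <- out + 180
  out
}

#' Sinusoidal grating image
#'
#' `cos(2 pi sf (x cos(ori) + y sin(ori)) + phase)` on a g x g grid, with
#' `x` the column index and `y` the row index (0-based).  Orientation follows
#' the package convention: it is the direction of the spatial-frequency
#' (modulation) vector, so `ori = 0` gives vertical stripes.
#'
#' @param g grid side length.
#' @param sf spatial frequency, cycles/pixel.
#' @param ori_deg orientation of the modulation vector, degrees.
#' @param phase phase offset, radians.
#' @return a g x g matrix.
#' @export
grating <- function(g, sf, ori_deg, phase = 0) {
  th <- ori_deg * pi / 180
  x <- matrix(0:(g - 1), g, g, byrow = TRUE)
  y <- matrix(0:(g - 1), g, g)
  cos(2 * pi * sf * (x * cos(th) + y * sin(th)) + phase)
}
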