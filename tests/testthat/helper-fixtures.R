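# Shared fixture builders and independent oracles for the test suite.

# Small synthetic luminance ensemble (positive pixels, 1/f structure).
make_test_ensemble <- function(n_images = 2L, size = 64L, seed = 1L,
                               bias = 1) {
  pink_noise_ensemble(synthetic_image_spec(
    n_images = n_images, size = size, orientation_bias = bias, seed = seed))
}

# Random standardized patch matrix (rows are patches).
make_random_patches <- function(n, g, seed = 1L) {
  set.seed(seed)
  standardize_patches(matrix(rnorm(n * g * g), n, g * g))
}

# Brute-force spatial "same" convolution with zero padding: shift-and-add
# over kernel taps, no Fourier transform anywhere.  Independent oracle for
# the FFT-based convolution and field reconstruction.
direct_conv_same <- function(image, kernel) {
  n <- nrow(image); m <- ncol(image)
  h <- (nrow(kernel) - 1L) %/% 2L
  padded <- matrix(0, n + 2L * h, m + 2L * h)
  padded[h + seq_len(n), h + seq_len(m)] <- image
  out <- matrix(0, n, m)
  for (dy in -h:h) {
    for (dx in -h:h) {
      k <- kernel[dy + h + 1L, dx + h + 1L]
      if (k == 0) next
      # convolution: output(y, x) += k * image(y - dy, x - dx)
      out <- out + k * padded[h + seq_len(n) - dy, h + seq_len(m) - dx]
    }
  }
  out
}

# Excess kurtosis.
excess_kurtosis <- function(x) {
  mean((x - mean(x))^4) / mean((x - mean(x))^2)^2 - 3
}

# Median spectral-energy excess kurtosis of weight patterns (unpadded DFT,
# DC bin excluded): ~6 or below for white-noise-like patterns, much larger
# for patterns with concentrated spectra.
weight_spectral_kurtosis <- function(weights, g) {
  vapply(seq_len(nrow(weights)), function(j) {
    e <- Mod(stats::fft(matrix(weights[j, ], g, g)))^2
    excess_kurtosis(as.vector(e[-1L]))
  }, numeric(1))
}

# Fourfold (90-degree-periodic) resultant of a set of axial orientations,
# and the shift between two sets measured in that space (degrees, in
# (-45, 45]).  Appropriate for ensembles biased toward both cardinal axes,
# whose doubled-angle resultant cancels by symmetry.
ori4_resultant <- function(ori_deg) sum(exp(4i * ori_deg * pi / 180))
ori4_shift <- function(ori_a, ori_b) {
  Arg(ori4_resultant(ori_b) * Conj(ori4_resultant(ori_a))) * 180 / pi / 4
}
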