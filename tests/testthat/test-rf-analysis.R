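test_that("reconstructed fields reproduce weight responses to filtered stimuli", {
  set.seed(11)
  k <- build_dog_kernel()
  W <- matrix(runif(5 * 256, -1, 1), 5, 256)
  rf <- reconstruct_fields(W, dog_params())
  expect_s3_class(rf, "rf_set")
  expect_lt(max(abs(rowMeans(rf$fields))), 1e-9)

  patches <- make_random_patches(30, 16, seed = 12)
  filtered <- t(apply(patches, 1, function(p)
    as.vector(direct_conv_same(matrix(p, 16, 16), k))))
  field_resp <- rf$fields %*% t(patches)
  weight_resp <- W %*% t(filtered)
  for (j in 1:5) expect_gt(cor(field_resp[j, ], weight_resp[j, ]), 0.99)
})

test_that("an impulse weight vector reconstructs a shifted DoG", {
  k <- build_dog_kernel(dog_params(0.6, 1.2))  # small support fits the crop
  w <- rep(0, 256)
  centre <- 8 + (8 - 1) * 16  # (row 8, col 8) in column-major order
  w[centre] <- 1
  rf <- reconstruct_fields(matrix(w, 1), k)
  f <- get_field(rf, 1)
  h <- (nrow(k) - 1) / 2
  patch <- f[8 + (-h:h), 8 + (-h:h)]
  expect_gt(cor(as.vector(patch), as.vector(k)), 0.999)
  expect_error(reconstruct_fields(matrix(0, 1, 256), k), "degenerate")
})

test_that("amplitude spectra are Hermitian with a vanishing DC for zero-mean fields", {
  set.seed(13)
  f <- matrix(rnorm(16 * 16), 16, 16)
  f <- f - mean(f)
  sp <- amplitude_spectrum(f)
  P <- nrow(sp)
  dc <- floor(P / 2) + 1L
  expect_lt(sp[dc, dc], 1e-10)
  # point symmetry through DC: A(u, v) == A(-u, -v)
  idx <- 2:P
  expect_lt(max(abs(sp[idx, idx] - sp[rev(idx), rev(idx)])), 1e-10)

  # a pure grating shows exactly two symmetric peaks at its frequency
  gsp <- amplitude_spectrum(grating(16, 0.25, 0))
  top2 <- order(gsp, decreasing = TRUE)[1:2]
  rc <- arrayInd(top2, dim(gsp))
  fx <- attr(gsp, "fx")[rc[, 2]]; fy <- attr(gsp, "fy")[rc[, 1]]
  expect_equal(sort(fx), c(-0.25, 0.25), tolerance = 1 / 64)
  expect_equal(fy, c(0, 0), tolerance = 1 / 64)
})

test_that("preferred tuning round-trips gratings and Gabors within one bin", {
  bin <- 1 / 64
  for (case in list(c(0.125, 30), c(0.25, -60), c(0.1875, 0), c(0.125, 90))) {
    pk <- preferred_tuning(amplitude_spectrum(grating(16, case[1], case[2])))
    expect_lt(abs(pk$preferred_sf - case[1]), 1.5 * bin)
    d <- abs(pk$preferred_ori - case[2]) %% 180
    expect_lt(min(d, 180 - d), 4)
  }
  gp <- data.frame(x0 = 8.5, y0 = 8.5, sf = 0.125, ori = 30,
                   sigma_x = 3, sigma_y = 3, phase = 0)
  pk <- preferred_tuning(amplitude_spectrum(get_field(gabor_field_set(gp), 1)))
  expect_lt(abs(pk$preferred_sf - 0.125), 1.5 * bin)
  expect_lt(abs(pk$preferred_ori - 30), 4)

  expect_error(preferred_tuning(amplitude_spectrum(matrix(0, 8, 8))),
               "all-zero")
})

test_that("exact ties break toward the lowest frequency, then lowest angle", {
  # unpadded spectra of exact DFT gratings give exactly equal peaks
  g <- 16
  x <- matrix(0:(g - 1), g, g, byrow = TRUE)
  y <- matrix(0:(g - 1), g, g)
  # equal-amplitude components at radial frequencies 2/16 and 4/16
  f1 <- cos(2 * pi * 2 * x / g) + cos(2 * pi * 4 * x / g)
  pk <- preferred_tuning(amplitude_spectrum(f1, pad_factor = 1))
  expect_equal(pk$preferred_sf, 2 / 16, tolerance = 1e-12)
  # equal frequency, orientations 0 and 90: lowest angle (0) wins...
  f2 <- cos(2 * pi * 2 * x / g) + cos(2 * pi * 2 * y / g)
  pk2 <- preferred_tuning(amplitude_spectrum(f2, pad_factor = 1))
  # ...where angles order within (-90, 90]
  expect_equal(pk2$preferred_ori, 0, tolerance = 1e-12)
})

test_that("spatial-frequency bandwidth matches the analytic Gabor spectrum", {
  for (sigma in c(2.5, 5)) {
    gp <- data.frame(x0 = 16.5, y0 = 16.5, sf = 0.2, ori = 0,
                     sigma_x = sigma, sigma_y = sigma, phase = 0)
    spec <- amplitude_spectrum(get_field(gabor_field_set(gp, g = 32), 1))
    pk <- preferred_tuning(spec)
    bw <- sf_bandwidth(spec, pk)
    sig_f <- 1 / (2 * pi * sigma)
    w <- sig_f * sqrt(2 * log(2))
    expect_equal(as.numeric(bw), log2((0.2 + w) / (0.2 - w)),
                 tolerance = 0.1 * log2((0.2 + w) / (0.2 - w)))
    expect_false(any(attr(bw, "censored")))
    # half-max width in linear frequency scales as 1/sigma
    if (sigma == 5) {
      width5 <- attr(bw, "r_hi") - attr(bw, "r_lo")
      expect_equal(width5 / width_2.5, 0.5, tolerance = 0.1)
      expect_lt(as.numeric(bw), bw_2.5)  # octave bandwidth shrinks too
    } else {
      width_2.5 <- attr(bw, "r_hi") - attr(bw, "r_lo")
      bw_2.5 <- as.numeric(bw)
    }
  }
})

test_that("a pure grating has near-resolution-limited bandwidths", {
  spec <- amplitude_spectrum(grating(16, 0.25, 0))
  pk <- preferred_tuning(spec)
  bw <- sf_bandwidth(spec, pk)
  expect_lt(as.numeric(bw), 0.8)   # windowed 16-px grating, ~grid limit
  expect_lt(as.numeric(ori_bandwidth(spec, pk)), 30)
})

test_that("rotating a field by 90 degrees rotates tuning and preserves bandwidths", {
  gp <- data.frame(x0 = 8.5, y0 = 8.5, sf = 0.15, ori = 20,
                   sigma_x = 2, sigma_y = 4, phase = 0.3)
  f <- get_field(gabor_field_set(gp), 1)
  f90 <- t(f)[, nrow(f):1]  # 90-degree rotation
  s1 <- amplitude_spectrum(f); s2 <- amplitude_spectrum(f90)
  p1 <- preferred_tuning(s1); p2 <- preferred_tuning(s2)
  d <- abs(p1$preferred_ori - p2$preferred_ori) %% 180
  expect_equal(min(d, 180 - d), 90, tolerance = 3)
  expect_equal(p1$preferred_sf, p2$preferred_sf, tolerance = 1 / 64)
  expect_equal(as.numeric(sf_bandwidth(s1, p1)),
               as.numeric(sf_bandwidth(s2, p2)), tolerance = 0.05)
  expect_equal(as.numeric(ori_bandwidth(s1, p1)),
               as.numeric(ori_bandwidth(s2, p2)), tolerance = 2)
})

test_that("tuning_table summarizes a field set with valid ranges", {
  gp <- data.frame(x0 = c(8, 9), y0 = c(8, 9), sf = c(0.125, 0.25),
                   ori = c(0, 45), sigma_x = c(2, 3), sigma_y = c(3, 2),
                   phase = c(0, pi / 2))
  tt <- tuning_table(gabor_field_set(gp))
  expect_equal(nrow(tt), 2L)
  expect_true(all(tt$preferred_sf > 0 & tt$preferred_sf <= 0.5))
  expect_true(all(tt$preferred_ori > -90 & tt$preferred_ori <= 90))
  expect_true(all(tt$sf_bandwidth >= 0) && all(tt$ori_bandwidth >= 0))
})

test_that("mean_orientation averages axially", {
  expect_equal(mean_orientation(c(80, -80)), 90)
  expect_equal(mean_orientation(c(10, 30)), 20)
  expect_equal(mean_orientation(c(-45, 45, 45)), 45, tolerance = 20)
})
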