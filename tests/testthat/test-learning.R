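test_that("activation applies the asymmetric saturating sigmoid", {
  W <- matrix(0, 3, 4)
  expect_equal(bcm_activation(W, rep(1, 4))$output, rep(0, 3))

  # r = 1 with k1 = 25; r = -1 with k2 = 1
  W <- rbind(c(1, 0), c(-1, 0))
  a <- bcm_activation(W, c(1, 0))
  expect_equal(a$output[1], 25 * tanh(1), tolerance = 1e-12)
  expect_equal(a$output[2], tanh(-1), tolerance = 1e-12)
  expect_error(bcm_activation(matrix(NaN, 1, 1), 1), "non-finite")

  # bounds on random inputs (tanh saturates to exactly 1 in floating point,
  # so the open analytic bound closes numerically)
  set.seed(1)
  W <- matrix(rnorm(20 * 16, sd = 3), 20, 16)
  c_out <- bcm_activation(W, matrix(rnorm(50 * 16), 50, 16))$output
  expect_true(all(c_out <= 25) && all(c_out >= -1))
})

test_that("divisive normalization matches its closed forms and limits", {
  expect_equal(contrast_normalize(rep(0, 5), norm_params(1, 2)), rep(0, 5))
  expect_equal(contrast_normalize(1, norm_params(1, 2)), 1)  # 2*1/(1+1)

  set.seed(2)
  cc <- rnorm(12)
  np <- norm_params(alpha = 1e9, beta = 3)
  expect_equal(contrast_normalize(cc, np), (3 / 1e9) * cc, tolerance = 1e-6)

  # matrix form normalizes each column with its own pool
  M <- matrix(rnorm(12 * 4), 12, 4)
  byhand <- sapply(seq_len(4), function(i) contrast_normalize(M[, i],
                                                             norm_params(2, 5)))
  expect_equal(contrast_normalize(M, norm_params(2, 5)), byhand)

  # denominator >= alpha implies the analytic output bound
  cn <- contrast_normalize(rnorm(8, sd = 100), norm_params(0.5, 2))
  expect_true(all(abs(cn) <= 2 * 25 / 0.5))
})

test_that("weight and threshold updates follow the BCM rule", {
  expect_equal(weight_delta(c(1, 1), c(1, 1), c(1, 2, 3), eta = 0.1),
               matrix(0, 2, 3))
  expect_equal(weight_delta(2, 1, 1, eta = 1e-5), matrix(2e-5, 1, 1))
  # anti-Hebbian: 0 < c < theta with positive input decreases the weight
  expect_lt(weight_delta(0.5, 2, 1, eta = 1e-3)[1, 1], 0)

  expect_equal(threshold_delta(c(2, 3), c(4, 9), tau = 1000), c(0, 0))
  expect_equal(threshold_delta(1, 0, tau = 1000), 0.001)
})

test_that("annealing is a stepwise 0.1% decrement every 1000 iterations", {
  expect_equal(anneal_eta(1e-5, 0), 1e-5)
  expect_equal(anneal_eta(1e-5, 999), 1e-5)
  expect_equal(anneal_eta(1e-5, 1000), 9.99e-6)
  expect_equal(anneal_eta(1e-5, 1e6), 1e-5 * 0.999^1000)
})

test_that("training is inert at eta 0, deterministic, and resumable", {
  ps <- make_random_patches(50, 6, seed = 4)
  cfg <- learning_config(eta0 = 0, n_iterations = 500, n_neurons = 5, seed = 2)
  st0 <- init_network(cfg, 36)
  st <- train_network(ps, cfg)
  expect_equal(st$weights, st0$weights)

  cfg <- learning_config(n_iterations = 3000, n_neurons = 5, seed = 2,
                         eta0 = 1e-3)
  a <- train_network(ps, cfg)
  b <- train_network(ps, cfg)
  expect_identical(a$weights, b$weights)

  # resume reproduces the uninterrupted run bit for bit
  part <- train_network(ps, cfg, n_steps = 1100)
  full <- train_network(ps, cfg, state = part)
  expect_identical(full$weights, a$weights)
  expect_identical(full$thresholds, a$thresholds)
  expect_equal(full$iteration, 3000)
})

test_that("one NBCM step reduces to a scaled BCM step when alpha dominates", {
  set.seed(5)
  d <- rnorm(16)
  W <- matrix(rnorm(4 * 16), 4, 16)
  theta <- runif(4)
  cc <- bcm_activation(W, d)$output
  np <- norm_params(alpha = 1e8, beta = 4)
  cp <- contrast_normalize(cc, np)
  scaled <- cc * np$beta / np$alpha
  dW_nbcm <- weight_delta(cp, theta, d, eta = 1e-5)
  dW_bcm <- weight_delta(scaled, theta, d, eta = 1e-5)
  expect_lt(max(abs(dW_nbcm - dW_bcm)), 1e-6)
  expect_lt(max(abs(threshold_delta(cp, theta, 1000) -
                    threshold_delta(scaled, theta, 1000))), 1e-6)
})

test_that("the trained step matches a manual step, for all NBCM threshold wirings", {
  ps <- make_random_patches(10, 4, seed = 6)
  sched <- rep(3L, 10)
  for (ndt in c(TRUE, FALSE)) {
    cfg <- learning_config(n_iterations = 1, n_neurons = 3, seed = 9,
                           eta0 = 1e-2, mode = "nbcm",
                           norm_drives_threshold = ndt)
    np <- norm_params(2, 3)
    st0 <- init_network(cfg, 16)
    st1 <- train_network(ps, cfg, norm = np, schedule = sched)
    d <- ps[3, ]
    cc <- bcm_activation(st0$weights, d)$output
    cp <- contrast_normalize(cc, np)
    W_exp <- st0$weights + weight_delta(cp, st0$thresholds, d, eta = 1e-2)
    th_src <- if (ndt) cp else cc
    th_exp <- st0$thresholds + threshold_delta(th_src, st0$thresholds, cfg$tau)
    expect_equal(st1$weights, W_exp, tolerance = 1e-12)
    expect_equal(st1$thresholds, th_exp, tolerance = 1e-12)
  }
})

test_that("threshold converges geometrically to c^2 on a constant stimulus", {
  # frozen weights, one repeated patch: theta(t) = c^2 (1 - (1 - 1/tau)^t)
  ps <- make_random_patches(1, 4, seed = 8)
  cfg <- learning_config(n_iterations = 5000, n_neurons = 2, seed = 3,
                         tau = 1000)
  st0 <- init_network(cfg, 16)
  cc <- bcm_activation(st0, ps[1, ])$output
  st <- train_network(ps, cfg, state = st0, freeze_weights = TRUE,
                      schedule = rep(1L, 5000))
  expect_equal(st$weights, st0$weights)
  expect_equal(st$thresholds, cc^2 * (1 - (1 - 1 / 1000)^5000),
               tolerance = 1e-9)
})

test_that("two-pattern BCM recovers the selective fixed point", {
  env <- two_pattern_environment(c(0.5, 0.5), dimension = 2, n_draws = 4e5,
                                 seed = 42)
  cfg <- learning_config(eta0 = 5e-5, n_iterations = 4e5, n_neurons = 1,
                         linear_output = TRUE, mode = "bcm", seed = 11)
  st0 <- init_network(cfg, 2)
  r0 <- drop(st0$weights %*% t(env$patterns))
  pat <- env$patterns * ifelse(r0 < 0, -1, 1)  # pattern sign is a convention
  st <- train_network(pat, cfg, state = st0, schedule = env$schedule)
  resp <- drop(st$weights %*% t(pat))
  sel <- which.max(abs(resp))
  expect_equal(resp[sel], 2, tolerance = 0.05)
  expect_lt(abs(resp[-sel]), 0.05)
  expect_equal(st$thresholds, 2, tolerance = 0.05)
})

test_that("divergence aborts with a state snapshot condition", {
  ps <- make_random_patches(20, 4, seed = 10)
  cfg <- learning_config(eta0 = 10, n_iterations = 5e4, n_neurons = 4,
                         linear_output = TRUE, seed = 1)
  err <- tryCatch(train_network(ps, cfg), nbcm_divergence = function(e) e)
  expect_s3_class(err, "nbcm_divergence")
  expect_s3_class(err$state, "network_state")
})

test_that("NBCM mode requires normalization parameters", {
  ps <- make_random_patches(5, 4, seed = 1)
  cfg <- learning_config(n_iterations = 10, n_neurons = 2, mode = "nbcm")
  expect_error(train_network(ps, cfg), "norm_params")
})

test_that("network checkpoints round-trip through text files", {
  dir <- withr::local_tempdir()
  ps <- make_random_patches(20, 4, seed = 2)
  cfg <- learning_config(n_iterations = 100, n_neurons = 3, seed = 5,
                         mode = "nbcm", eta0 = 1e-3)
  st <- train_network(ps, cfg, norm = norm_params(1, 2))
  save_network(st, dir)
  back <- load_network(dir)
  expect_equal(back$weights, st$weights, tolerance = 1e-12)
  expect_equal(back$thresholds, st$thresholds, tolerance = 1e-12)
  expect_equal(back$iteration, st$iteration)
  expect_equal(back$config$mode, "nbcm")
  expect_equal(back$norm$beta, 2)
})
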