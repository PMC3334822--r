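test_that("field responses are matched-filter-like and linear", {
  p <- make_random_patches(10, 8, seed = 20)
  f <- p[1:4, ]
  r <- field_responses(f, p)
  expect_equal(dim(r), c(4L, 10L))
  # a field identical to a standardized patch responds with its squared norm
  expect_equal(r[1, 1], sum(p[1, ]^2))
  expect_equal(r[1, 1], max(abs(r[1, ])))
  # orthogonal field/patch gives zero
  f2 <- rbind(c(1, -1, rep(0, 62)), c(1, 1, rep(0, 62)))
  expect_equal(field_responses(f2, matrix(c(1, 1, rep(0, 62)), 1))[1, 1], 0)
  # linearity
  expect_equal(field_responses(f, 2 * p[1, , drop = FALSE] -
                                    3 * p[2, , drop = FALSE]),
               2 * r[, 1, drop = FALSE] - 3 * r[, 2, drop = FALSE])
  expect_error(field_responses(f, matrix(1, 2, 9)), "differ")
})

test_that("lifetime sparseness matches closed forms and the exponential oracle", {
  expect_equal(lifetime_sparseness(matrix(3, 2, 50))$values, c(0, 0))
  onehot <- matrix(0, 1, 20); onehot[1, 7] <- 5
  expect_equal(lifetime_sparseness(onehot)$values, 1 - 1 / 20)
  # |r| ~ Exponential(1): E[r]^2 / E[r^2] = 1/2, so S = 0.5
  set.seed(21)
  r <- matrix(rexp(1e5), 1)
  expect_equal(lifetime_sparseness(r)$mean, 0.5, tolerance = 0.01)
  # all-zero row is reported missing, not propagated
  m <- rbind(rexp(10), rep(0, 10))
  ls <- lifetime_sparseness(m)
  expect_true(is.na(ls$values[2]) && !is.na(ls$mean))
})

test_that("population sparseness is lifetime sparseness of the transpose", {
  set.seed(22)
  m <- matrix(rnorm(30 * 40), 30, 40)
  expect_equal(population_sparseness(m), lifetime_sparseness(t(m)))
  # one active neuron per stimulus among J
  J <- 16
  m1 <- diag(J)[, rep(1:J, 2)]
  expect_equal(population_sparseness(m1)$values, rep(1 - 1 / J, 2 * J))
  # identical rows: every stimulus has constant population response
  expect_equal(population_sparseness(matrix(rep(rexp(10), each = 5), 5))$mean, 0)
})

test_that("dispersal matches its closed forms", {
  base <- rep(c(-1, 1), 10)
  expect_equal(dispersal(matrix(base, 256, 20, byrow = TRUE))$D, 256)
  single <- rbind(base, matrix(0, 5, 20))
  expect_equal(dispersal(single)$D, 1)
  expect_equal(dispersal(rbind(base, 0.5 * base))$D, 1.5)
  expect_equal(dispersal(rbind(base, 0.5 * base))$normalized, 0.75)
  expect_error(dispersal(matrix(1, 3, 5)), "zero response variance")
})

test_that("orthogonality scores orthogonal, identical, and oblique sets correctly", {
  B <- sinusoid_basis(8)
  expect_equal(orthogonality(B[1:20, ]), 1)
  expect_equal(orthogonality(rbind(B[1, ], B[1, ], B[1, ])), 0)
  # two unit fields at 60 degrees: |cos| = 0.5
  v1 <- c(1, 0, rep(0, 14)); v2 <- c(0.5, sqrt(3) / 2, rep(0, 14))
  expect_equal(orthogonality(rbind(v1, v2)), 0.5)
  expect_error(orthogonality(rbind(v1, rep(0, 16))), "zero field")
  expect_error(orthogonality(matrix(1, 1, 4)), "at least two")
})

test_that("rank counts singular values above the absolute tolerance", {
  g <- 8
  B <- sinusoid_basis(g) * g  # orthogonal rows with norm g = 8 > 2.5
  expect_equal(field_rank(B), 64L)
  proto <- B[5, , drop = FALSE]
  expect_equal(field_rank(proto[rep(1, 10), ]), 1L)
  for (k in c(3, 17)) {
    stack <- rbind(B[1:k, ], B[sample(1:k, 20, replace = TRUE), ])
    expect_equal(field_rank(stack), sum(svd(stack)$d > 2.5))  # SVD oracle
    expect_equal(field_rank(stack), k)
  }
  # scale below tolerance: rank collapses
  expect_equal(field_rank(B * 0.1), 0L)
})

test_that("the sinusoid basis is a complete orthonormal set of g^2 stimuli", {
  for (g in c(8L, 16L)) {
    B <- sinusoid_basis(g)
    expect_equal(dim(B), c(g^2, g^2))
    expect_lt(max(abs(sqrt(rowSums(B^2)) - 1)), 1e-12)
    gram <- B %*% t(B)
    expect_lt(max(abs(gram - diag(g^2))), 1e-10)
    # completeness: any image is exactly recovered from its projections
    set.seed(23)
    img <- rnorm(g^2)
    expect_equal(drop(t(B) %*% (B %*% img)), img, tolerance = 1e-10)
  }
  expect_error(sinusoid_basis(7), "even")
  fr <- attr(sinusoid_basis(16), "freq")
  expect_equal(sum(fr$phase == "cos") - sum(fr$phase == "sin"), 4L)
})

test_that("coverage equals projection residuals and matches a dense oracle", {
  g <- 8
  B <- sinusoid_basis(g)
  full <- B * g
  cv <- coverage(full)
  expect_equal(cv$R, 1)
  expect_lt(max(cv$m), 1e-10)

  half <- full[1:32, ]
  cvh <- coverage(half)
  expect_equal(cvh$R, 0.5)
  expect_equal(sort(unique(round(cvh$m, 10))), c(0, 1))

  # all singular values under the tolerance: decoding is zero, R = 0
  expect_equal(coverage(full * 0.01)$R, 0)

  # dense least-squares oracle on random fields (rank above tolerance)
  set.seed(24)
  f <- matrix(rnorm(20 * g^2, sd = 2), 20, g^2)
  cvr <- coverage(f)
  qrq <- qr.Q(qr(t(f)))  # orthonormal basis of the row space
  m_oracle <- sapply(seq_len(g^2), function(i) {
    x <- B[i, ]
    sum((x - qrq %*% (t(qrq) %*% x))^2)
  })
  expect_equal(sum(svd(f)$d > 2.5), 20L)  # no truncation in this instance
  expect_equal(cvr$m, m_oracle, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(cvr$R, 1 - mean(m_oracle), tolerance = 1e-8)
})

test_that("coverage and rank are monotone in added fields", {
  set.seed(25)
  g <- 8
  f <- matrix(rnorm(10 * g^2, sd = 2), 10, g^2)
  B <- sinusoid_basis(g)
  prevR <- -Inf; prevRank <- -1L
  for (k in c(2, 5, 10)) {
    cv <- coverage(f[1:k, ], basis = B)
    expect_gte(cv$R, prevR)
    expect_gte(cv$rank, prevRank)
    prevR <- cv$R; prevRank <- cv$rank
  }
})

test_that("coding_report satisfies its invariants on random inputs", {
  set.seed(26)
  g <- 8
  fields <- standardize_patches(matrix(rnorm(12 * g^2), 12, g^2))
  patches <- make_random_patches(50, g, seed = 27)
  rep <- coding_report(fields, patches)
  expect_true(rep$lifetime_sparseness >= 0 && rep$lifetime_sparseness <= 1)
  expect_true(rep$population_sparseness >= 0 && rep$population_sparseness <= 1)
  expect_lte(rep$coverage, 1)
  expect_true(rep$dispersal_raw >= 1 && rep$dispersal_raw <= 12)
  expect_true(rep$rank >= 0 && rep$rank <= 12)
  expect_equal(rep$reconstruction_error, 1 - rep$coverage)
  expect_output(print(rep), "orthogonality")

  # coverage map arranges the per-sinusoid errors on the frequency grid
  cm <- coverage_map(rep$coverage_detail, g)
  expect_equal(dim(cm), c(g, g))
  expect_true(all(cm >= 0 & cm <= 1 + 1e-12))
})
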