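#' Responses of reconstructed fields to evaluation patches
#'
#' Linear responses: flattened fields times patches.  Evaluation patches are
#' log-transformed image fragments that are *not* DoG-filtered: the
#' reconstructed fields already absorb the DoG, so they act on the stimulus
#' directly.
#'
#' @param fields an `rf_set` or J x g^2 matrix.
#' @param patches a `patch_set` or N x g^2 matrix.
#' @return J x N response matrix.
#' @export
field_responses <- function(fields, patches) {
  f <- if (inherits(fields, "rf_set")) fields$fields else fields
  p <- if (inherits(patches, "patch_set")) patches$data else patches
  if (ncol(f) != ncol(p)) stop("field and patch dimensions differ")
  f %*% t(p)
}

sparseness_rows <- function(m, rectify) {
  if (rectify) m <- abs(m)
  mu <- rowMeans(m)
  mu2 <- rowMeans(m^2)
  s <- 1 - mu^2 / mu2
  s[mu2 == 0] <- NA_real_  # all-zero response row: undefined
  s
}

#' Lifetime sparseness
#'
#' Vinje-Gallant sparseness `S = 1 - E[r]^2 / E[r^2]` of each neuron's
#' responses across stimuli; `S = 0` for perfectly constant responses and
#' `1 - 1/n` for a one-hot neuron over n stimuli.  Responses are rectified to
#' magnitudes first by default (signed near-zero-mean responses would
#' degenerate toward S = 1 regardless of shape); set `rectify = FALSE` for the
#' literal signed statistic.  Rows with no nonzero response give `NA`.
#'
#' @param responses J x N response matrix (neurons x stimuli).
#' @param rectify take absolute values first (default `TRUE`).
#' @return list with `values` (per-neuron S) and `mean` (population summary,
#'   NA rows dropped).
#' @export
lifetime_sparseness <- function(responses, rectify = TRUE) {
  s <- sparseness_rows(responses, rectify)
  list(values = s, mean = mean(s, na.rm = TRUE))
}

#' Population sparseness
#'
#' The same statistic applied across neurons for each single stimulus, then
#' averaged across stimuli: identically [lifetime_sparseness()] of the
#' transposed response matrix.
#'
#' @inheritParams lifetime_sparseness
#' @return list with `values` (per-stimulus S) and `mean`.
#' @export
population_sparseness <- function(responses, rectify = TRUE) {
  lifetime_sparseness(t(responses), rectify = rectify)
}

#' Dispersal of response variance across the population
#'
#' `D = sum_j sigma_j / max_j sigma_j`, where `sigma_j` is the standard
#' deviation of neuron j's responses; D ranges from 1 (a single responsive
#' neuron) to J (all neurons equally responsive).  The normalized form `D / J`
#' in \[1/J, 1\] is also returned, which is the conventional summary for
#' comparing populations of different size.
#'
#' @param responses J x N response matrix.
#' @return list with `D`, `normalized` (= D / J), and `sigma`.
#' @export
dispersal <- function(responses) {
  sigma <- apply(responses, 1L, sd)
  if (max(sigma) == 0) stop("all neurons have zero response variance")
  d <- sum(sigma / max(sigma))
  list(D = d, normalized = d / nrow(responses), sigma = sigma)
}

#' Orthogonality of a field set
#'
#' One minus the mean absolute cosine similarity over all unordered distinct
#' pairs of flattened fields (each field normalized so its scalar product with
#' itself is 1).  A perfectly orthogonal set scores 1; identical fields score
#' 0.
#'
#' @param fields an `rf_set` or J x g^2 matrix with J >= 2 and no zero rows.
#' @return scalar in \[0, 1\].
#' @export
orthogonality <- function(fields) {
  f <- if (inherits(fields, "rf_set")) fields$fields else fields
  if (nrow(f) < 2L) stop("need at least two fields")
  nrm <- sqrt(rowSums(f^2))
  if (any(nrm == 0)) stop("zero field encountered")
  fn <- f / nrm
  gram <- fn %*% t(fn)
  1 - mean(abs(gram[upper.tri(gram)]))
}

#' Numerical rank of the field matrix
#'
#' Number of singular values of the (rows = flattened fields) matrix
#' exceeding the absolute tolerance, default 2.5.  The tolerance is
#' meaningful because standardized fields have row norm ~ g (sqrt(g^2 - 1)).
#'
#' @param fields an `rf_set` or matrix.
#' @param tol absolute singular-value cutoff.
#' @return integer rank.
#' @export
field_rank <- function(fields, tol = 2.5) {
  f <- if (inherits(fields, "rf_set")) fields$fields else fields
  sum(svd(f, nu = 0, nv = 0)$d > tol)
}

#' Complete real sinusoid basis on a square grid
#'
#' For every distinct 2-D integer frequency (u, v) of the g x g discrete
#' Fourier grid (one representative per conjugate pair), a cosine-phase and a
#' sine-phase sinusoid, each scaled to unit Euclidean norm; the DC and
#' Nyquist-axis self-conjugate frequencies contribute a single cosine-only
#' member.  The g^2 stimuli form a complete orthonormal basis of the grid
#' (for g = 16: 256 sinusoids, an odd-even pair at every orientation and
#' spatial frequency).
#'
#' @param g even grid side length.
#' @return a g^2 x g^2 matrix with stimuli in rows (column-major flattening),
#'   with attribute `freq`: a data.frame of `u`, `v` (integer frequencies
#'   along x/columns and y/rows), centered `fx`, `fy` in cycles/pixel, radial
#'   `f`, and `phase` ("cos"/"sin") per stimulus.
#' @export
sinusoid_basis <- function(g) {
  g <- as.integer(g)
  if (g %% 2L != 0L) stop("g must be even")
  x <- matrix(0:(g - 1), g, g, byrow = TRUE)  # column index
  y <- matrix(0:(g - 1), g, g)                # row index
  rows <- list(); info <- list(); k <- 0L
  for (u in 0:(g - 1)) {
    for (v in 0:(g - 1)) {
      cu <- (g - u) %% g; cv <- (g - v) %% g
      keep <- (u < cu) || (u == cu && v <= cv)
      if (!keep) next
      a <- 2 * pi * (u * x + v * y) / g
      self_conj <- (u == cu && v == cv)
      fx <- (if (u > g / 2) u - g else u) / g
      fy <- (if (v > g / 2) v - g else v) / g
      cz <- cos(a)
      k <- k + 1L
      rows[[k]] <- as.vector(cz) / sqrt(sum(cz^2))
      info[[k]] <- data.frame(u = u, v = v, fx = fx, fy = fy,
                              f = sqrt(fx^2 + fy^2), phase = "cos")
      if (!self_conj) {
        sz <- sin(a)
        k <- k + 1L
        rows[[k]] <- as.vector(sz) / sqrt(sum(sz^2))
        info[[k]] <- data.frame(u = u, v = v, fx = fx, fy = fy,
                                f = sqrt(fx^2 + fy^2), phase = "sin")
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "freq") <- do.call(rbind, info)
  out
}

#' Spectral coverage: sinusoid encode/decode quality
#'
#' Each unit-norm basis sinusoid `x` is encoded by the field matrix `F`
#' (`r = F x`) and decoded with the tolerance-truncated pseudo-inverse
#' (`x_hat = pinv(F, tol) r`, singular values <= tol discarded).  The
#' decode is the orthogonal projection of `x` onto the retained right
#' singular subspace, so the per-sinusoid squared residual
#' `m_i = ||x - x_hat||^2` lies in \[0, 1\] and the coverage
#' `R = 1 - mean(m_i)` is 1 exactly for a complete invertible code.
#'
#' @param fields an `rf_set` or J x g^2 matrix of standardized fields.
#' @param tol absolute singular-value cutoff for the pseudo-inverse
#'   (default 2.5).
#' @param basis optional precomputed [sinusoid_basis()] (saves recomputation).
#' @return list with `R`, `m` (per-sinusoid squared error), `rank` (retained
#'   singular values), and `freq` (the basis frequency table).
#' @export
coverage <- function(fields, tol = 2.5, basis = NULL) {
  f <- if (inherits(fields, "rf_set")) fields$fields else fields
  g <- as.integer(round(sqrt(ncol(f))))
  if (is.null(basis)) basis <- sinusoid_basis(g)
  sv <- svd(f, nu = 0)
  k <- sum(sv$d > tol)
  X <- t(basis)  # g^2 x n, stimuli in columns
  if (k > 0L) {
    vk <- sv$v[, seq_len(k), drop = FALSE]
    resid <- X - vk %*% (t(vk) %*% X)
  } else {
    resid <- X
  }
  m <- colSums(resid^2)
  list(R = 1 - mean(m), m = m, rank = k, freq = attr(basis, "freq"))
}

#' Arrange per-sinusoid coverage errors on the frequency plane
#'
#' Averages the cosine/sine members of each frequency and mirrors each value
#' to its conjugate, giving a DC-centered g x g error map (the analogue of a
#' reconstruction-quality spectrum plot).
#'
#' @param cov result of [coverage()].
#' @param g grid side length.
#' @return g x g matrix with attribute `fx`/`fy` axes; entry (i, j) is the
#'   mean squared decode error of the sinusoid at that frequency.
#' @export
coverage_map <- function(cov, g) {
  g <- as.integer(g)
  acc <- matrix(0, g, g); cnt <- matrix(0L, g, g)
  fr <- cov$freq
  for (i in seq_len(nrow(fr))) {
    u <- fr$u[i]; v <- fr$v[i]
    for (pr in list(c(u, v), c((g - u) %% g, (g - v) %% g))) {
      r <- pr[2] + 1L; cc <- pr[1] + 1L
      acc[r, cc] <- acc[r, cc] + cov$m[i]
      cnt[r, cc] <- cnt[r, cc] + 1L
    }
  }
  map <- fftshift2(acc / pmax(cnt, 1L))
  f_axis <- (seq_len(g) - 1L - floor(g / 2)) / g
  structure(map, fx = f_axis, fy = f_axis)
}

#' Full coding-quality report for a field set
#'
#' Computes the six population-coding metrics used to compare BCM and NBCM
#' codes: mean per-sinusoid reconstruction error and coverage R, pairwise
#' orthogonality, numerical rank (tolerance 2.5), mean lifetime sparseness,
#' mean population sparseness, and dispersal (raw and normalized by J).
#'
#' @param fields an `rf_set` or J x g^2 matrix of standardized fields.
#' @param patches evaluation stimuli (`patch_set` or matrix): log-transformed,
#'   *not* DoG-filtered image fragments.
#' @param tol singular-value tolerance for rank and pseudo-inverse.
#' @param rectify rectify responses for the sparseness statistics.
#' @param basis optional precomputed [sinusoid_basis()].
#' @return an object of class `coding_report`.
#' @export
coding_report <- function(fields, patches, tol = 2.5, rectify = TRUE,
                          basis = NULL) {
  f <- if (inherits(fields, "rf_set")) fields$fields else fields
  resp <- field_responses(f, patches)
  cov <- coverage(f, tol = tol, basis = basis)
  disp <- dispersal(resp)
  structure(list(
    reconstruction_error = mean(cov$m),
    coverage = cov$R,
    orthogonality = orthogonality(f),
    rank = field_rank(f, tol = tol),
    lifetime_sparseness = lifetime_sparseness(resp, rectify)$mean,
    population_sparseness = population_sparseness(resp, rectify)$mean,
    dispersal = disp$normalized,
    dispersal_raw = disp$D,
    n_neurons = nrow(f),
    n_stimuli = ncol(resp),
    tol = tol,
    coverage_detail = cov
  ), class = "coding_report")
}

#' @export
print.coding_report <- function(x, ...) {
  cat(sprintf("Coding properties (%d fields, %d evaluation stimuli)\n",
              x$n_neurons, x$n_stimuli))
  rows <- c(
    "mean reconstruction error" = x$reconstruction_error,
    "coverage R" = x$coverage,
    "orthogonality" = x$orthogonality,
    "rank" = x$rank,
    "lifetime sparseness" = x$lifetime_sparseness,
    "population sparseness" = x$population_sparseness,
    "dispersal (/J)" = x$dispersal,
    "dispersal (raw)" = x$dispersal_raw
  )
  for (nm in names(rows)) cat(sprintf("  %-26s %9.4f\n", nm, rows[[nm]]))
  invisible(x)
}
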