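#' Image ensembles
#'
#' Light-weight container for a set of equally sized grayscale luminance
#' images.  Pixel values must be strictly positive because the first stage of
#' the retinal model is a log transform (photoreceptor light adaptation).
#'
#' @param images a list of numeric matrices (or a single matrix), all with the
#'   same dimensions.
#' @param check_positive validate that every pixel is > 0 (default `TRUE`).
#'   Positivity is only a hard requirement for [log_transform()]; ensembles of
#'   already log-transformed or filtered images may switch the check off.
#' @return an object of class `image_ensemble`: a list with elements `images`
#'   (list of matrices) and `dim` (common height/width).
#' @export
image_ensemble <- function(images, check_positive = TRUE) {
  if (is.matrix(images)) images <- list(images)
  if (!is.list(images) || length(images) == 0L) {
    stop("'images' must be a non-empty list of numeric matrices")
  }
  ok <- vapply(images, function(im) is.matrix(im) && is.numeric(im), logical(1))
  if (!all(ok)) stop("all ensemble members must be numeric matrices")
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all images in an ensemble must share dimensions")
  }
  if (check_positive) {
    bad <- vapply(images, function(im) any(!is.finite(im)) || any(im <= 0),
                  logical(1))
    if (any(bad)) {
      stop("images ", paste(which(bad), collapse = ", "),
           " contain non-positive or non-finite pixels")
    }
  }
  structure(list(images = images, dim = dims[, 1]), class = "image_ensemble")
}

#' @export
print.image_ensemble <- function(x, ...) {
  cat(sprintf("<image_ensemble: %d image(s), %d x %d>\n",
              length(x$images), x$dim[1], x$dim[2]))
  invisible(x)
}

#' @export
length.image_ensemble <- function(x) length(x$images)

as_image_list <- function(x) {
  if (inherits(x, "image_ensemble")) x$images
  else if (is.matrix(x)) list(x)
  else if (is.list(x)) x
  else stop("expected an image_ensemble, matrix, or list of matrices")
}

#' Log-transform an image ensemble
#'
#' Takes the natural logarithm of every pixel, the standard model of light
#' adaptation in individual photoreceptors.  Images containing non-positive
#' pixels cannot be log-transformed; they are dropped with a diagnostic
#' warning (an error is raised if no image survives).
#'
#' @param images an [image_ensemble()], matrix, or list of matrices.
#' @return an `image_ensemble` of log-luminance images (positivity check off:
#'   log values are signed).
#' @export
log_transform <- function(images) {
  imgs <- as_image_list(images)
  bad <- vapply(imgs, function(im) any(!is.finite(im)) || any(im <= 0),
                logical(1))
  if (any(bad)) {
    warning(sprintf(
      "dropping %d image(s) with non-positive pixels (indices: %s)",
      sum(bad), paste(which(bad), collapse = ", ")))
    imgs <- imgs[!bad]
  }
  if (length(imgs) == 0L) stop("no image with strictly positive pixels")
  image_ensemble(lapply(imgs, log), check_positive = FALSE)
}

#' Difference-of-Gaussians filter parameters
#'
#' Center/surround standard deviations of the retinal ganglion cell (RGC)
#' spatial filter, in pixels.  The defaults (0.75 center, 2.25 surround, a 1:3
#' ratio) are typical of retina/LGN receptive fields.  The discrete kernel is
#' truncated to a square of half-width `ceiling(4 * sigma_surround)` pixels,
#' which captures essentially all (> 99.99%) of the surround Gaussian volume.
#'
#' @param sigma_center standard deviation of the excitatory center Gaussian
#'   (pixels).
#' @param sigma_surround standard deviation of the inhibitory surround
#'   Gaussian (pixels); must exceed `sigma_center`.
#' @param kernel_halfwidth half-width of the square support (pixels); defaults
#'   to `ceiling(4 * sigma_surround)`.
#' @return an object of class `dog_params`.
#' @export
dog_params <- function(sigma_center = 0.75, sigma_surround = 2.25,
                       kernel_halfwidth = NULL) {
  if (!(is.numeric(sigma_center) && sigma_center > 0)) {
    stop("sigma_center must be > 0")
  }
  if (!(is.numeric(sigma_surround) && sigma_surround > sigma_center)) {
    stop("sigma_surround must exceed sigma_center")
  }
  if (is.null(kernel_halfwidth)) {
    kernel_halfwidth <- as.integer(ceiling(4 * sigma_surround))
  }
  kernel_halfwidth <- as.integer(kernel_halfwidth)
  if (kernel_halfwidth < 1L) stop("kernel_halfwidth must be >= 1")
  structure(list(sigma_center = sigma_center,
                 sigma_surround = sigma_surround,
                 kernel_halfwidth = kernel_halfwidth),
            class = "dog_params")
}

#' Build the discrete difference-of-Gaussians kernel
#'
#' Center Gaussian minus surround Gaussian on a square grid.  The surround is
#' rescaled so that the *sampled* kernel sums exactly to zero (a zero-DC,
#' volume-balanced filter): balancing the discrete sums rather than the
#' analytic volumes avoids a residual DC term from truncation/sampling.
#'
#' @param params a [dog_params()] object (or arguments passed on to it).
#' @param ... forwarded to [dog_params()] when `params` is missing.
#' @return a square numeric matrix of odd size `2 * kernel_halfwidth + 1`,
#'   with attribute `params`.  Its entries sum to zero within 1e-10 and the
#'   central (center-Gaussian-dominated) element is the maximum.
#' @export
build_dog_kernel <- function(params = dog_params(), ...) {
  if (!inherits(params, "dog_params")) params <- dog_params(params, ...)
  h <- params$kernel_halfwidth
  x <- -h:h
  r2 <- outer(x^2, x^2, `+`)
  g_c <- exp(-r2 / (2 * params$sigma_center^2))
  g_s <- exp(-r2 / (2 * params$sigma_surround^2))
  kernel <- g_c - (sum(g_c) / sum(g_s)) * g_s
  attr(kernel, "params") <- params
  kernel
}

#' 2-D "same" convolution with zero padding
#'
#' Linear (zero-padded) convolution computed in the Fourier domain, cropped to
#' the size of the input.  The kernel must have odd dimensions so that the
#' output is centered on the input grid.
#'
#' @param image numeric matrix.
#' @param kernel numeric matrix with odd dimensions.
#' @return matrix with the dimensions of `image`.
#' @export
conv2_same <- function(image, kernel) {
  nk <- nrow(kernel); mk <- ncol(kernel)
  if (nk %% 2 == 0 || mk %% 2 == 0) stop("kernel dimensions must be odd")
  ni <- nrow(image); mi <- ncol(image)
  n <- ni + nk - 1L; m <- mi + mk - 1L
  a <- matrix(0, n, m); a[seq_len(ni), seq_len(mi)] <- image
  b <- matrix(0, n, m); b[seq_len(nk), seq_len(mk)] <- kernel
  full <- Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / (n * m)
  full[(nk - 1L) / 2L + seq_len(ni), (mk - 1L) / 2L + seq_len(mi)]
}

#' Filter an image with the RGC kernel and discard contaminated borders
#'
#' Convolves with the DoG kernel in "same" mode (zero padding) and removes a
#' border of `crop` pixels on every side, where the zero padding contaminates
#' the result.  A 256 x 256 image with the default 10-pixel crop yields a
#' 236 x 236 model-RGC response map.
#'
#' @param image numeric matrix (a log-luminance image), or an
#'   [image_ensemble()]/list thereof.
#' @param kernel DoG kernel from [build_dog_kernel()].
#' @param crop border width to discard, in pixels (default 10).
#' @return a matrix (or `image_ensemble` when given several images).
#' @export
filter_and_crop <- function(image, kernel, crop = 10L) {
  crop <- as.integer(crop)
  if (!is.matrix(image)) {
    imgs <- as_image_list(image)
    return(image_ensemble(lapply(imgs, filter_and_crop, kernel = kernel,
                                 crop = crop),
                          check_positive = FALSE))
  }
  if (nrow(image) <= 2L * crop || ncol(image) <= 2L * crop) {
    stop(sprintf("image (%d x %d) too small for a %d-pixel border crop",
                 nrow(image), ncol(image), crop))
  }
  out <- conv2_same(image, kernel)
  if (crop > 0L) {
    out <- out[(crop + 1L):(nrow(out) - crop), (crop + 1L):(ncol(out) - crop),
               drop = FALSE]
  }
  out
}

#' Standardize patch rows to zero mean and unit standard deviation
#'
#' @param x numeric matrix whose rows are flattened patches, or a `patch_set`.
#' @return object of the same shape with each row standardized (sample
#'   standard deviation, denominator n - 1).  Idempotent.
#' @export
standardize_patches <- function(x) {
  if (inherits(x, "patch_set")) {
    x$data <- standardize_patches(x$data)
    return(x)
  }
  mu <- rowMeans(x)
  centered <- x - mu
  s <- sqrt(rowSums(centered^2) / (ncol(x) - 1L))
  if (any(s == 0)) stop("zero-variance patch cannot be standardized")
  centered / s
}

#' Extract random standardized patches from filtered images
#'
#' Draws `n_patches` square patches of side `grid_size` from the filtered
#' images, with replacement across and within images (per patch: a uniformly
#' random image, then a uniformly random top-left corner).  Each patch is
#' standardized by subtracting its mean and dividing by its standard
#' deviation; these standardized patches are the model RGC responses `d_i`
#' that drive learning.  Patches with zero variance (possible on degenerate
#' inputs) are resampled; more than 1000 consecutive failed draws is an error.
#'
#' @param images an [image_ensemble()], matrix, or list of matrices of
#'   filtered (RGC-response) images.
#' @param grid_size patch side length in pixels (paper-scale default 16; 32 is
#'   supported, as is any size that fits the images).
#' @param n_patches number of patches to draw (0 gives an empty set).
#' @param seed optional integer; when given, the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return an object of class `patch_set`: list with `data` (n_patches x
#'   grid_size^2 matrix, rows standardized, column-major flattening),
#'   `grid_size`, `sources` (data.frame: image, row, col of each top-left
#'   corner) and `seed`.
#' @export
extract_patches <- function(images, grid_size = 16L, n_patches = 1000L,
                            seed = NULL) {
  imgs <- as_image_list(images)
  g <- as.integer(grid_size)
  n_patches <- as.integer(n_patches)
  nr <- nrow(imgs[[1]]); nc <- ncol(imgs[[1]])
  if (g > nr || g > nc) stop("grid_size exceeds filtered image size")
  if (n_patches < 0L) stop("n_patches must be >= 0")
  if (n_patches == 0L) {
    return(structure(list(data = matrix(numeric(0), 0L, g * g),
                          grid_size = g,
                          sources = data.frame(image = integer(0),
                                               row = integer(0),
                                               col = integer(0)),
                          seed = seed),
                     class = "patch_set"))
  }

  draw <- function() {
    with_seed(seed, {
      data <- matrix(NA_real_, n_patches, g * g)
      src <- matrix(NA_integer_, n_patches, 3L)
      need <- seq_len(n_patches)
      consecutive_failures <- 0L
      while (length(need) > 0L) {
        im <- sample.int(length(imgs), length(need), replace = TRUE)
        r0 <- sample.int(nr - g + 1L, length(need), replace = TRUE)
        c0 <- sample.int(nc - g + 1L, length(need), replace = TRUE)
        for (k in seq_along(need)) {
          p <- imgs[[im[k]]][r0[k]:(r0[k] + g - 1L), c0[k]:(c0[k] + g - 1L)]
          v <- as.vector(p)
          s <- sd(v)
          if (is.finite(s) && s > 0) {
            data[need[k], ] <- (v - mean(v)) / s
            src[need[k], ] <- c(im[k], r0[k], c0[k])
            consecutive_failures <- 0L
          } else {
            consecutive_failures <- consecutive_failures + 1L
            if (consecutive_failures > 1000L) {
              stop("more than 1000 consecutive zero-variance patches; ",
                   "the input images appear to be degenerate")
            }
          }
        }
        need <- which(is.na(src[, 1L]))
      }
      list(data = data, src = src)
    })
  }
  res <- draw()
  structure(list(data = res$data,
                 grid_size = g,
                 sources = data.frame(image = res$src[, 1L],
                                      row = res$src[, 2L],
                                      col = res$src[, 3L]),
                 seed = seed),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set: %d patches, %d x %d grid%s>\n",
              nrow(x$data), x$grid_size, x$grid_size,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Run the full retinal front end
#'
#' Convenience wrapper: log transform, DoG filtering with border crop, and
#' random patch extraction.
#'
#' @inheritParams extract_patches
#' @inheritParams filter_and_crop
#' @param images raw luminance images (strictly positive pixels).
#' @param dog a [dog_params()] object.
#' @return a `patch_set` (see [extract_patches()]).
#' @export
retina_pipeline <- function(images, dog = dog_params(), crop = 10L,
                            grid_size = 16L, n_patches = 1000L, seed = NULL) {
  kernel <- build_dog_kernel(dog)
  filtered <- filter_and_crop(log_transform(images), kernel, crop = crop)
  extract_patches(filtered, grid_size = grid_size, n_patches = n_patches,
                  seed = seed)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded draws inside the package never perturb user
#' code.  A `NULL` seed evaluates the expression under the current RNG state.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
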