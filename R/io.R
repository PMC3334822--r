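#' Read a grayscale image from a plain-text file
#'
#' Supports ASCII portable graymap (`.pgm`, magic `P2`) and plain CSV matrices
#' (`.csv`).  PGM files may legitimately contain zero-valued pixels, which the
#' retinal log transform cannot accept; `epsilon` (default 0, i.e. off) is
#' added to every pixel to lift such images onto strictly positive values.
#'
#' @param path file path; format inferred from the extension.
#' @param epsilon non-negative offset added to all pixels (default 0).
#' @return a numeric matrix of luminance values.
#' @export
read_image <- function(path, epsilon = 0) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    pgm = read_pgm(path),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop("unsupported image format: .", ext, " (use .pgm or .csv)")
  )
  storage.mode(img) <- "double"
  dimnames(img) <- NULL
  img + epsilon
}

read_pgm <- function(path) {
  tokens <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (tokens[1] != "P2") stop("only ASCII (P2) PGM files are supported")
  vals <- as.numeric(tokens[-1])
  w <- vals[1]; h <- vals[2]  # maxval at vals[3] is ignored
  px <- vals[-(1:3)]
  if (length(px) != w * h) stop("corrupt PGM: pixel count mismatch")
  # PGM is row-major (raster scan)
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale image to a plain-text file
#'
#' @param image numeric matrix.
#' @param path destination; `.pgm` writes ASCII P2 (pixels rescaled to
#'   0..maxval integers), `.csv` writes the raw values.
#' @param maxval PGM maximum gray value (default 65535).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, maxval = 65535L) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(image, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (ext == "pgm") {
    rng <- range(image)
    scaled <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
    px <- round(scaled * maxval)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
               con)
    utils::write.table(px, con, sep = " ", row.names = FALSE,
                       col.names = FALSE)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

#' Serialize a patch set (or any matrix) with a JSON sidecar
#'
#' The matrix goes to `<path>` as headerless CSV; provenance (grid size, seed,
#' source indices, free-form parameters) goes to `<path>.json`.
#'
#' @param x a `patch_set` or numeric matrix.
#' @param path destination CSV path.
#' @param meta named list of extra metadata to store.
#' @return `path`, invisibly.
#' @export
write_patch_set <- function(x, path, meta = list()) {
  if (inherits(x, "patch_set")) {
    meta <- c(meta, list(grid_size = x$grid_size, seed = x$seed,
                         sources = x$sources))
    mat <- x$data
  } else {
    mat <- x
  }
  utils::write.table(mat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read back a serialized patch set
#'
#' @param path CSV path previously written by [write_patch_set()].
#' @return a `patch_set` (with whatever metadata the sidecar preserved).
#' @export
read_patch_set <- function(path) {
  mat <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(mat) <- NULL
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else list()
  g <- meta$grid_size %||% as.integer(sqrt(ncol(mat)))
  sources <- if (!is.null(meta$sources) && length(meta$sources)) {
    as.data.frame(meta$sources)
  } else {
    data.frame(image = integer(0), row = integer(0), col = integer(0))
  }
  structure(list(data = mat, grid_size = as.integer(g), sources = sources,
                 seed = meta$seed %||% NULL),
            class = "patch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
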