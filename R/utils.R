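#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rnorm runif sd var median rbinom aggregate setNames
#' @importFrom utils read.csv write.csv head tail
#' @importFrom tools file_ext
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so seeded helpers never
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

check_binary_mask <- function(m, name = "mask") {
  if (!all(m %in% c(0, 1))) {
    stop(sprintf("'%s' must be binary {0,1}", name), call. = FALSE)
  }
  invisible(m)
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must have identical shapes (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

round_half_up <- function(x) floor(x + 0.5)

#' Read a grayscale image from PNG or TIFF
#'
#' Multi-channel images are averaged to a single channel. Values are on the
#' `[0,1]` scale.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix.
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image extension '%s' (use png/tif/tiff)", ext),
         call. = FALSE)
  )
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE], c(1, 2), mean)
  img
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img numeric matrix in `[0,1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(clamp01(img), target = path)
  invisible(path)
}

#' Read a binary mask from a 0/255 (or 0/1) PNG
#'
#' @param path file path.
#' @return integer matrix with values in `{0,1}`.
#' @export
read_mask <- function(path) {
  m <- read_gray(path)
  (m >= 0.5) * 1L
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask binary matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  check_binary_mask(mask)
  png::writePNG(mask * 1.0, target = path)
  invisible(path)
}
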