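#' Integer raster image
#'
#' Constructs the package's basic image container: an integer-valued
#' \code{H x W x C} array with \code{C} in \{1, 3\} and pixel values in
#' \code{[0, levels - 1]}. All classical preprocessing (enhancement,
#' augmentation) operates on this type; the diffusion/network path uses
#' [to_tensor()] images instead.
#'
#' @param pixels numeric array \code{H x W} or \code{H x W x C} of integers.
#' @param levels number of intensity levels L (max value + 1); default 256.
#' @return object of class \code{raster_image}: the integer array with
#'   attributes \code{levels} and \code{channels}.
#' @export
raster_image <- function(pixels, levels = 256L) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(dim(pixels), 1L))
  }
  if (length(dim(pixels)) != 3L) {
    stop("pixels must be an H x W or H x W x C array", call. = FALSE)
  }
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L) stop("image must have H >= 1 and W >= 1", call. = FALSE)
  if (!d[3] %in% c(1L, 3L)) stop("channels must be 1 or 3", call. = FALSE)
  if (anyNA(pixels)) stop("image contains NA pixels", call. = FALSE)
  if (any(pixels != round(pixels))) stop("pixel values must be integers", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > levels - 1) {
    stop(sprintf("pixel values must lie in [0, %d]", levels - 1L), call. = FALSE)
  }
  structure(array(as.numeric(pixels), dim = d),
            levels = as.integer(levels), channels = d[3],
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image %d x %d x %d, levels %d, range [%d, %d]>\n",
              d[1], d[2], d[3], attr(x, "levels"), min(x), max(x)))
  invisible(x)
}

is_raster_image <- function(x) inherits(x, "raster_image")

img_levels <- function(img) {
  L <- attr(img, "levels")
  if (is.null(L)) 256L else as.integer(L)
}

# round-half-up; the single rounding convention wherever intensity levels
# are produced (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

clip_levels <- function(x, L) pmin(pmax(x, 0), L - 1)

#' Load a PNG or JPEG image as a raster image
#'
#' PNG files are decoded with the \pkg{png} package; JPEG files through
#' \pkg{EBImage} when available. 8-bit output with fixed RGB channel order;
#' an alpha channel, if present, is dropped.
#'
#' @param path path to an existing PNG or JPEG file.
#' @return [raster_image()] with \code{levels = 256}.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- tryCatch(png::readPNG(path),
                    error = function(e) stop(sprintf("cannot decode PNG %s: %s",
                                                     path, conditionMessage(e)), call. = FALSE))
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG decoding requires the EBImage package", call. = FALSE)
    }
    e <- EBImage::readImage(path)
    arr <- EBImage::imageData(e)
    if (length(dim(arr)) == 3L) arr <- aperm(arr, c(2L, 1L, 3L)) else arr <- t(arr)
  } else {
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE)
  }
  if (length(dim(arr)) == 3L && dim(arr)[3] == 4L) arr <- arr[, , 1:3, drop = FALSE]
  if (length(dim(arr)) == 3L && dim(arr)[3] == 2L) arr <- arr[, , 1L, drop = FALSE]
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  raster_image(round_half_up(arr * 255), levels = 256L)
}

#' Save a raster image as PNG
#'
#' @param img a [raster_image()].
#' @param path output path (".png").
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(is_raster_image(img))
  L <- img_levels(img)
  arr <- unclass(img) / (L - 1)
  if (dim(arr)[3] == 1L) arr <- arr[, , 1L]
  png::writePNG(arr, target = path)
  invisible(path)
}

#' Convert a raster image to a symmetric-range tensor image
#'
#' Maps level \code{p} to \code{2 p / (L - 1) - 1}, so the output lies in
#' \code{[-1, 1]}. The symmetric range matches the zero-mean Gaussian noise
#' injected by the diffusion forward process.
#'
#' @param img a [raster_image()].
#' @return numeric \code{H x W x C} array in \code{[-1, 1]} of class
#'   \code{tensor_image}.
#' @export
to_tensor <- function(img) {
  stopifnot(is_raster_image(img))
  L <- img_levels(img)
  structure(2 * unclass(img) / (L - 1) - 1, levels = L,
            channels = attr(img, "channels"), class = "tensor_image")
}

#' Convert a tensor image back to integer levels
#'
#' Inverse of [to_tensor()] up to quantization: values are mapped back to
#' \code{[0, L - 1]}, rounded half-up and clipped. The roundtrip
#' raster -> tensor -> raster is exact.
#'
#' @param x tensor image (array in \code{[-1, 1]}).
#' @param levels number of intensity levels of the result.
#' @return [raster_image()].
#' @export
from_tensor <- function(x, levels = NULL) {
  L <- if (!is.null(levels)) as.integer(levels) else {
    La <- attr(x, "levels"); if (is.null(La)) 256L else as.integer(La)
  }
  arr <- unclass(x)
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  raster_image(clip_levels(round_half_up((arr + 1) / 2 * (L - 1)), L), levels = L)
}

#' @export
print.tensor_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<tensor_image %d x %d x %d, range [%.3f, %.3f]>\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

# Run code under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derived seed (keeps results below 2^31).
derive_seed <- function(seed, salt) {
  (as.double(seed) * 1103515245 + sum(utf8ToInt(as.character(salt))) * 12345) %% 2147483647
}
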