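#' Histogram equalization
#'
#' Remaps intensity level k to \code{round((L-1) * CDF(k))} where CDF is the
#' empirical cumulative histogram of the input; the mapping is monotone
#' non-decreasing, and rounding is half-up. For RGB images the default policy
#' converts to luma (ITU-R BT.601 weights 0.299/0.587/0.114), equalizes the
#' luma channel and rescales the chroma proportionally, which avoids the hue
#' shifts that independent per-channel equalization produces; per-channel
#' mode is available with \code{mode = "channel"}.
#'
#' @param img a [raster_image()].
#' @param mode \code{"luma"} (default, RGB only) or \code{"channel"}.
#' @return equalized [raster_image()].
#' @export
equalize_hist <- function(img, mode = c("luma", "channel")) {
  stopifnot(is_raster_image(img))
  mode <- match.arg(mode)
  L <- img_levels(img)
  d <- dim(img)
  if (d[1] * d[2] == 0) stop("empty image", call. = FALSE)
  eq_plane <- function(plane) {
    h <- tabulate(as.integer(plane) + 1L, nbins = L)
    cdf <- cumsum(h) / sum(h)
    map <- round_half_up((L - 1) * cdf)
    array(map[as.integer(plane) + 1L], dim = dim(plane))
  }
  if (d[3] == 1L || mode == "channel") {
    out <- unclass(img)
    for (c in seq_len(d[3])) out[, , c] <- eq_plane(out[, , c, drop = FALSE])
    return(raster_image(out, levels = L))
  }
  x <- unclass(img)
  y <- round_half_up(0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3])
  y2 <- eq_plane(y)
  scale <- ifelse(y > 0, y2 / y, 0)
  out <- x
  for (c in 1:3) {
    ch <- x[, , c] * scale
    ch[y == 0] <- y2[y == 0]
    out[, , c] <- clip_levels(round_half_up(ch), L)
  }
  raster_image(out, levels = L)
}

#' Linear contrast stretching
#'
#' Affine rescaling of intensities: \code{r_min} maps to 0 and \code{r_max}
#' to \code{L - 1}, values between them linearly (then rounded half-up),
#' values outside \code{[r_min, r_max]} clipped first. When the bounds are
#' omitted they default to the image's own minimum and maximum.
#'
#' @param img a [raster_image()].
#' @param r_min,r_max input levels mapped to the output extremes;
#'   \code{r_min < r_max} required.
#' @return stretched [raster_image()].
#' @export
stretch_contrast <- function(img, r_min = NULL, r_max = NULL) {
  stopifnot(is_raster_image(img))
  L <- img_levels(img)
  x <- unclass(img)
  if (is.null(r_min)) r_min <- min(x)
  if (is.null(r_max)) r_max <- max(x)
  if (r_min >= r_max) {
    stop("r_min must be strictly less than r_max (constant image?)", call. = FALSE)
  }
  x <- pmin(pmax(x, r_min), r_max)
  out <- round_half_up((x - r_min) / (r_max - r_min) * (L - 1))
  raster_image(out, levels = L)
}

# replicate-pad a single plane by r on every side
pad_replicate <- function(plane, r) {
  h <- nrow(plane); w <- ncol(plane)
  ri <- c(rep(1L, r), seq_len(h), rep(h, r))
  ci <- c(rep(1L, r), seq_len(w), rep(w, r))
  plane[ri, ci, drop = FALSE]
}

#' Median filter
#'
#' Replaces each pixel by the median of its \code{k x k} neighborhood
#' (replicate padding at the borders); applied per channel. Suited to
#' salt-and-pepper noise.
#'
#' @param img a [raster_image()].
#' @param k odd window size, >= 1.
#' @return filtered [raster_image()].
#' @export
median_filter <- function(img, k = 3L) {
  stopifnot(is_raster_image(img))
  if (k < 1L || k %% 2L == 0L) stop("k must be odd and >= 1", call. = FALSE)
  if (k == 1L) return(img)
  L <- img_levels(img)
  r <- (k - 1L) %/% 2L
  d <- dim(img)
  out <- unclass(img)
  for (c in seq_len(d[3])) {
    p <- pad_replicate(out[, , c], r)
    neigh <- matrix(0, nrow = d[1] * d[2], ncol = k * k)
    j <- 1L
    for (dy in 0:(k - 1L)) for (dx in 0:(k - 1L)) {
      neigh[, j] <- as.vector(p[dy + seq_len(d[1]), dx + seq_len(d[2])])
      j <- j + 1L
    }
    out[, , c] <- array(apply(neigh, 1L, stats::median), dim = d[1:2])
  }
  raster_image(out, levels = L)
}

#' Gaussian convolution kernel
#'
#' Square kernel with weights proportional to
#' \code{exp(-(x^2 + y^2) / (2 sigma^2))} — the isotropic Gaussian with
#' normalization \code{1/(2 pi sigma^2)} — renormalized to sum to 1.
#'
#' @param sigma standard deviation, > 0.
#' @param radius kernel radius R (size \code{2R+1}); default \code{ceiling(3 sigma)}.
#' @param normalize renormalize the truncated kernel to sum to 1 (default TRUE).
#' @return \code{(2R+1) x (2R+1)} matrix of class \code{gaussian_kernel} with
#'   attribute \code{sigma}.
#' @export
gaussian_kernel <- function(sigma, radius = NULL, normalize = TRUE) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (is.null(radius)) radius <- ceiling(3 * sigma)
  xs <- -radius:radius
  g <- outer(xs, xs, function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)) / (2 * pi * sigma^2))
  if (normalize) g <- g / sum(g)
  structure(g, sigma = sigma, class = c("gaussian_kernel", "matrix", "array"))
}

# dense 2-D convolution of one plane with a centro-symmetric kernel,
# replicate padding; returns a float plane
convolve_plane <- function(plane, kern) {
  r <- (nrow(kern) - 1L) %/% 2L
  h <- nrow(plane); w <- ncol(plane)
  p <- pad_replicate(plane, r)
  acc <- matrix(0, h, w)
  for (dy in 0:(2L * r)) for (dx in 0:(2L * r)) {
    wgt <- kern[dy + 1L, dx + 1L]
    if (wgt != 0) acc <- acc + wgt * p[dy + seq_len(h), dx + seq_len(w)]
  }
  acc
}

#' Gaussian filter
#'
#' Convolution with a normalized [gaussian_kernel()] (replicate padding),
#' rounded back to integer levels; applied per channel.
#'
#' @param img a [raster_image()].
#' @param sigma Gaussian standard deviation, > 0.
#' @param radius optional kernel radius (default \code{ceiling(3 sigma)}).
#' @return filtered [raster_image()].
#' @export
gaussian_filter <- function(img, sigma, radius = NULL) {
  stopifnot(is_raster_image(img))
  kern <- gaussian_kernel(sigma, radius)
  L <- img_levels(img)
  d <- dim(img)
  out <- unclass(img)
  for (c in seq_len(d[3])) {
    out[, , c] <- clip_levels(round_half_up(convolve_plane(out[, , c], kern)), L)
  }
  raster_image(out, levels = L)
}
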