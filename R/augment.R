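#' Soft-labeled image
#'
#' Pairs an image with a length-K probability vector over classes, the
#' bookkeeping unit for label-mixing augmentations (CutMix, Mosaic).
#'
#' @param image a [raster_image()].
#' @param label probability vector (nonnegative, sums to 1) or a single
#'   integer class id in \code{0..K-1} combined with \code{n_classes}.
#' @param n_classes number of classes K when `label` is a class id.
#' @return object of class \code{soft_labeled}.
#' @export
soft_labeled <- function(image, label, n_classes = NULL) {
  stopifnot(is_raster_image(image))
  if (length(label) == 1L && !is.null(n_classes)) {
    v <- numeric(n_classes)
    v[label + 1L] <- 1
    label <- v
  }
  if (any(label < 0) || abs(sum(label) - 1) > 1e-9) {
    stop("label must be a probability vector summing to 1", call. = FALSE)
  }
  structure(list(image = image, label = as.numeric(label)), class = "soft_labeled")
}

#' Random rectangular binary mask
#'
#' Generates a seeded mask whose number of ones equals
#' \code{round(area_fraction * h * w)} exactly, placed uniformly at random.
#' The shape is a rectangle whose aspect ratio is drawn in \code{[0.5, 2]};
#' when the exact area admits no integer rectangle fitting the canvas the
#' mask is a rectangle minus part of its last row, so the pixel count stays
#' exact (the \code{box} attribute then records the bounding box).
#'
#' @param h,w canvas dimensions, positive.
#' @param area_fraction fraction of the canvas to mask, in (0, 1].
#' @param seed integer seed.
#' @return \code{h x w} 0/1 matrix of class \code{binary_mask} with
#'   attribute \code{box = c(top, left, height, width)}.
#' @export
make_box_mask <- function(h, w, area_fraction, seed = 0L) {
  if (h < 1L || w < 1L) stop("mask dimensions must be positive", call. = FALSE)
  if (area_fraction <= 0 || area_fraction > 1) {
    stop("area_fraction must lie in (0, 1]", call. = FALSE)
  }
  A <- round_half_up(area_fraction * h * w)
  A <- max(1L, min(A, h * w))
  with_seed(seed, {
    aspect <- stats::runif(1, 0.5, 2)   # target height/width ratio
    # feasible divisor pairs (bh, bw) with bh*bw == A
    divs <- which(A %% seq_len(min(h, A)) == 0)
    bhs <- divs[A / divs <= w]
    if (length(bhs) > 0) {
      bh <- bhs[which.min(abs(log(bhs^2 / A) - log(aspect)))]
      bw <- A %/% bh
      partial <- 0L
    } else {
      bw <- max(1L, min(w, round_half_up(sqrt(A / aspect))))
      bh <- ceiling(A / bw)
      if (bh > h) {                       # widen until the box fits vertically
        bw <- ceiling(A / h)              # <= w since A <= h*w
        bh <- ceiling(A / bw)
      }
      partial <- bh * bw - A              # < bw: dropped from the last row
    }
    top <- sample.int(h - bh + 1L, 1L)
    left <- sample.int(w - bw + 1L, 1L)
    m <- matrix(0L, h, w)
    m[top + seq_len(bh) - 1L, left + seq_len(bw) - 1L] <- 1L
    if (partial > 0L) {
      m[top + bh - 1L, left + bw - seq_len(partial)] <- 0L
    }
    structure(m, box = c(top = top, left = left, height = bh, width = bw),
              class = c("binary_mask", "matrix", "array"))
  })
}

mask_area <- function(m) sum(m == 1)

check_mask_shape <- function(img, m) {
  d <- dim(img)
  if (nrow(m) != d[1] || ncol(m) != d[2]) {
    stop("mask shape does not match image", call. = FALSE)
  }
}

#' CutOut augmentation
#'
#' Element-wise product of the image with \code{1 - M}: pixels under the
#' mask are zeroed, the rest untouched.
#'
#' @param img a [raster_image()].
#' @param m [make_box_mask()] of the same height/width.
#' @return augmented [raster_image()].
#' @export
cutout <- function(img, m) {
  stopifnot(is_raster_image(img))
  check_mask_shape(img, m)
  keep <- 1 - unclass(m)
  out <- unclass(img) * as.vector(keep)   # recycles over channels
  raster_image(out, levels = img_levels(img))
}

#' CutMix augmentation
#'
#' Composite image \code{M * A + (1 - M) * B}; the label is mixed as
#' \code{lambda * label_A + (1 - lambda) * label_B} with
#' \code{lambda = area(M) / (H W)}, so the soft label reflects each source's
#' pixel share.
#'
#' @param a,b [soft_labeled()] images of identical shape and class count.
#' @param m [make_box_mask()]; ones select pixels from `a`.
#' @return [soft_labeled()] composite.
#' @export
cutmix <- function(a, b, m) {
  stopifnot(inherits(a, "soft_labeled"), inherits(b, "soft_labeled"))
  if (!identical(dim(a$image), dim(b$image)) || length(a$label) != length(b$label)) {
    stop("cutmix inputs must have identical shapes and class counts", call. = FALSE)
  }
  check_mask_shape(a$image, m)
  sel <- as.vector(unclass(m))
  out <- unclass(a$image) * sel + unclass(b$image) * (1 - sel)
  lambda <- mask_area(m) / prod(dim(m))
  soft_labeled(raster_image(out, levels = img_levels(a$image)),
               lambda * a$label + (1 - lambda) * b$label)
}

#' Mosaic augmentation
#'
#' Stitches the four quadrants (split at a center point inside the central
#' 50% band of the canvas) from four images: quadrant q of the output copies
#' the geometrically corresponding region of input q (order: top-left,
#' top-right, bottom-left, bottom-right). The label is the area-weighted
#' mixture of the four labels.
#'
#' @param imgs list of four [soft_labeled()] images already at canvas size.
#' @param center optional \code{c(y, x)} split point; drawn uniformly in the
#'   central band when NULL.
#' @param seed seed for the random center.
#' @return [soft_labeled()] composite.
#' @export
mosaic <- function(imgs, center = NULL, seed = 0L) {
  stopifnot(length(imgs) == 4L, all(vapply(imgs, inherits, TRUE, "soft_labeled")))
  d <- dim(imgs[[1]]$image)
  for (i in 2:4) {
    if (!identical(dim(imgs[[i]]$image), d)) {
      stop("all four mosaic inputs must share the canvas size", call. = FALSE)
    }
  }
  H <- d[1]; W <- d[2]
  lo_y <- ceiling(H / 4); hi_y <- floor(3 * H / 4)
  lo_x <- ceiling(W / 4); hi_x <- floor(3 * W / 4)
  if (is.null(center)) {
    center <- with_seed(seed, c(lo_y + sample.int(hi_y - lo_y + 1L, 1L) - 1L,
                                lo_x + sample.int(hi_x - lo_x + 1L, 1L) - 1L))
  }
  cy <- center[1]; cx <- center[2]
  if (cy < lo_y || cy > hi_y || cx < lo_x || cx > hi_x) {
    stop("mosaic center must lie within the central 50% band", call. = FALSE)
  }
  rows <- list(seq_len(cy), (cy + 1L):H)
  cols <- list(seq_len(cx), (cx + 1L):W)
  out <- unclass(imgs[[1]]$image)
  areas <- numeric(4)
  q <- 1L
  K <- length(imgs[[1]]$label)
  lab <- numeric(K)
  for (ry in 1:2) for (rx in 1:2) {
    out[rows[[ry]], cols[[rx]], ] <- unclass(imgs[[q]]$image)[rows[[ry]], cols[[rx]], ]
    areas[q] <- length(rows[[ry]]) * length(cols[[rx]])
    lab <- lab + areas[q] / (H * W) * imgs[[q]]$label
    q <- q + 1L
  }
  soft_labeled(raster_image(out, levels = img_levels(imgs[[1]]$image)), lab)
}
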