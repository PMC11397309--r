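# Seeded generator of class-conditional synthetic leaf images. Each class
# is defined by lesion statistics (count ~ Poisson, radius range, RGB color
# mean/sd, shape) on an elliptical leaf over a contrasting background, plus
# global Gaussian pixel noise. The six default specs are mnemonic stand-ins
# for common jujube foliar diseases; a single difficulty scalar pulls every
# lesion color toward the leaf color, making class separability controllable.

#' Class specification for the synthetic leaf generator
#'
#' @param name class name.
#' @param lesion_lambda Poisson mean of the lesion count, >= 0.
#' @param lesion_radius length-2 positive range of lesion radii in pixels.
#' @param lesion_color,lesion_sd RGB mean (0..255) and sd of lesion color.
#' @param shape lesion shape: \code{"disc"}, \code{"ring"} or
#'   \code{"blotch"}.
#' @param leaf_color,leaf_sd RGB mean and sd of the leaf blade.
#' @param noise_sd global Gaussian pixel noise sd (levels).
#' @return list of class \code{leaf_class_spec}.
#' @export
leaf_class_spec <- function(name, lesion_lambda, lesion_radius, lesion_color,
                            lesion_sd = c(12, 12, 12),
                            shape = c("disc", "ring", "blotch"),
                            leaf_color = c(58, 110, 52), leaf_sd = c(8, 8, 8),
                            noise_sd = 4) {
  shape <- match.arg(shape)
  if (lesion_lambda < 0) stop("lesion_lambda must be >= 0", call. = FALSE)
  if (any(lesion_radius <= 0)) stop("lesion radii must be positive", call. = FALSE)
  if (any(lesion_color < 0 | lesion_color > 255)) {
    stop("lesion color means must lie in [0, 255]", call. = FALSE)
  }
  structure(list(name = name, lesion_lambda = lesion_lambda,
                 lesion_radius = sort(lesion_radius),
                 lesion_color = lesion_color, lesion_sd = lesion_sd,
                 shape = shape, leaf_color = leaf_color, leaf_sd = leaf_sd,
                 noise_sd = noise_sd),
            class = "leaf_class_spec")
}

#' Default six-class disease specifications
#'
#' Mnemonic lesion statistics: powdery mildew (pale blotches), black spot
#' (dark discs), anthracnose (brown rings), rust (many small orange discs),
#' leaf mottle (yellow blotches), stem rot (few large dark-brown blotches).
#'
#' @param difficulty scalar in \code{[0, 1]} interpolating every lesion
#'   color toward the leaf color (0 = fully distinct, 1 = invisible).
#' @return named list of six [leaf_class_spec()]s.
#' @export
default_leaf_specs <- function(difficulty = 0) {
  if (difficulty < 0 || difficulty > 1) stop("difficulty must be in [0, 1]", call. = FALSE)
  specs <- list(
    leaf_class_spec("powdery_mildew", 6, c(2.5, 4.5), c(228, 228, 214),
                    shape = "blotch"),
    leaf_class_spec("black_spot", 5, c(2, 4), c(28, 24, 22), shape = "disc"),
    leaf_class_spec("anthracnose", 4, c(3, 5), c(142, 84, 40), shape = "ring"),
    leaf_class_spec("rust", 8, c(1.2, 2.2), c(214, 126, 28), shape = "disc"),
    leaf_class_spec("leaf_mottle", 5, c(2.5, 4.5), c(222, 206, 60),
                    shape = "blotch"),
    leaf_class_spec("stem_rot", 2, c(4.5, 7), c(92, 54, 24), shape = "blotch")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (difficulty > 0) {
    specs <- lapply(specs, function(s) {
      s$lesion_color <- (1 - difficulty) * s$lesion_color +
        difficulty * s$leaf_color
      s
    })
  }
  specs
}

#' Render one synthetic leaf image
#'
#' Elliptical leaf on a contrasting soil-colored background;
#' \code{n ~ Poisson(lesion_lambda)} lesions of the spec's shape and color
#' placed uniformly inside the leaf; Gaussian pixel noise added; clipped to
#' \code{[0, 255]}. Deterministic given (spec, size, seed).
#'
#' @param spec [leaf_class_spec()].
#' @param size canvas side in pixels, >= 16.
#' @param seed integer seed.
#' @return [raster_image()] (size x size x 3).
#' @export
render_leaf <- function(spec, size = 64L, seed = 0L) {
  if (!inherits(spec, "leaf_class_spec")) stop("spec must be a leaf_class_spec", call. = FALSE)
  if (size < 16L) stop("size must be >= 16", call. = FALSE)
  with_seed(seed, {
    yy <- matrix(seq_len(size), size, size)
    xx <- t(yy)
    cy <- size / 2 + stats::rnorm(1, 0, size * 0.02)
    cx <- size / 2 + stats::rnorm(1, 0, size * 0.02)
    ry <- size * stats::runif(1, 0.33, 0.4)
    rx <- size * stats::runif(1, 0.22, 0.3)
    theta <- stats::runif(1, 0, pi)
    dy <- yy - cy; dx <- xx - cx
    u <- cos(theta) * dy + sin(theta) * dx
    v <- -sin(theta) * dy + cos(theta) * dx
    leaf_mask <- (u / ry)^2 + (v / rx)^2 <= 1
    img <- array(0, dim = c(size, size, 3))
    bg_color <- c(121, 94, 66)  # dry soil
    for (c in 1:3) {
      plane <- matrix(bg_color[c] + stats::rnorm(1, 0, 6), size, size)
      leaf_base <- spec$leaf_color[c] + stats::rnorm(1, 0, spec$leaf_sd[c])
      # mild vertical shading so the blade is not flat
      shade <- 1 + 0.08 * (yy - size / 2) / size
      plane[leaf_mask] <- (leaf_base * shade)[leaf_mask]
      img[, , c] <- plane
    }
    n_lesions <- stats::rpois(1, spec$lesion_lambda)
    inside <- which(leaf_mask)
    if (n_lesions > 0 && length(inside) > 0) {
      for (i in seq_len(n_lesions)) {
        pos <- inside[sample.int(length(inside), 1L)]
        ly <- ((pos - 1L) %% size) + 1L
        lx <- ((pos - 1L) %/% size) + 1L
        rad <- stats::runif(1, spec$lesion_radius[1], spec$lesion_radius[2])
        col <- spec$lesion_color + stats::rnorm(3, 0, spec$lesion_sd)
        dist2 <- (yy - ly)^2 + (xx - lx)^2
        lm <- switch(spec$shape,
                     disc = dist2 <= rad^2,
                     ring = dist2 <= rad^2 & dist2 >= (0.55 * rad)^2,
                     blotch = {
                       # union of overlapping discs makes an irregular patch
                       m <- dist2 <= (0.75 * rad)^2
                       for (s in 1:2) {
                         oy <- ly + stats::rnorm(1, 0, rad * 0.5)
                         ox <- lx + stats::rnorm(1, 0, rad * 0.5)
                         m <- m | ((yy - oy)^2 + (xx - ox)^2 <= (0.7 * rad)^2)
                       }
                       m
                     })
        lm <- lm & leaf_mask
        for (c in 1:3) {
          plane <- img[, , c]
          plane[lm] <- col[c]
          img[, , c] <- plane
        }
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    }
    raster_image(clip_levels(round_half_up(img), 256L), levels = 256L)
  })
}

#' Generate a synthetic labeled dataset on disk
#'
#' Renders \code{n_per_class} images per class (exact counts; a numeric
#' vector gives per-class counts, e.g. proportional to a field tally),
#' writes PNGs into \code{out_dir} and returns the manifest.
#'
#' @param specs list of [leaf_class_spec()]s (>= 2 classes).
#' @param n_per_class images per class; scalar or per-class vector.
#' @param size canvas side.
#' @param seed master seed; image i of class k gets an independent derived
#'   seed, so datasets are byte-reproducible.
#' @param out_dir output directory (created if needed); NULL keeps images
#'   in memory only.
#' @return list of class \code{synthetic_dataset}: \code{manifest},
#'   \code{images} (named by path), \code{specs}, \code{seed}.
#' @export
generate_dataset <- function(specs, n_per_class, size = 64L, seed = 0L,
                             out_dir = NULL) {
  if (length(specs) < 2L) stop("need at least 2 classes", call. = FALSE)
  K <- length(specs)
  counts <- rep_len(as.integer(n_per_class), K)
  if (any(counts < 1L)) stop("n_per_class must be >= 1", call. = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  paths <- character(0); labels <- integer(0)
  images <- list()
  for (k in seq_len(K)) {
    for (i in seq_len(counts[k])) {
      img <- render_leaf(specs[[k]], size = size,
                         seed = derive_seed(seed, sprintf("leaf-%d-%d", k, i)))
      p <- file.path(if (is.null(out_dir)) "" else out_dir,
                     sprintf("%s_%04d.png", specs[[k]]$name, i))
      if (!is.null(out_dir)) save_image(img, p)
      images[[p]] <- img
      paths <- c(paths, p)
      labels <- c(labels, k - 1L)
    }
  }
  m <- manifest(paths, labels,
                class_names = vapply(specs, `[[`, character(1), "name"))
  if (!is.null(out_dir)) {
    write_manifest(m, file.path(out_dir, "manifest.csv"))
  }
  structure(list(manifest = m, images = images, specs = specs, seed = seed),
            class = "synthetic_dataset")
}
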