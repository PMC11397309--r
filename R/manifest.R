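#' Dataset manifest
#'
#' A manifest is a data.frame with columns \code{path} (unique file paths),
#' \code{label} (integer class ids in \code{0..K-1}) and \code{split}
#' (one of \code{"train"}, \code{"val"}, \code{"test"}, \code{"unassigned"}),
#' plus a \code{class_names} attribute of length K. The on-disk form is a
#' plain CSV with header \code{path,label,split}; manifests extended with
#' soft labels carry K extra columns \code{p0..p<K-1>}.
#'
#' @param path character vector of image paths.
#' @param label integer labels in \code{0..K-1}.
#' @param split split tags; defaults to \code{"unassigned"}.
#' @param class_names character vector of the K class names.
#' @return data.frame of class \code{leaf_manifest}.
#' @export
manifest <- function(path, label, split = "unassigned", class_names = NULL) {
  path <- as.character(path)
  label <- as.integer(label)
  if (anyDuplicated(path)) stop("manifest paths must be unique", call. = FALSE)
  if (is.null(class_names)) {
    class_names <- paste0("class", seq_len(max(label) + 1L) - 1L)
  }
  K <- length(class_names)
  if (any(label < 0L | label >= K)) {
    stop(sprintf("labels must lie in 0..%d", K - 1L), call. = FALSE)
  }
  split <- rep_len(as.character(split), length(path))
  ok <- split %in% c("train", "val", "test", "unassigned")
  if (!all(ok)) stop("invalid split tag(s): ", paste(unique(split[!ok]), collapse = ", "),
                     call. = FALSE)
  out <- data.frame(path = path, label = label, split = split,
                    stringsAsFactors = FALSE)
  attr(out, "class_names") <- class_names
  class(out) <- c("leaf_manifest", "data.frame")
  out
}

#' @export
print.leaf_manifest <- function(x, ...) {
  cn <- attr(x, "class_names")
  cat(sprintf("<leaf_manifest: %d records, %d classes>\n", nrow(x), length(cn)))
  print(table(label = x$label, split = x$split))
  invisible(x)
}

#' Read / write a manifest CSV
#'
#' @param file CSV path with header \code{path,label,split} (extra soft-label
#'   columns are preserved).
#' @param class_names optional class names; default derived from labels.
#' @return [manifest()] data.frame.
#' @export
read_manifest <- function(file, class_names = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(df))) {
    stop("manifest CSV must have 'path' and 'label' columns", call. = FALSE)
  }
  if (is.null(df$split)) df$split <- "unassigned"
  m <- manifest(df$path, df$label, df$split, class_names)
  extra <- setdiff(names(df), c("path", "label", "split"))
  for (nm in extra) m[[nm]] <- df[[nm]]
  m
}

#' @rdname read_manifest
#' @param m manifest to write.
#' @export
write_manifest <- function(m, file) {
  utils::write.csv(as.data.frame(m), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Largest-remainder apportionment
#'
#' Allocates \code{n} items to fractional quotas deterministically: each bin
#' first receives the floor of its quota, remaining items go to the bins with
#' the largest fractional parts (ties broken by bin order).
#'
#' @param n total count.
#' @param fractions nonnegative weights summing to 1.
#' @return integer vector of bin sizes summing to \code{n}.
#' @export
apportion <- function(n, fractions) {
  if (any(fractions < 0)) stop("fractions must be nonnegative", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1", call. = FALSE)
  quota <- n * fractions
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a manifest into train/val/test
#'
#' Assigns every record to exactly one split by a seeded permutation. Split
#' sizes are the largest-remainder apportionment of \code{n} by the ratios
#' (e.g. n = 1000 at 70/15/15 gives 700/150/150). By default the assignment
#' is stratified by class; a reconciliation pass keeps the global sizes at
#' their exact apportionment while per-class proportions stay within one
#' record of the target.
#'
#' @param m [manifest()].
#' @param ratios length-3 nonnegative vector (train, val, test) summing to 1.
#' @param seed integer seed.
#' @param stratify stratify by class (default TRUE).
#' @return the manifest with its \code{split} column filled in.
#' @export
split_manifest <- function(m, ratios = c(0.7, 0.15, 0.15), seed = 0L,
                           stratify = TRUE) {
  if (length(ratios) != 3L || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must be 3 nonnegative fractions summing to 1", call. = FALSE)
  }
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 records to split", call. = FALSE)
  splits <- c("train", "val", "test")
  target <- apportion(n, ratios)
  assign_vec <- character(n)
  if (!stratify) {
    perm <- with_seed(seed, sample.int(n))
    assign_vec[perm] <- rep(splits, times = target)
  } else {
    labs <- m$label
    classes <- sort(unique(labs))
    counts <- matrix(0L, nrow = length(classes), ncol = 3L)
    ord_within <- vector("list", length(classes))
    for (ci in seq_along(classes)) {
      idx <- which(labs == classes[ci])
      counts[ci, ] <- apportion(length(idx), ratios)
      ord_within[[ci]] <- with_seed(derive_seed(seed, paste0("strat", ci)),
                                    sample(idx))
    }
    # reconcile per-class sums to the global largest-remainder sizes
    over <- colSums(counts) - target
    while (any(over != 0)) {
      from <- which.max(over)
      to <- which.min(over)
      # move one record of the class whose `from` quota is most overshot
      resid <- vapply(seq_along(classes), function(ci) {
        nk <- sum(counts[ci, ])
        counts[ci, from] - nk * ratios[from]
      }, numeric(1))
      cand <- which(counts[, from] > 0)
      ci <- cand[which.max(resid[cand])]
      counts[ci, from] <- counts[ci, from] - 1L
      counts[ci, to] <- counts[ci, to] + 1L
      over <- colSums(counts) - target
    }
    for (ci in seq_along(classes)) {
      assign_vec[ord_within[[ci]]] <- rep(splits, times = counts[ci, ])
    }
  }
  m$split <- assign_vec
  m
}
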