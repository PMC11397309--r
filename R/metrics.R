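#' Multiclass evaluation report
#'
#' Builds the confusion matrix (rows = true, columns = predicted), per-class
#' and macro precision/recall/F1, overall accuracy, and one-vs-rest ROC and
#' precision-recall curves from score columns. Macro averages are the
#' unweighted mean over classes; a class absent from both truth and
#' prediction has undefined precision/recall and is excluded from the macro
#' mean.
#'
#' @param y_true integer true labels in \code{0..K-1}.
#' @param y_pred integer predicted labels in \code{0..K-1}.
#' @param scores optional n x K score matrix (e.g. softmax probabilities)
#'   for the curves.
#' @param n_classes K; default inferred.
#' @param class_names optional class names.
#' @return list of class \code{metrics_report}.
#' @export
metrics_report <- function(y_true, y_pred, scores = NULL, n_classes = NULL,
                           class_names = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  K <- if (!is.null(n_classes)) as.integer(n_classes) else max(y_true, y_pred) + 1L
  if (is.null(class_names)) class_names <- paste0("class", 0:(K - 1L))
  n <- length(y_true)
  confusion <- matrix(0L, K, K, dimnames = list(true = class_names,
                                                pred = class_names))
  for (i in seq_len(n)) {
    confusion[y_true[i] + 1L, y_pred[i] + 1L] <-
      confusion[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall),
               ifelse(!is.na(precision) & !is.na(recall), 0, NA_real_))
  # a class with no truth and no prediction has undefined P and R
  absent <- (rowSums(confusion) == 0) & (colSums(confusion) == 0)
  precision[absent] <- NA_real_; recall[absent] <- NA_real_; f1[absent] <- NA_real_
  accuracy <- sum(tp) / n
  roc <- pr <- NULL
  auc <- NULL
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    roc <- vector("list", K); pr <- vector("list", K)
    auc <- rep(NA_real_, K)
    for (k in seq_len(K)) {
      truth <- as.integer(y_true == (k - 1L))
      if (length(unique(truth)) < 2L) next
      roc[[k]] <- roc_points(scores[, k], truth)
      pr[[k]] <- pr_points(scores[, k], truth)
      auc[k] <- trapezoid_auc(roc[[k]]$fpr, roc[[k]]$tpr)
    }
    names(roc) <- names(pr) <- names(auc) <- class_names
  }
  structure(list(confusion = confusion,
                 precision = precision, recall = recall, f1 = f1,
                 accuracy = accuracy,
                 macro_precision = mean(precision, na.rm = TRUE),
                 macro_recall = mean(recall, na.rm = TRUE),
                 macro_f1 = mean(f1, na.rm = TRUE),
                 roc = roc, pr = pr, auc = auc,
                 macro_auc = if (!is.null(auc)) mean(auc, na.rm = TRUE) else NULL,
                 n = n, class_names = class_names),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: n = %d, accuracy = %.4f>\n", x$n, x$accuracy))
  cat(sprintf("macro P = %.4f, R = %.4f, F1 = %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

# one-vs-rest ROC curve by descending score threshold
roc_points <- function(score, truth) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]
  tp <- cumsum(truth)
  fp <- cumsum(1 - truth)
  # collapse ties: keep the last point of each distinct score
  keep <- c(diff(score[ord]) != 0, TRUE)
  P <- sum(truth); N <- length(truth) - P
  data.frame(threshold = c(Inf, score[ord][keep]),
             fpr = c(0, fp[keep] / N),
             tpr = c(0, tp[keep] / P))
}

# one-vs-rest precision-recall curve
pr_points <- function(score, truth) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]
  tp <- cumsum(truth)
  fp <- cumsum(1 - truth)
  keep <- c(diff(score[ord]) != 0, TRUE)
  P <- sum(truth)
  data.frame(threshold = score[ord][keep],
             recall = tp[keep] / P,
             precision = tp[keep] / (tp[keep] + fp[keep]))
}

trapezoid_auc <- function(x, y) {
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' k-fold cross-validation plan
#'
#' Seeded partition of n records into k folds whose sizes differ by at most
#' one (largest-remainder apportionment of equal quotas); with
#' stratification, per-class proportions are preserved within one record.
#' Rotating the validation fold over the k folds uses every record for
#' validation exactly once.
#'
#' @param n record count.
#' @param k fold count (default 5), \code{2 <= k <= n}.
#' @param seed integer seed.
#' @param stratify_labels optional integer labels for stratified folding.
#' @return list of class \code{fold_plan} with \code{assignments}
#'   (length n fold ids in 1..k), \code{k}, \code{seed}.
#' @export
kfold_plan <- function(n, k = 5L, seed = 0L, stratify_labels = NULL) {
  if (k < 2L || n < k) stop("need n >= k >= 2", call. = FALSE)
  target <- apportion(n, rep(1 / k, k))
  assignments <- integer(n)
  if (is.null(stratify_labels)) {
    perm <- with_seed(seed, sample.int(n))
    assignments[perm] <- rep(seq_len(k), times = target)
  } else {
    labs <- as.integer(stratify_labels)
    classes <- sort(unique(labs))
    counts <- matrix(0L, nrow = length(classes), ncol = k)
    perms <- vector("list", length(classes))
    for (ci in seq_along(classes)) {
      idx <- which(labs == classes[ci])
      nk <- length(idx)
      # rotate which folds receive the remainder so extras spread out
      quota <- rep(1 / k, k)
      sizes <- apportion(nk, quota)
      rot <- (ci - 1L) %% k
      sizes <- sizes[((seq_len(k) - 1L + rot) %% k) + 1L]
      counts[ci, ] <- sizes
      perms[[ci]] <- with_seed(derive_seed(seed, paste0("fold", ci)), sample(idx))
    }
    over <- colSums(counts) - target
    while (any(over != 0)) {
      from <- which.max(over); to <- which.min(over)
      cand <- which(counts[, from] > 0)
      resid <- counts[cand, from] - rowSums(counts[cand, , drop = FALSE]) / k
      ci <- cand[which.max(resid)]
      counts[ci, from] <- counts[ci, from] - 1L
      counts[ci, to] <- counts[ci, to] + 1L
      over <- colSums(counts) - target
    }
    for (ci in seq_along(classes)) {
      assignments[perms[[ci]]] <- rep(seq_len(k), times = counts[ci, ])
    }
  }
  structure(list(assignments = assignments, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Exhaustive grid search over configurations
#'
#' Evaluates every cell of the cartesian grid by the mean of a
#' user-supplied validation metric across folds; ties break
#' deterministically by lexicographic cell order (first axis fastest).
#'
#' @param grid named list of parameter vectors.
#' @param eval_fn function(cell, fold) returning a scalar metric (higher is
#'   better); `cell` is a named list.
#' @param folds number of folds to average over, or a [kfold_plan()].
#' @param budget optional cap on the number of cells evaluated (in
#'   lexicographic order).
#' @return list(best = named list, table = data.frame of cells and mean
#'   metric).
#' @export
grid_search <- function(grid, eval_fn, folds = 5L, budget = Inf) {
  if (length(grid) == 0L || any(lengths(grid) == 0L)) {
    stop("grid must be non-empty", call. = FALSE)
  }
  cells <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ncells <- min(nrow(cells), budget)
  k <- if (inherits(folds, "fold_plan")) folds$k else as.integer(folds)
  metric <- rep(NA_real_, nrow(cells))
  for (i in seq_len(ncells)) {
    cell <- as.list(cells[i, , drop = FALSE])
    vals <- vapply(seq_len(k), function(f) eval_fn(cell, f), numeric(1))
    metric[i] <- mean(vals)
  }
  best_i <- which.max(metric)  # which.max returns the first (lexicographic) tie
  out <- cbind(cells, mean_metric = metric)
  list(best = as.list(cells[best_i, , drop = FALSE]), table = out)
}
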