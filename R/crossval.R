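#' Weighted multiclass precision, recall and F1
#'
#' Per-class precision, recall and F1 are averaged with weights proportional
#' to the true support of each class. Classes with no predicted positives
#' get precision 0; classes with no true members contribute weight 0.
#'
#' @param truth True labels (factor or character).
#' @param pred Predicted labels.
#' @param levels Class levels; defaults to the union of observed labels in
#'   canonical order when applicable.
#' @return Named numeric vector with \code{precision}, \code{recall},
#'   \code{f1}, all in [0, 1].
#' @export
weighted_metrics <- function(truth, pred, levels = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  if (is.null(levels)) levels <- .binn_levels(c(truth, pred))
  tf <- factor(truth, levels = levels)
  pf <- factor(pred, levels = levels)
  tab <- table(tf, pf)
  support <- rowSums(tab)
  tp <- diag(tab)
  prec_c <- ifelse(colSums(tab) > 0, tp / colSums(tab), 0)
  rec_c <- ifelse(support > 0, tp / support, 0)
  f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  w <- support / sum(support)
  c(precision = sum(w * prec_c), recall = sum(w * rec_c), f1 = sum(w * f1_c))
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of \code{k} folds, preserving the class
#' proportions: within each class, shuffled samples are dealt to folds in
#' turn, so fold class counts differ by at most one sample.
#'
#' @param y Class labels.
#' @param k Number of folds.
#' @param seed Integer seed for the within-class shuffle.
#' @return Integer vector of fold ids in \code{1..k}.
#' @export
stratified_folds <- function(y, k = 5, seed = 1L) {
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < k)) {
    stop("Class(es) with fewer than k = ", k, " samples: ",
         paste(names(counts)[counts < k], collapse = ", "),
         "; use a smaller k", call. = FALSE)
  }
  folds <- integer(length(y))
  .with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated evaluation of the masked network
#'
#' Runs stratified k-fold cross-validation: for each fold the model is
#' trained on the remaining folds (with preprocessing statistics fitted on
#' the training portion only) and evaluated on the held-out fold. Weighted
#' precision, recall and F1 are reported per fold and pooled over all
#' held-out predictions.
#'
#' @param x Samples-by-genes expression matrix (raw TPM-like scale).
#' @param y Class labels.
#' @param masks A \code{mask_stack}.
#' @param k_folds Number of folds (default 5).
#' @param seed Seed controlling fold assignment and each fold's training.
#' @param refit Also fit a final model on the complete dataset with the same
#'   configuration (default FALSE); returned as \code{$final_model}.
#' @param ... Passed to [binn()] (epochs, batch_size, lr, activation, ...).
#' @return An object of class \code{binn_cv}: per-fold metrics, pooled
#'   metrics, fold assignments, per-fold loss curves, the seed, and
#'   optionally the final refit model.
#' @export
binn_cv <- function(x, y, masks, k_folds = 5, seed = 1L, refit = FALSE, ...) {
  x <- as.matrix(x)
  y <- as.character(y)
  folds <- stratified_folds(y, k = k_folds, seed = seed)
  levs <- .binn_levels(y)
  pred_all <- character(length(y))
  fold_metrics <- matrix(NA_real_, k_folds, 3,
                         dimnames = list(NULL, c("precision", "recall", "f1")))
  losses <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    fit <- binn(x[tr, , drop = FALSE], y[tr], masks,
                seed = seed + f, class_levels = levs, ...)
    ph <- as.character(predict(fit, x[!tr, , drop = FALSE]))
    pred_all[!tr] <- ph
    fold_metrics[f, ] <- weighted_metrics(y[!tr], ph, levels = levs)
    losses[[f]] <- fit$loss
  }
  out <- list(metrics = weighted_metrics(y, pred_all, levels = levs),
              fold_metrics = fold_metrics, folds = folds,
              predictions = factor(pred_all, levels = levs),
              losses = losses, seed = seed, k_folds = k_folds,
              classes = levs)
  if (isTRUE(refit)) {
    out$final_model <- binn(x, y, masks, seed = seed, class_levels = levs, ...)
  }
  structure(out, class = "binn_cv")
}

#' @export
print.binn_cv <- function(x, ...) {
  cat(sprintf("Stratified %d-fold cross-validation (%d samples, %d classes)\n",
              x$k_folds, length(x$folds), length(x$classes)))
  cat(sprintf("  pooled held-out: precision %.4f, recall %.4f, F1 %.4f\n",
              x$metrics["precision"], x$metrics["recall"], x$metrics["f1"]))
  cat(sprintf("  per-fold F1: %s\n",
              paste(sprintf("%.3f", x$fold_metrics[, "f1"]), collapse = ", ")))
  invisible(x)
}
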