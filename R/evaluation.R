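# Classification metrics, confusion matrices, stratified repeated
# cross-validation and run-level dispersion.

#' Confusion matrix
#'
#' Counts of (true class, predicted class) pairs over the union of
#' observed classes; rows are truth, columns are predictions.
#'
#' @param truth,predicted Label vectors of equal (positive) length.
#' @return An integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) == 0L || length(predicted) == 0L) {
    stop("'truth' and 'predicted' must be non-empty", call. = FALSE)
  }
  if (length(truth) != length(predicted)) {
    stop("'truth' and 'predicted' must have the same length", call. = FALSE)
  }
  if (is.factor(truth) || is.factor(predicted)) {
    classes <- sort(unique(c(levels(truth), levels(predicted),
                             as.character(truth), as.character(predicted))))
    truth <- as.character(truth)
    predicted <- as.character(predicted)
  } else {
    classes <- sort(unique(c(truth, predicted)))
  }
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  structure(unclass(matrix(as.integer(cm), nrow = length(classes),
                           dimnames = list(truth = as.character(classes),
                                           predicted = as.character(classes)))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows = truth, columns = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class and macro classification metrics
#'
#' One-vs-rest precision, recall and F1 per class with
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)` and F1 their harmonic
#' mean; overall accuracy is the trace of the confusion matrix over the
#' total. Any 0/0 is defined as 0 so macro averages stay defined even for
#' classes absent from a test fold.
#'
#' @param cm A [confusion_matrix()].
#' @return A `metrics_report`: list with `per_class` (data frame of class,
#'   precision, recall, f1, support), `accuracy`, and macro-averaged
#'   `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0L) {
    stop("empty confusion matrix", call. = FALSE)
  }
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  per_class <- data.frame(
    class = rownames(cm), precision = unname(precision),
    recall = unname(recall), f1 = unname(f1),
    support = unname(rowSums(cm)), stringsAsFactors = FALSE)
  structure(
    list(per_class = per_class,
         accuracy = sum(tp) / total,
         macro_precision = mean(precision),
         macro_recall = mean(recall),
         macro_f1 = mean(f1),
         confusion = cm),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy: %.4f  macro P/R/F1: %.4f / %.4f / %.4f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$per_class, row.names = FALSE, digits = 4)
  if (!is.null(x$run_accuracies)) {
    cat(sprintf("runs: %d, mean accuracy %.4f, std %.4f\n",
                length(x$run_accuracies), mean(x$run_accuracies),
                run_std(x$run_accuracies)))
  }
  invisible(x)
}

#' Run-level standard deviation of accuracies
#'
#' Population standard deviation
#' \eqn{\sqrt{\frac{1}{n} \sum_i (ACC_i - \bar{ACC})^2}} over per-run
#' accuracies; 0 for a single run and exactly 0 iff all runs agree.
#'
#' @param accuracies Numeric vector of per-run accuracies (length >= 1).
#' @return Non-negative scalar.
#' @export
run_std <- function(accuracies) {
  if (length(accuracies) == 0L) {
    stop("'accuracies' must be non-empty", call. = FALSE)
  }
  sqrt(mean((accuracies - mean(accuracies))^2))
}

# Stratified (or plain) fold assignment: within each class, shuffled
# indices are dealt round-robin, continuing the deal across classes so
# global fold sizes differ by at most one. Uses the current RNG state.
make_fold_ids <- function(labels, k_folds, stratify = TRUE) {
  n <- length(labels)
  folds <- integer(n)
  if (!stratify) {
    folds <- sample(rep_len(seq_len(k_folds), n))
    return(folds)
  }
  offset <- 0L
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- if (length(idx) > 1L) sample(idx) else idx
    folds[idx] <- ((offset + seq_along(idx) - 1L) %% k_folds) + 1L
    offset <- offset + length(idx)
  }
  folds
}

#' Repeated stratified cross-validation
#'
#' Runs `n_repeats` rounds of `k_folds`-fold cross-validation of a
#' classifier on a chosen feature subset. Each repeat's pooled accuracy is
#' recorded as one run; the confusion matrix pooled over all folds and
#' repeats feeds [class_metrics()]. Folds are stratified by class (unless
#' disabled) and fully determined by `seed`.
#'
#' @param fm A discrete [feature_matrix()].
#' @param features Feature ids (or a `selection_trace`) to use; `NULL`
#'   means all features.
#' @param classifier A classifier object (see [classifier_1nn()]).
#' @param k_folds Number of folds (2..n_samples).
#' @param n_repeats Number of repeats.
#' @param seed Integer seed for fold assignment.
#' @param stratify Stratify folds by class (default `TRUE`).
#' @return A `metrics_report` with additional components
#'   `run_accuracies` (per-repeat accuracy), `mean_accuracy` and
#'   `std_accuracy` (population standard deviation across runs).
#' @export
cross_validate <- function(fm, features = NULL,
                           classifier = classifier_1nn(),
                           k_folds = 10, n_repeats = 10, seed = 1,
                           stratify = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  check_discrete(fm, "cross_validate()")
  n <- nrow(fm$values)
  if (k_folds < 2L || k_folds > n) {
    stop("'k_folds' must be between 2 and the number of samples",
         call. = FALSE)
  }
  if (is.null(features)) {
    features <- fm$feature_ids
  } else if (inherits(features, "selection_trace")) {
    features <- features$feature_id
  }
  feats <- match(as.character(features), fm$feature_ids)
  if (anyNA(feats)) {
    stop("unknown feature id(s): ",
         paste(features[is.na(feats)], collapse = ", "), call. = FALSE)
  }
  labels <- fm$labels
  cols <- fm$values[, feats, drop = FALSE]
  run_acc <- numeric(n_repeats)
  truth_all <- c()
  pred_all <- c()
  with_local_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      folds <- make_fold_ids(labels, k_folds, stratify)
      correct <- 0L
      for (fold in seq_len(k_folds)) {
        test <- folds == fold
        train_y <- labels[!test]
        if (length(unique(train_y)) < length(unique(labels))) {
          warning("a class is absent from a training fold; consider fewer ",
                  "folds or stratification")
        }
        model <- classifier$fit(cols[!test, , drop = FALSE], train_y)
        pred <- classifier$predict(model, cols[test, , drop = FALSE])
        correct <- correct + sum(pred == labels[test])
        truth_all <- c(truth_all, labels[test])
        pred_all <- c(pred_all, pred)
      }
      run_acc[rep_i] <- correct / n
    }
  })
  report <- class_metrics(confusion_matrix(truth_all, pred_all))
  report$run_accuracies <- run_acc
  report$mean_accuracy <- mean(run_acc)
  report$std_accuracy <- run_std(run_acc)
  report
}
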