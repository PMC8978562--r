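# Bundled classifiers for the IFS / cross-validation machinery. All
# classifiers share a minimal fit/predict contract so that external
# learners (gradient boosting, SVM, ...) can be plugged in without being
# package dependencies.

#' Define a classifier for cross-validation
#'
#' A classifier is a name plus two functions: `fit(x, y)` consuming a
#' numeric matrix of discrete feature codes and a label vector and
#' returning an arbitrary model object, and `predict(model, x)` returning
#' one predicted label per row of `x`. Any learner honouring this
#' contract (e.g. a gradient-boosting or SVM wrapper) can be passed to
#' [ifs_curve()] and [cross_validate()].
#'
#' @param name Short display name.
#' @param fit Function `(x, y) -> model`.
#' @param predict Function `(model, x) -> labels`.
#' @return A `cria_classifier` object.
#' @export
new_classifier <- function(name, fit, predict) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict),
            class = "cria_classifier")
}

#' @export
print.cria_classifier <- function(x, ...) {
  cat("classifier:", x$name, "\n")
  invisible(x)
}

# Map character predictions back to the type of the training labels.
restore_label_type <- function(pred, y) {
  pred <- as.character(pred)
  if (is.numeric(y)) as.numeric(pred) else pred
}

#' One-nearest-neighbour classifier (Hamming distance)
#'
#' Instance-based learner for discrete feature codes: each test sample is
#' assigned the label of the training sample with the fewest disagreeing
#' feature values (the overlap metric used by IB1 for nominal
#' attributes). Distance ties are broken towards the earliest training
#' sample, making predictions deterministic.
#'
#' @return A `cria_classifier`.
#' @export
classifier_1nn <- function() {
  new_classifier(
    "1nn",
    fit = function(x, y) list(x = x, y = y),
    predict = function(model, x) {
      train <- model$x
      vapply(seq_len(nrow(x)), function(i) {
        d <- rowSums(train != matrix(x[i, ], nrow(train), ncol(train),
                                     byrow = TRUE))
        model$y[which.min(d)]
      }, model$y[1])
    })
}

#' Categorical naive Bayes classifier
#'
#' Wraps [e1071::naiveBayes()] over factor-coded features with Laplace
#' smoothing 1. Feature levels are those observed in the training fold;
#' unseen test codes fall back to the class prior for that attribute.
#'
#' @return A `cria_classifier`.
#' @export
classifier_naive_bayes <- function() {
  new_classifier(
    "naive_bayes",
    fit = function(x, y) {
      lv <- lapply(seq_len(ncol(x)), function(j) sort(unique(x[, j])))
      df <- as.data.frame(lapply(seq_len(ncol(x)), function(j) {
        factor(x[, j], levels = lv[[j]])
      }))
      names(df) <- paste0("v", seq_len(ncol(x)))
      list(model = e1071::naiveBayes(x = df, y = factor(y), laplace = 1),
           levels = lv, y = y)
    },
    predict = function(model, x) {
      df <- as.data.frame(lapply(seq_len(ncol(x)), function(j) {
        factor(x[, j], levels = model$levels[[j]])
      }))
      names(df) <- paste0("v", seq_len(ncol(x)))
      restore_label_type(stats::predict(model$model, df), model$y)
    })
}

#' Decision-tree classifier
#'
#' Wraps [rpart::rpart()] with its default control, treating the integer
#' feature codes as ordered values (natural for copy-number calls and
#' MDLP bin indices).
#'
#' @return A `cria_classifier`.
#' @export
classifier_decision_tree <- function() {
  new_classifier(
    "decision_tree",
    fit = function(x, y) {
      df <- as.data.frame(x)
      names(df) <- paste0("v", seq_len(ncol(x)))
      df$.class <- factor(y)
      list(model = rpart::rpart(.class ~ ., data = df, method = "class"),
           y = y)
    },
    predict = function(model, x) {
      df <- as.data.frame(x)
      names(df) <- paste0("v", seq_len(ncol(x)))
      restore_label_type(
        stats::predict(model$model, df, type = "class"), model$y)
    })
}

#' Majority-class baseline classifier
#'
#' Always predicts the most frequent training label (earliest-observed
#' label on ties). Useful as a floor for IFS curves.
#'
#' @return A `cria_classifier`.
#' @export
classifier_majority <- function() {
  new_classifier(
    "majority",
    fit = function(x, y) {
      lv <- unique(y)
      lv[which.max(tabulate(match(y, lv)))]
    },
    predict = function(model, x) rep(model, nrow(x)))
}

# Resolve a classifier by name (for the command line).
resolve_classifier <- function(name) {
  switch(name,
    `1nn` = classifier_1nn(),
    naive_bayes = classifier_naive_bayes(),
    decision_tree = classifier_decision_tree(),
    majority = classifier_majority(),
    stop("unknown classifier '", name,
         "'; must be one of: 1nn, naive_bayes, decision_tree, majority",
         call. = FALSE))
}
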