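# The central container: an n_samples x n_features matrix with unique
# feature ids and a categorical class label per sample.

#' Construct a feature matrix
#'
#' Bundles an `n_samples x n_features` value matrix, unique feature
#' identifiers and a per-sample class label into a single object used by
#' every downstream stage. Values may be continuous (to be discretized with
#' [fit_mdlp()]) or already-discrete integer codes such as GISTIC
#' copy-number calls in \{-2, -1, 0, 1, 2\}.
#'
#' @param values Numeric matrix, samples as rows, features as columns.
#'   No missing values are allowed.
#' @param labels Class label per sample (vector of length `nrow(values)`).
#' @param feature_ids Character vector of unique feature identifiers;
#'   defaults to `colnames(values)` or `f1, f2, ...`.
#' @return An object of class `feature_matrix` with components `values`,
#'   `feature_ids` and `labels`.
#' @examples
#' fm <- feature_matrix(matrix(c(0, 1, 0, 1, 1, 1, 0, 0), nrow = 4),
#'                      labels = c("a", "a", "b", "b"))
#' fm
#' @export
feature_matrix <- function(values, labels, feature_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("'values' must have at least one sample and one feature", call. = FALSE)
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)
    stop("missing values in 'values' at [row, column]: ",
         paste(sprintf("[%d, %d]", bad[, 1], bad[, 2])[seq_len(min(5, nrow(bad)))],
               collapse = ", "),
         if (nrow(bad) > 5) sprintf(" and %d more", nrow(bad) - 5L) else "",
         "; impute or drop them before constructing a feature_matrix",
         call. = FALSE)
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
  }
  if (is.null(feature_ids)) {
    feature_ids <- paste0("f", seq_len(ncol(values)))
  }
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != ncol(values)) {
    stop("'feature_ids' must have one entry per column of 'values'",
         call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) {
    dup <- unique(feature_ids[duplicated(feature_ids)])
    stop("duplicate feature ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (length(labels) != nrow(values)) {
    stop("'labels' must have one entry per sample (row)", call. = FALSE)
  }
  if (anyNA(labels)) {
    stop("'labels' contains missing values", call. = FALSE)
  }
  colnames(values) <- feature_ids
  structure(
    list(values = values, feature_ids = feature_ids, labels = labels),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features, %d classes%s\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$labels)),
              if (is_discrete(x)) " (discrete)" else ""))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Test whether all feature values are integer codes
#'
#' @param fm A [feature_matrix()].
#' @return `TRUE` if every value is a whole number (so the matrix can be
#'   consumed directly by the information measures), else `FALSE`.
#' @export
is_discrete <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  all(fm$values == round(fm$values))
}

# Column of a feature matrix by id or index, as a plain vector.
feature_column <- function(fm, feature) {
  if (is.character(feature)) {
    idx <- match(feature, fm$feature_ids)
    if (is.na(idx)) {
      stop("unknown feature id: ", feature, call. = FALSE)
    }
  } else {
    idx <- as.integer(feature)
    if (idx < 1L || idx > ncol(fm$values)) {
      stop("feature index out of range: ", feature, call. = FALSE)
    }
  }
  fm$values[, idx]
}

check_discrete <- function(fm, what = "this operation") {
  if (!is_discrete(fm)) {
    stop(what, " requires a discrete feature matrix; run fit_mdlp()/",
         "apply_discretization() first", call. = FALSE)
  }
  invisible(fm)
}

check_selection_ready <- function(fm) {
  if (length(unique(fm$labels)) < 2L) {
    stop("labels must contain at least two classes", call. = FALSE)
  }
  invisible(fm)
}

# Evaluate code with a private, restorable RNG state.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
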