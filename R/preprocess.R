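# Preprocessing: rescaling of copy-number calls and MDLP discretization
# of continuous features.

#' Rescale copy-number values to \[-1, 1\]
#'
#' Divides every value by the maximum absolute value in the matrix, so
#' GISTIC-coded calls \{-2, -1, 0, 1, 2\} become \{-1, -0.5, 0, 0.5, 1\}.
#' The rescale is affine, so entropy-based measures are unaffected; it
#' matters only for classifiers that consume raw values. An all-zero
#' matrix is returned unchanged with a warning.
#'
#' @param fm A [feature_matrix()] (or plain numeric matrix).
#' @return The rescaled object of the same type.
#' @export
cnv_rescale <- function(fm) {
  vals <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  max_abs <- max(abs(vals))
  if (max_abs == 0) {
    warning("all values are zero; returning the matrix unchanged")
    return(fm)
  }
  vals <- vals / max_abs
  if (inherits(fm, "feature_matrix")) {
    fm$values <- vals
    fm
  } else {
    vals
  }
}

# Entropy (bits) of a label vector given as dense codes, from counts.
entropy_from_counts <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  p <- counts / n
  -sum(p * log2(p))
}

# Recursive Fayyad-Irani MDLP split of the index range [lo, hi] of
# x_sorted / y_sorted (sorted by x). Appends accepted cut values to `acc`.
mdlp_split <- function(x_sorted, y_sorted, lo, hi, acc) {
  n <- hi - lo + 1L
  if (n < 2L) {
    return(acc)
  }
  x <- x_sorted[lo:hi]
  y <- y_sorted[lo:hi]
  k <- length(unique(y))
  if (k < 2L) {
    return(acc)
  }
  ent_s <- entropy_from_counts(tabulate(match(y, unique(y))))

  # Candidate cuts: midpoints between consecutive distinct x values whose
  # adjacent class composition differs (boundary points).
  distinct <- which(diff(x) > 0)
  if (length(distinct) == 0L) {
    return(acc)
  }
  best_gain <- -Inf
  best <- NULL
  for (i in distinct) {
    # class sets on the two sides of the candidate must differ at the boundary
    left_classes <- unique(y[x == x[i]])
    right_classes <- unique(y[x == x[i + 1L]])
    if (length(left_classes) == 1L && length(right_classes) == 1L &&
        left_classes == right_classes) {
      next
    }
    n1 <- i
    n2 <- n - i
    y1 <- y[seq_len(i)]
    y2 <- y[(i + 1L):n]
    e1 <- entropy_from_counts(tabulate(match(y1, unique(y1))))
    e2 <- entropy_from_counts(tabulate(match(y2, unique(y2))))
    gain <- ent_s - (n1 / n) * e1 - (n2 / n) * e2
    if (gain > best_gain + 1e-12) {
      best_gain <- gain
      best <- list(i = i, e1 = e1, e2 = e2,
                   k1 = length(unique(y1)), k2 = length(unique(y2)))
    }
    # ties broken by the smaller cut value = earlier index, so keep first
  }
  if (is.null(best)) {
    return(acc)
  }
  # MDLP acceptance test
  delta <- log2(3^k - 2) -
    (k * ent_s - best$k1 * best$e1 - best$k2 * best$e2)
  threshold <- (log2(n - 1) + delta) / n
  if (best_gain <= threshold) {
    return(acc)
  }
  cut <- (x[best$i] + x[best$i + 1L]) / 2
  acc <- c(acc, cut)
  acc <- mdlp_split(x_sorted, y_sorted, lo, lo + best$i - 1L, acc)
  mdlp_split(x_sorted, y_sorted, lo + best$i, hi, acc)
}

#' MDLP cut points for one continuous feature
#'
#' Recursive entropy-based binary splitting (Fayyad & Irani). Candidate
#' thresholds are midpoints between consecutive distinct values at class
#' boundaries; at each level the split maximizing the class-information
#' gain is kept only if the gain exceeds the minimum-description-length
#' acceptance threshold
#' \deqn{Gain > [\log_2(N-1) + \log_2(3^k - 2) - (k H(S) - k_1 H(S_1) - k_2 H(S_2))] / N}
#' where \eqn{k, k_1, k_2} count the classes present in the node and its
#' two children. Ties in gain are broken towards the smaller cut value.
#'
#' @param x Numeric vector (one feature column).
#' @param labels Class labels of the same length; must not be constant
#'   when `x` is non-constant (a constant `x` simply yields no cuts).
#' @return Sorted numeric vector of accepted cut points (possibly empty).
#' @examples
#' mdlp_cuts(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)) # one cut in (3, 10)
#' @export
mdlp_cuts <- function(x, labels) {
  if (length(x) != length(labels)) {
    stop("'x' and 'labels' must have the same length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(labels)) {
    stop("missing values are not supported", call. = FALSE)
  }
  ord <- order(x)
  sort(mdlp_split(x[ord], labels[ord], 1L, length(x), numeric(0)))
}

#' Fit an MDLP discretization model for every feature
#'
#' Runs [mdlp_cuts()] on every column of a feature matrix against its
#' class labels, producing a model that [apply_discretization()] can use.
#' Columns that are already discrete can be kept as-is via
#' `skip_discrete = TRUE` (an identity entry with no cuts).
#'
#' @param fm A [feature_matrix()].
#' @param skip_discrete If `TRUE` (default), integer-valued columns get an
#'   identity mapping instead of cuts.
#' @return A `discretization_model`: a named list with, per feature, either
#'   a numeric vector of strictly increasing cut points or the string
#'   `"identity"`.
#' @export
fit_mdlp <- function(fm, skip_discrete = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  check_selection_ready(fm)
  cuts <- lapply(seq_len(ncol(fm$values)), function(j) {
    col <- fm$values[, j]
    if (skip_discrete && all(col == round(col))) {
      return("identity")
    }
    mdlp_cuts(col, fm$labels)
  })
  names(cuts) <- fm$feature_ids
  structure(cuts, class = "discretization_model")
}

#' Apply a discretization model
#'
#' Maps every value to its bin index: the number of cut points lying at or
#' below the value (so an empty cut list collapses a feature to the single
#' bin 0). Identity entries pass values through unchanged.
#'
#' @param fm A [feature_matrix()].
#' @param model A `discretization_model` from [fit_mdlp()] covering every
#'   feature id in `fm`.
#' @return A discrete [feature_matrix()] of bin indices.
#' @export
apply_discretization <- function(fm, model) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(model, "discretization_model"))
  missing_ids <- setdiff(fm$feature_ids, names(model))
  if (length(missing_ids) > 0L) {
    stop("discretization model has no entry for feature(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  vals <- fm$values
  for (j in seq_len(ncol(vals))) {
    entry <- model[[fm$feature_ids[j]]]
    if (identical(entry, "identity")) {
      next
    }
    vals[, j] <- findInterval(vals[, j], entry)
  }
  feature_matrix(vals, labels = fm$labels, feature_ids = fm$feature_ids)
}

#' Discretize a feature matrix with MDLP in one step
#'
#' Convenience wrapper: [fit_mdlp()] followed by [apply_discretization()].
#'
#' @inheritParams fit_mdlp
#' @return A discrete [feature_matrix()].
#' @export
mdlp_discretize <- function(fm, skip_discrete = TRUE) {
  apply_discretization(fm, fit_mdlp(fm, skip_discrete = skip_discrete))
}
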