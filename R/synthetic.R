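# Seeded generator of discrete fixtures with known relevance, redundancy
# and interaction structure — the ground truth every selection criterion
# is meant to detect.

#' Specify a synthetic discrete dataset
#'
#' Describes a dataset with four kinds of feature columns:
#' \describe{
#'   \item{main}{the class label passed through a symmetric category-flip
#'     channel (marginally informative);}
#'   \item{redundant}{copies of designated main features, optionally passed
#'     through their own flip channel (informative but redundant);}
#'   \item{interaction pair}{for binary labels, a uniform random bit `u`
#'     paired with `u XOR label`: each member is marginally independent of
#'     the label while the pair jointly determines it;}
#'   \item{noise}{uniform draws independent of everything.}
#' }
#' The symmetric flip channel replaces a value, with the stated
#' probability, by a uniformly chosen *different* category, so the
#' marginal information content of each column is analytically known.
#'
#' @param n_samples Number of samples.
#' @param n_classes Number of classes (labels drawn uniformly).
#' @param n_main Number of main-effect features.
#' @param n_redundant Number of redundant copies (sources cycle through
#'   the main features; requires `n_main >= 1` when positive).
#' @param n_interaction_pairs Number of XOR interaction pairs (binary
#'   labels only).
#' @param n_noise Number of pure-noise features.
#' @param label_flip_rate Flip probability of the main-feature channel,
#'   in \[0, 1).
#' @param feature_noise_rate Flip probability applied to redundant copies
#'   and interaction-pair members; the default 0 makes redundant features
#'   exact duplicates of their sources.
#' @param seed Integer seed; identical specs produce identical datasets.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_samples = 1000, n_classes = 2, n_main = 5,
                           n_redundant = 5, n_interaction_pairs = 0,
                           n_noise = 40, label_flip_rate = 0.05,
                           feature_noise_rate = 0, seed = 1) {
  counts <- c(n_main = n_main, n_redundant = n_redundant,
              n_interaction_pairs = n_interaction_pairs, n_noise = n_noise)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("feature counts must be non-negative whole numbers", call. = FALSE)
  }
  total <- n_main + n_redundant + 2 * n_interaction_pairs + n_noise
  if (total < 1) {
    stop("the spec must describe at least one feature", call. = FALSE)
  }
  if (n_redundant > 0 && n_main < 1) {
    stop("redundant features need at least one main feature as source",
         call. = FALSE)
  }
  if (n_interaction_pairs > 0 && n_classes != 2) {
    stop("interaction pairs use an XOR construction and require exactly ",
         "two classes", call. = FALSE)
  }
  if (label_flip_rate < 0 || label_flip_rate >= 1 ||
      feature_noise_rate < 0 || feature_noise_rate >= 1) {
    stop("flip rates must lie in [0, 1)", call. = FALSE)
  }
  if (n_samples < 1 || n_classes < 2) {
    stop("need at least one sample and two classes", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes),
                 n_main = as.integer(n_main),
                 n_redundant = as.integer(n_redundant),
                 n_interaction_pairs = as.integer(n_interaction_pairs),
                 n_noise = as.integer(n_noise),
                 label_flip_rate = label_flip_rate,
                 feature_noise_rate = feature_noise_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Symmetric category-flip channel over the alphabet 0..(k-1).
flip_channel <- function(x, rate, k) {
  if (rate <= 0 || k < 2L) {
    return(x)
  }
  n <- length(x)
  hit <- stats::runif(n) < rate
  if (any(hit)) {
    # shift by 1..(k-1) modulo k: lands on a uniformly chosen other category
    shift <- sample.int(k - 1L, sum(hit), replace = TRUE)
    x[hit] <- (x[hit] + shift) %% k
  }
  x
}

#' Generate a synthetic discrete dataset
#'
#' Realizes a [synthetic_spec()] as a discrete [feature_matrix()] plus a
#' role map recording each column's ground-truth role and source. All
#' randomness derives from the spec's seed, so identical specs yield
#' byte-identical datasets.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `matrix` (the [feature_matrix()]) and `roles`
#'   (data frame with columns `feature_id`, `role` in
#'   main/redundant/interaction/noise, and `source` — the id of the copied
#'   main feature, the paired partner, or `NA`).
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_samples
    k <- spec$n_classes
    labels <- sample.int(k, n, replace = TRUE) - 1L

    cols <- list()
    ids <- character(0)
    roles <- character(0)
    sources <- character(0)

    for (i in seq_len(spec$n_main)) {
      cols[[length(cols) + 1L]] <- flip_channel(labels, spec$label_flip_rate, k)
      ids <- c(ids, sprintf("main_%02d", i))
      roles <- c(roles, "main")
      sources <- c(sources, NA_character_)
    }
    for (i in seq_len(spec$n_redundant)) {
      src <- ((i - 1L) %% spec$n_main) + 1L
      cols[[length(cols) + 1L]] <-
        flip_channel(cols[[src]], spec$feature_noise_rate, k)
      ids <- c(ids, sprintf("red_%02d", i))
      roles <- c(roles, "redundant")
      sources <- c(sources, sprintf("main_%02d", src))
    }
    for (i in seq_len(spec$n_interaction_pairs)) {
      u <- sample.int(2L, n, replace = TRUE) - 1L
      v <- bitwAnd(bitwXor(u, labels), 1L)
      a_id <- sprintf("pair_%02d_a", i)
      b_id <- sprintf("pair_%02d_b", i)
      cols[[length(cols) + 1L]] <- flip_channel(u, spec$feature_noise_rate, 2L)
      cols[[length(cols) + 1L]] <- flip_channel(v, spec$feature_noise_rate, 2L)
      ids <- c(ids, a_id, b_id)
      roles <- c(roles, "interaction", "interaction")
      sources <- c(sources, b_id, a_id)
    }
    for (i in seq_len(spec$n_noise)) {
      cols[[length(cols) + 1L]] <- sample.int(k, n, replace = TRUE) - 1L
      ids <- c(ids, sprintf("noise_%02d", i))
      roles <- c(roles, "noise")
      sources <- c(sources, NA_character_)
    }

    values <- do.call(cbind, cols)
    colnames(values) <- ids
    list(matrix = feature_matrix(values, labels = labels, feature_ids = ids),
         roles = data.frame(feature_id = ids, role = roles, source = sources,
                            stringsAsFactors = FALSE))
  })
}

#' Empirical structure report for a generated dataset
#'
#' Computes, for every feature, its empirical symmetrical uncertainty and
#' mutual information with the label and (where a source exists) the
#' symmetrical uncertainty with its source column — the quantities the
#' generator's construction pins down, for use in assertions.
#'
#' @param fm The generated [feature_matrix()].
#' @param roles The matching role map from [make_dataset()].
#' @return The role data frame extended with columns `su_label`,
#'   `mi_label` and `su_source`.
#' @export
expected_structure_report <- function(fm, roles) {
  stopifnot(inherits(fm, "feature_matrix"), is.data.frame(roles))
  if (!identical(roles$feature_id, fm$feature_ids)) {
    stop("role map does not match the matrix feature ids", call. = FALSE)
  }
  roles$su_label <- vapply(roles$feature_id, function(id) {
    symmetrical_uncertainty(feature_column(fm, id), fm$labels)
  }, numeric(1))
  roles$mi_label <- vapply(roles$feature_id, function(id) {
    mutual_information(feature_column(fm, id), fm$labels)
  }, numeric(1))
  roles$su_source <- vapply(seq_len(nrow(roles)), function(i) {
    if (is.na(roles$source[i])) {
      return(NA_real_)
    }
    symmetrical_uncertainty(feature_column(fm, roles$feature_id[i]),
                            feature_column(fm, roles$source[i]))
  }, numeric(1))
  roles
}
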