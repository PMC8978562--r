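# Greedy forward-selection engines: the two-stage CRIA algorithm, a
# generic engine for the comparator criteria, and the incremental feature
# selection (IFS) accuracy curve.
#
# The engine memoizes per-candidate statistics (pairwise terms, running
# interaction weights, the joint row-tuple codes of the selected subset)
# but is contractually identical to re-scoring every candidate from
# scratch each round with score_cria()/score_criterion(); the test suite
# asserts that equivalence against a brute-force oracle.

#' Stage-1 main-effect feature
#'
#' Returns the feature with the largest symmetrical uncertainty with the
#' class label, which seeds the CRIA selection. Ties are broken towards
#' the lowest column index.
#'
#' @param fm A discrete [feature_matrix()] with at least two classes.
#' @return The winning feature id (character scalar).
#' @export
select_main_effect <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  check_discrete(fm, "select_main_effect()")
  check_selection_ready(fm)
  su <- vapply(seq_len(ncol(fm$values)), function(j) {
    symmetrical_uncertainty(fm$values[, j], fm$labels)
  }, numeric(1))
  fm$feature_ids[which.max(su)]
}

new_selection_trace <- function(df, spec, n_features) {
  structure(df,
            class = c("selection_trace", "data.frame"),
            criterion = spec$name, spec = spec, n_features = n_features)
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("selection_trace: criterion '%s', %d of %d features\n",
              attr(x, "criterion"), nrow(x), attr(x, "n_features")))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

# Shared engine. Round 1 picks the criterion's own relevance argmax
# (symmetrical uncertainty for cria/dwfs/iwfs/raiw, mutual information
# otherwise); later rounds pick the argmax of the criterion's objective,
# with ties broken towards the lowest original column index.
greedy_engine <- function(fm, M, spec) {
  stopifnot(inherits(fm, "feature_matrix"))
  check_discrete(fm, "feature selection")
  check_selection_ready(fm)
  n_feat <- ncol(fm$values)
  if (!is.numeric(M) || length(M) != 1L || M != round(M) || M < 1L) {
    stop("'M' must be a positive whole number", call. = FALSE)
  }
  M <- as.integer(M)
  if (M > n_feat) {
    stop(sprintf("'M' (%d) exceeds the number of features (%d)", M, n_feat),
         call. = FALSE)
  }
  name <- spec$name
  alpha <- spec$alpha
  if (name == "raiw" && is.null(alpha)) {
    alpha <- 1 / n_feat
  }

  codes <- lapply(seq_len(n_feat), function(j) as_codes(fm$values[, j]))
  ccodes <- as_codes(fm$labels)
  h_f <- vapply(codes, entropy_from_codes, numeric(1))
  h_c <- entropy_from_codes(ccodes)
  su_fc <- vapply(codes, function(x) symmetrical_uncertainty(x, ccodes),
                  numeric(1))
  mi_fc <- vapply(codes, function(x) mutual_information(x, ccodes),
                  numeric(1))
  su_based <- name %in% SU_BASED
  relevance <- if (su_based) su_fc else mi_fc

  # per-candidate caches, one column appended per selection round
  term_mat <- matrix(NA_real_, n_feat, max(M - 1L, 1L))   # criterion-specific
  factor_mat <- matrix(NA_real_, n_feat, max(M - 1L, 1L)) # weight factors
  su_mat <- matrix(NA_real_, n_feat, max(M - 1L, 1L))     # SU(f, f_s)
  cmi_coef <- NULL
  if (name == "cmi") {
    cmi_coef <- vapply(seq_len(n_feat), function(j) {
      if (h_f[j] <= 0) 0 else conditional_entropy(codes[[j]], ccodes) / h_f[j]
    }, numeric(1))
  }

  candidates <- seq_len(n_feat)
  selected <- integer(0)
  h_sel <- numeric(0)
  key_s <- NULL   # joint codes of the selected subset (cria)
  key_sc <- NULL  # joint codes of (selected subset, class)

  records <- vector("list", M)
  first <- candidates[which.max(relevance[candidates])]
  records[[1L]] <- data.frame(
    rank = 1L, feature_id = fm$feature_ids[first],
    score = relevance[first], relevance = relevance[first],
    redundancy = NA_real_, interaction_factor = NA_real_,
    stringsAsFactors = FALSE)
  selected <- first
  candidates <- setdiff(candidates, first)

  update_caches <- function(just, round_col) {
    js_codes <- codes[[just]]
    for (j in candidates) {
      if (name == "cria" || name == "raiw") {
        su_mat[j, round_col] <<-
          symmetrical_uncertainty(codes[[j]], js_codes)
      }
      term_mat[j, round_col] <<- switch(name,
        cria = symmetrical_uncertainty(codes[[j]], js_codes),
        mifs = ,
        mrmr = mutual_information(codes[[j]], js_codes),
        nmifs = {
          d <- min(h_f[j], h_f[just])
          if (d <= 0) 0 else mutual_information(codes[[j]], js_codes) / d
        },
        cmi = {
          if (h_f[just] <= 0 || h_c <= 0) 0 else
            mi_fc[just] * mutual_information(codes[[j]], js_codes) /
              (h_f[just] * h_c)
        },
        jmim = joint_mutual_information(list(codes[[j]], js_codes), ccodes),
        cfr = conditional_mutual_information(codes[[j]], ccodes, js_codes) +
          interaction_gain(codes[[j]], js_codes, ccodes),
        dcsf = conditional_mutual_information(codes[[j]], ccodes, js_codes) +
          conditional_mutual_information(js_codes, ccodes, codes[[j]]) -
          mutual_information(codes[[j]], js_codes),
        mri = conditional_mutual_information(codes[[j]], ccodes, js_codes) +
          conditional_mutual_information(js_codes, ccodes, codes[[j]]),
        NA_real_)
      if (name %in% WEIGHTED_CRITERIA) {
        factor_mat[j, round_col] <<-
          interaction_weight_factor(name, codes[[j]], js_codes, ccodes)
      }
    }
  }

  for (r in seq_len(M - 1L)) {
    just <- selected[length(selected)]
    h_sel <- c(h_sel, h_f[just])
    if (name == "cria") {
      key_s <- if (is.null(key_s)) codes[[just]] else
        combine_codes(key_s, codes[[just]])
      key_sc <- combine_codes(key_s, ccodes)
    }
    update_caches(just, r)
    ns <- length(selected)
    det <- NULL
    scores <- vapply(candidates, function(j) {
      switch(name,
        cria = {
          red <- sum(term_mat[j, seq_len(ns)]) / ns
          denom <- sum(c(h_sel, h_c)) - entropy_from_codes(key_sc)
          denom <- clamp_tiny_negative(denom)
          if (denom <= 1e-12) {
            inter <- 1
          } else {
            num <- sum(c(h_sel, h_f[j], h_c)) -
              entropy_from_codes(combine_codes(combine_codes(key_s, codes[[j]]),
                                               ccodes))
            inter <- clamp_tiny_negative(num) / denom
          }
          (su_fc[j] - red) * inter
        },
        mifs = mi_fc[j] - spec$beta * sum(term_mat[j, seq_len(ns)]),
        mrmr = mi_fc[j] - sum(term_mat[j, seq_len(ns)]) / ns,
        nmifs = mi_fc[j] - sum(term_mat[j, seq_len(ns)]) / ns,
        cmi = mi_fc[j] - cmi_coef[j] *
          (if (cmi_coef[j] == 0) 0 else sum(term_mat[j, seq_len(ns)])),
        dwfs = su_fc[j] * prod(factor_mat[j, seq_len(ns)]),
        iwfs = prod(factor_mat[j, seq_len(ns)]) * (1 + su_fc[j]),
        raiw = su_fc[j] * (1 - alpha * su_mat[j, ns]) *
          prod(factor_mat[j, seq_len(ns)]),
        cfr = sum(term_mat[j, seq_len(ns)]),
        jmim = min(term_mat[j, seq_len(ns)]),
        dcsf = sum(term_mat[j, seq_len(ns)]),
        mri = mi_fc[j] + sum(term_mat[j, seq_len(ns)]))
    }, numeric(1))
    pick_pos <- which.max(scores)
    pick <- candidates[pick_pos]
    if (name == "cria") {
      red <- sum(term_mat[pick, seq_len(ns)]) / ns
      denom <- clamp_tiny_negative(sum(c(h_sel, h_c)) -
                                     entropy_from_codes(key_sc))
      inter <- if (denom <= 1e-12) 1 else {
        num <- sum(c(h_sel, h_f[pick], h_c)) -
          entropy_from_codes(combine_codes(combine_codes(key_s, codes[[pick]]),
                                           ccodes))
        clamp_tiny_negative(num) / denom
      }
      det <- c(red, inter)
    }
    records[[r + 1L]] <- data.frame(
      rank = r + 1L, feature_id = fm$feature_ids[pick],
      score = scores[pick_pos], relevance = relevance[pick],
      redundancy = if (name == "cria") det[1L] else NA_real_,
      interaction_factor = if (name == "cria") det[2L] else NA_real_,
      stringsAsFactors = FALSE)
    selected <- c(selected, pick)
    candidates <- setdiff(candidates, pick)
  }

  new_selection_trace(do.call(rbind, records), spec, n_feat)
}

#' CRIA feature selection
#'
#' Two-stage greedy selection: stage 1 picks the main-effect feature (the
#' argmax of symmetrical uncertainty with the class); each subsequent
#' round adds the candidate maximizing the CRIA score
#' (relevance minus mean redundancy, times the total-correlation
#' interaction factor over the whole selected subset). See [score_cria()].
#'
#' @param fm A discrete [feature_matrix()].
#' @param M Number of features to select (1..n_features).
#' @return A `selection_trace`: a data frame with one row per round and
#'   columns `rank`, `feature_id`, `score`, `relevance`, `redundancy` and
#'   `interaction_factor` (row 1 stores the stage-1 relevance as its
#'   score). The trace preserves selection order.
#' @examples
#' fm <- make_dataset(synthetic_spec(n_samples = 100, n_noise = 5, seed = 1))$matrix
#' cria_select(fm, M = 3)
#' @export
cria_select <- function(fm, M) {
  greedy_engine(fm, M, criterion_spec("cria"))
}

#' Greedy forward selection under any supported criterion
#'
#' Generic engine for the comparator criteria (and `"cria"` itself, for
#' which it is identical to [cria_select()]). The first feature is the
#' argmax of the criterion's own relevance measure; each later round picks
#' the argmax of [score_criterion()], and the weighted criteria
#' (dwfs/iwfs/raiw) multiply every remaining candidate's weight by its
#' [interaction_weight_factor()] after each pick.
#'
#' @inheritParams cria_select
#' @param criterion A [criterion_spec()] or criterion name.
#' @return A `selection_trace` (see [cria_select()]).
#' @export
greedy_select <- function(fm, M, criterion = "cria") {
  greedy_engine(fm, M, as_criterion_spec(criterion))
}

#' Incremental feature selection accuracy curve
#'
#' Evaluates growing prefixes of a selection trace: for each prefix size
#' k, the mean cross-validated accuracy of the supplied classifier trained
#' on the first k selected features, using the same folds across all
#' prefix sizes within a repeat so the curve is comparable point-to-point.
#' The optimal subset size is the smallest k attaining the maximum mean
#' accuracy.
#'
#' @param fm The discrete [feature_matrix()] the trace was selected from.
#' @param trace A `selection_trace` (or character vector of feature ids in
#'   rank order).
#' @param classifier A classifier object (see [classifier_1nn()]).
#' @param k_folds Number of cross-validation folds (>= 2).
#' @param n_repeats Number of repetitions of the full cross-validation.
#' @param seed Integer seed controlling fold assignment.
#' @param stratify Stratify folds by class (default `TRUE`).
#' @return An `ifs_curve` data frame with columns `k` and `accuracy`
#'   (fractions), plus attributes `optimal_k` and `accuracy_at_optimal`.
#' @export
ifs_curve <- function(fm, trace, classifier = classifier_1nn(),
                      k_folds = 10, n_repeats = 10, seed = 1,
                      stratify = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  check_discrete(fm, "ifs_curve()")
  ids <- if (inherits(trace, "selection_trace")) trace$feature_id
         else as.character(trace)
  feats <- match(ids, fm$feature_ids)
  if (anyNA(feats)) {
    stop("trace features not in the matrix: ",
         paste(ids[is.na(feats)], collapse = ", "), call. = FALSE)
  }
  n <- nrow(fm$values)
  if (k_folds < 2L) {
    stop("'k_folds' must be at least 2", call. = FALSE)
  }
  if (k_folds > n) {
    stop("fewer samples than folds", call. = FALSE)
  }
  K <- length(feats)
  labels <- fm$labels
  acc <- matrix(NA_real_, n_repeats, K)
  with_local_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      folds <- make_fold_ids(labels, k_folds, stratify)
      for (k in seq_len(K)) {
        cols <- fm$values[, feats[seq_len(k)], drop = FALSE]
        correct <- 0L
        for (fold in seq_len(k_folds)) {
          test <- folds == fold
          model <- classifier$fit(cols[!test, , drop = FALSE], labels[!test])
          pred <- classifier$predict(model, cols[test, , drop = FALSE])
          correct <- correct + sum(pred == labels[test])
        }
        acc[rep_i, k] <- correct / n
      }
    }
  })
  mean_acc <- colMeans(acc)
  optimal_k <- which.max(mean_acc) # first maximum = smallest argmax
  structure(
    data.frame(k = seq_len(K), accuracy = mean_acc),
    class = c("ifs_curve", "data.frame"),
    optimal_k = as.integer(optimal_k),
    accuracy_at_optimal = mean_acc[optimal_k],
    classifier = classifier$name, k_folds = k_folds,
    n_repeats = n_repeats, seed = seed)
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat(sprintf("ifs_curve: %d prefix sizes, optimal k = %d (accuracy %.4f)\n",
              nrow(x), attr(x, "optimal_k"), attr(x, "accuracy_at_optimal")))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
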