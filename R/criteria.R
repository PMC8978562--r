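# Scoring of a candidate feature against the current selection state:
# the CRIA criterion and the eleven classical information-theoretic
# comparators it is benchmarked against.
#
# All scorers work on plain categorical vectors: `selected` is the ordered
# list of already-selected feature columns (Omega_S), `f` the candidate
# column and `c` the class label. The greedy engine in selection.R calls
# the same formulas through per-candidate caches; tests assert that the
# cached route equals these from-scratch definitions.

CRITERION_NAMES <- c("cria", "mifs", "mrmr", "nmifs", "cmi", "dwfs",
                     "iwfs", "raiw", "cfr", "jmim", "dcsf", "mri")

# Criteria whose relevance measure is symmetrical uncertainty; all others
# use plain mutual information. The distinction drives the first pick.
SU_BASED <- c("cria", "dwfs", "iwfs", "raiw")

# Criteria that maintain multiplicative per-candidate interaction weights.
WEIGHTED_CRITERIA <- c("dwfs", "iwfs", "raiw")

#' Supported selection criteria
#'
#' @return Character vector of the criterion names accepted by
#'   [criterion_spec()], [greedy_select()] and the command line.
#' @export
criterion_names <- function() CRITERION_NAMES

#' Specify a selection criterion
#'
#' @param name One of [criterion_names()]. `"cria"` combines
#'   symmetrical-uncertainty relevance and redundancy with a
#'   total-correlation interaction factor; the rest are classical
#'   mutual-information filters.
#' @param beta Trade-off between relevance and redundancy, consumed only
#'   by `"mifs"` (default 0.5).
#' @param alpha Redundancy coefficient, consumed only by `"raiw"`. The
#'   default `NULL` resolves to `1 / n_features` of the matrix being
#'   selected from.
#' @return A `criterion_spec` object.
#' @export
criterion_spec <- function(name, beta = 0.5, alpha = NULL) {
  name <- as.character(name)
  if (length(name) != 1L || !(name %in% CRITERION_NAMES)) {
    stop("unknown criterion '", paste(name, collapse = ","),
         "'; must be one of: ", paste(CRITERION_NAMES, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) {
    stop("'beta' must be a single non-negative number", call. = FALSE)
  }
  if (!is.null(alpha) &&
      (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)) {
    stop("'alpha' must be NULL or a single non-negative number", call. = FALSE)
  }
  structure(list(name = name, beta = beta, alpha = alpha),
            class = "criterion_spec")
}

as_criterion_spec <- function(spec) {
  if (inherits(spec, "criterion_spec")) spec else criterion_spec(spec)
}

check_selected <- function(selected) {
  if (!is.list(selected) || length(selected) == 0L) {
    stop("'selected' must be a non-empty list of feature columns ",
         "(run the main-effect stage first)", call. = FALSE)
  }
  selected
}

#' CRIA interaction factor
#'
#' Measures the interaction the candidate feature contributes on top of
#' the selected subset:
#' \deqn{IF = TC(\Omega_S, f, c) / TC(\Omega_S, c)}
#' where TC is the total correlation (negative discrete copula entropy).
#' Because total correlation can only grow when a variable is added, the
#' factor is at least 1 whenever the denominator is positive. A degenerate
#' denominator (selected subset carrying no dependence with the class,
#' below 1e-12) returns the neutral factor 1 so that the
#' relevance-redundancy ordering is preserved.
#'
#' @param selected Non-empty ordered list of selected feature columns.
#' @param f Candidate feature column.
#' @param c Class label vector.
#' @return Interaction factor (positive real, >= 1 away from the guard).
#' @export
interaction_factor_cria <- function(selected, f, c) {
  check_selected(selected)
  denom <- total_correlation(c(selected, list(c)))
  if (denom <= 1e-12) {
    return(1)
  }
  total_correlation(c(selected, list(f), list(c))) / denom
}

#' CRIA candidate score
#'
#' The correlation-redundancy-and-interaction criterion
#' \deqn{J(f) = [SU(f, c) - \frac{1}{n_s}\sum_{f_s \in \Omega_S} SU(f, f_s)] \times IF}
#' with \eqn{n_s = |\Omega_S|} and IF the [interaction_factor_cria()].
#'
#' @inheritParams interaction_factor_cria
#' @param detail If `TRUE`, return a list with `score`, `relevance`,
#'   `redundancy` and `interaction_factor`; otherwise the score alone.
#' @return Numeric score, or a list when `detail = TRUE`.
#' @export
score_cria <- function(selected, f, c, detail = FALSE) {
  check_selected(selected)
  relevance <- symmetrical_uncertainty(f, c)
  redundancy <- sum(vapply(selected, function(fs) {
    symmetrical_uncertainty(f, fs)
  }, numeric(1))) / length(selected)
  interaction <- interaction_factor_cria(selected, f, c)
  score <- (relevance - redundancy) * interaction
  if (detail) {
    list(score = score, relevance = relevance, redundancy = redundancy,
         interaction_factor = interaction)
  } else {
    score
  }
}

#' Score a candidate under a comparator criterion
#'
#' Evaluates the named criterion's objective for candidate `f` given the
#' ordered selected subset. With an empty `selected` the score reduces to
#' the criterion's own relevance measure (symmetrical uncertainty for the
#' weighted SU-based criteria, mutual information otherwise), which is
#' exactly the seeding rule the greedy engine uses for the first pick.
#'
#' The implemented objectives (all information quantities in bits):
#' \describe{
#'   \item{mifs}{\eqn{I(f;c) - \beta \sum_s I(f;f_s)}}
#'   \item{mrmr}{\eqn{I(f;c) - \frac{1}{n_s} \sum_s I(f;f_s)}}
#'   \item{nmifs}{\eqn{I(f;c) - \frac{1}{n_s} \sum_s I(f;f_s)/\min(H(f),H(f_s))}}
#'   \item{cmi}{\eqn{I(f;c) - \frac{H(f|c)}{H(f)} \sum_s I(f_s;c) I(f;f_s) / (H(f_s) H(c))}}
#'   \item{dwfs}{\eqn{SU(f;c) \cdot w(f)}}
#'   \item{iwfs}{\eqn{w(f) \cdot [1 + SU(f;c)]}}
#'   \item{raiw}{\eqn{SU(f;c) \cdot [1 - \alpha SU(f;f_{last})] \cdot w(f)}, with
#'     \eqn{f_{last}} the most recently selected feature}
#'   \item{cfr}{\eqn{\sum_s I(f;c|f_s) + \sum_s IG(f;f_s;c)}}
#'   \item{jmim}{\eqn{\min_s I(f,f_s;c)}}
#'   \item{dcsf}{\eqn{\sum_s I(f;c|f_s) + \sum_s I(f_s;c|f) - \sum_s I(f;f_s)}}
#'   \item{mri}{\eqn{I(f;c) + \sum_s I(f;c|f_s) + \sum_s I(f_s;c|f)}}
#' }
#' Zero-entropy denominators contribute 0 to their term.
#'
#' @param spec A [criterion_spec()] or criterion name.
#' @param f Candidate feature column.
#' @param c Class label vector.
#' @param selected Ordered list of selected feature columns (may be empty).
#' @param weight Current interaction weight of the candidate (only
#'   consumed by dwfs/iwfs/raiw; weights start at 1).
#' @param n_features Total number of features in the originating matrix;
#'   used to resolve the default raiw `alpha = 1 / n_features`.
#' @return Numeric score.
#' @export
score_criterion <- function(spec, f, c, selected = list(), weight = 1,
                            n_features = NULL) {
  spec <- as_criterion_spec(spec)
  name <- spec$name
  if (name == "cria") {
    return(score_cria(check_selected(selected), f, c))
  }
  ns <- length(selected)
  su_fc <- function() symmetrical_uncertainty(f, c)
  mi_fc <- function() mutual_information(f, c)
  switch(name,
    mifs = {
      red <- if (ns == 0) 0 else
        sum(vapply(selected, function(fs) mutual_information(f, fs),
                   numeric(1)))
      mi_fc() - spec$beta * red
    },
    mrmr = {
      red <- if (ns == 0) 0 else
        sum(vapply(selected, function(fs) mutual_information(f, fs),
                   numeric(1))) / ns
      mi_fc() - red
    },
    nmifs = {
      hf <- entropy(f)
      red <- if (ns == 0) 0 else
        sum(vapply(selected, function(fs) {
          d <- min(hf, entropy(fs))
          if (d <= 0) 0 else mutual_information(f, fs) / d
        }, numeric(1))) / ns
      mi_fc() - red
    },
    cmi = {
      hf <- entropy(f)
      hc <- entropy(c)
      coef <- if (hf <= 0) 0 else conditional_entropy(f, c) / hf
      red <- if (ns == 0 || coef == 0) 0 else
        sum(vapply(selected, function(fs) {
          hfs <- entropy(fs)
          if (hfs <= 0 || hc <= 0) return(0)
          mutual_information(fs, c) * mutual_information(f, fs) / (hfs * hc)
        }, numeric(1)))
      mi_fc() - coef * red
    },
    dwfs = su_fc() * weight,
    iwfs = weight * (1 + su_fc()),
    raiw = {
      alpha <- spec$alpha
      if (is.null(alpha)) {
        if (is.null(n_features)) {
          stop("raiw needs 'alpha' or 'n_features' to resolve its default ",
               "alpha = 1/n_features", call. = FALSE)
        }
        alpha <- 1 / n_features
      }
      red <- if (ns == 0) 0 else
        alpha * symmetrical_uncertainty(f, selected[[ns]])
      su_fc() * (1 - red) * weight
    },
    cfr = {
      if (ns == 0) return(mi_fc())
      sum(vapply(selected, function(fs) {
        conditional_mutual_information(f, c, fs) + interaction_gain(f, fs, c)
      }, numeric(1)))
    },
    jmim = {
      if (ns == 0) return(mi_fc())
      min(vapply(selected, function(fs) {
        joint_mutual_information(list(f, fs), c)
      }, numeric(1)))
    },
    dcsf = {
      if (ns == 0) return(mi_fc())
      sum(vapply(selected, function(fs) {
        conditional_mutual_information(f, c, fs) +
          conditional_mutual_information(fs, c, f) -
          mutual_information(f, fs)
      }, numeric(1)))
    },
    mri = {
      mi_fc() + (if (ns == 0) 0 else
        sum(vapply(selected, function(fs) {
          conditional_mutual_information(f, c, fs) +
            conditional_mutual_information(fs, c, f)
        }, numeric(1))))
    }
  )
}

#' Interaction weight update factor
#'
#' After feature `f_s` is selected, dwfs/iwfs/raiw multiply every remaining
#' candidate's weight by a factor built from the three-way interaction gain
#' \eqn{IG = IG(f; f_s; c)}:
#' \describe{
#'   \item{dwfs}{\eqn{1 + 2 IG / (H(f) + H(c))}}
#'   \item{iwfs}{\eqn{1 + IG / (H(f) + H(f_s))}}
#'   \item{raiw}{\eqn{1 + 2 IG / (H(f) + H(f_s) + H(c))}}
#' }
#' A zero denominator yields the neutral factor 1. For criteria without
#' weights the factor is 1 with a warning.
#'
#' @param name Criterion name.
#' @param f Candidate feature column whose weight is being updated.
#' @param f_s The just-selected feature column.
#' @param c Class label vector.
#' @return Multiplicative weight factor.
#' @export
interaction_weight_factor <- function(name, f, f_s, c) {
  name <- as_criterion_spec(name)$name
  if (!(name %in% WEIGHTED_CRITERIA)) {
    warning("criterion '", name, "' does not maintain feature weights; ",
            "returning the neutral factor 1")
    return(1)
  }
  ig <- interaction_gain(f, f_s, c)
  denom <- switch(name,
    dwfs = entropy(f) + entropy(c),
    iwfs = entropy(f) + entropy(f_s),
    raiw = entropy(f) + entropy(f_s) + entropy(c)
  )
  if (denom <= 0) {
    return(1)
  }
  num <- switch(name, dwfs = 2 * ig, iwfs = ig, raiw = 2 * ig)
  1 + num / denom
}
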