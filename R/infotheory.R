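# Plug-in (empirical frequency) estimators of discrete information measures.
# All measures use log base 2 (bits) and the convention 0 * log(0) = 0.
# Joint distributions are estimated by exact row-tuple counting, so any
# finite alphabet (integer codes, characters, factors) is supported; codes
# carry no ordering semantics.

# Canonicalize a categorical vector to dense integer codes 1..K.
# Rejects empty vectors and missing values (missing data are handled,
# if at all, during preprocessing, never inside the estimators).
as_codes <- function(x, arg = "x") {
  if (!is.atomic(x) || is.null(x)) {
    stop(sprintf("'%s' must be an atomic vector of category codes", arg),
         call. = FALSE)
  }
  if (length(x) == 0L) {
    stop(sprintf("'%s' must contain at least one observation", arg),
         call. = FALSE)
  }
  if (anyNA(x)) {
    stop(sprintf("'%s' contains missing values; information measures require complete data", arg),
         call. = FALSE)
  }
  match(x, unique(x))
}

check_equal_lengths <- function(...) {
  lens <- vapply(list(...), length, integer(1))
  if (length(unique(lens)) > 1L) {
    stop("all vectors must have the same length (got lengths ",
         paste(lens, collapse = ", "), ")", call. = FALSE)
  }
  invisible(lens[1L])
}

# Merge two dense code vectors into dense codes of the pair (a_i, b_i).
combine_codes <- function(a, b) {
  k <- (as.double(a) - 1) * max(b) + as.double(b)
  match(k, unique(k))
}

# Dense codes of the row tuples of a list of code vectors.
joint_codes <- function(codes_list) {
  key <- codes_list[[1L]]
  for (i in seq_along(codes_list)[-1L]) {
    key <- combine_codes(key, codes_list[[i]])
  }
  key
}

entropy_from_codes <- function(codes) {
  p <- tabulate(codes) / length(codes)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Tiny negative results of information differences are floating-point
# artefacts; clamp them to zero (anything more negative is a bug upstream).
clamp_tiny_negative <- function(v, tol = 1e-12) {
  if (v < 0 && v > -tol) 0 else v
}

codes_from_list <- function(xs, arg = "xs") {
  if (!is.list(xs) || length(xs) == 0L) {
    stop(sprintf("'%s' must be a non-empty list of categorical vectors", arg),
         call. = FALSE)
  }
  codes <- lapply(seq_along(xs), function(i) {
    as_codes(xs[[i]], arg = sprintf("%s[[%d]]", arg, i))
  })
  lens <- vapply(codes, length, integer(1))
  if (length(unique(lens)) > 1L) {
    stop(sprintf("all vectors in '%s' must have the same length", arg),
         call. = FALSE)
  }
  codes
}

#' Shannon entropy of a categorical sample
#'
#' Plug-in estimate \eqn{H(X) = -\sum_k \hat p_k \log_2 \hat p_k} over the
#' empirical category frequencies, in bits, with \eqn{0 \log 0 = 0}.
#'
#' @param x A categorical vector (integer codes, character, or factor).
#'   Codes compare by equality only; their numeric values carry no meaning.
#' @return Entropy in bits (non-negative scalar).
#' @examples
#' entropy(c(0, 0, 1, 1)) # 1 bit
#' entropy(c(5, 5, 5))    # 0 bits
#' @export
entropy <- function(x) {
  entropy_from_codes(as_codes(x))
}

#' Joint entropy of several categorical samples
#'
#' Entropy of the empirical distribution of row tuples: each sample's tuple
#' of codes across all vectors is counted as a single outcome.
#'
#' @param xs A non-empty list of categorical vectors of equal length.
#' @return Joint entropy in bits.
#' @examples
#' joint_entropy(list(c(0, 1, 0, 1), c(0, 0, 1, 1))) # 2 bits
#' @export
joint_entropy <- function(xs) {
  entropy_from_codes(joint_codes(codes_from_list(xs)))
}

#' Conditional entropy H(Y | X)
#'
#' Computed by the chain rule \eqn{H(Y|X) = H(X,Y) - H(X)}; always
#' non-negative for plug-in estimates from a common sample.
#'
#' @param y,x Categorical vectors of equal length.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(y, x) {
  cy <- as_codes(y, "y")
  cx <- as_codes(x, "x")
  check_equal_lengths(cy, cx)
  clamp_tiny_negative(entropy_from_codes(combine_codes(cx, cy)) -
                        entropy_from_codes(cx))
}

#' Mutual information I(X; Y)
#'
#' Plug-in estimate via \eqn{I(X;Y) = H(X) + H(Y) - H(X,Y)}, in bits.
#' Symmetric in its arguments and non-negative on a common sample.
#'
#' @param x,y Categorical vectors of equal length.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  cx <- as_codes(x, "x")
  cy <- as_codes(y, "y")
  check_equal_lengths(cx, cy)
  clamp_tiny_negative(entropy_from_codes(cx) + entropy_from_codes(cy) -
                        entropy_from_codes(combine_codes(cx, cy)))
}

#' Conditional mutual information I(X; Y | Z)
#'
#' Computed as \eqn{H(Y|Z) - H(Y|X,Z)} through joint entropies.
#'
#' @param x,y,z Categorical vectors of equal length.
#' @return Conditional mutual information in bits (non-negative).
#' @export
conditional_mutual_information <- function(x, y, z) {
  cx <- as_codes(x, "x")
  cy <- as_codes(y, "y")
  cz <- as_codes(z, "z")
  check_equal_lengths(cx, cy, cz)
  h_yz <- entropy_from_codes(combine_codes(cy, cz))
  h_z <- entropy_from_codes(cz)
  h_xyz <- entropy_from_codes(joint_codes(list(cx, cy, cz)))
  h_xz <- entropy_from_codes(combine_codes(cx, cz))
  clamp_tiny_negative((h_yz - h_z) - (h_xyz - h_xz))
}

#' Joint mutual information I(X1, ..., Xq; Y)
#'
#' Information shared between the joint variable formed by all predictors
#' and a target: \eqn{H(X_{1..q}) + H(Y) - H(X_{1..q}, Y)}.
#'
#' @param xs A non-empty list of predictor vectors of equal length.
#' @param y Target categorical vector of the same length.
#' @return Joint mutual information in bits.
#' @export
joint_mutual_information <- function(xs, y) {
  codes <- codes_from_list(xs)
  cy <- as_codes(y, "y")
  check_equal_lengths(codes[[1L]], cy)
  key <- joint_codes(codes)
  clamp_tiny_negative(entropy_from_codes(key) + entropy_from_codes(cy) -
                        entropy_from_codes(combine_codes(key, cy)))
}

#' Interaction gain (three-way interaction information)
#'
#' \eqn{IG(X;Y;Z) = I(X,Y;Z) - I(X;Z) - I(Y;Z)}. Positive values indicate
#' synergy (the pair carries information about Z that neither member does
#' alone, e.g. an XOR pair); negative values indicate redundancy.
#'
#' @param x,y,z Categorical vectors of equal length.
#' @return Interaction gain in bits; may be negative.
#' @export
interaction_gain <- function(x, y, z) {
  joint_mutual_information(list(x, y), z) -
    mutual_information(x, z) - mutual_information(y, z)
}

#' Symmetrical uncertainty SU(X; Y)
#'
#' Mutual information normalized by the sum of marginal entropies,
#' \eqn{SU = 2 I(X;Y) / (H(X) + H(Y))}, lying in \[0, 1\]. When both
#' variables are constant (zero total entropy) the value is defined as 0:
#' a constant feature carries no information.
#'
#' @param x,y Categorical vectors of equal length.
#' @return Symmetrical uncertainty in \[0, 1\].
#' @export
symmetrical_uncertainty <- function(x, y) {
  cx <- as_codes(x, "x")
  cy <- as_codes(y, "y")
  check_equal_lengths(cx, cy)
  hx <- entropy_from_codes(cx)
  hy <- entropy_from_codes(cy)
  if (hx + hy <= 0) {
    return(0)
  }
  i <- clamp_tiny_negative(hx + hy - entropy_from_codes(combine_codes(cx, cy)))
  2 * i / (hx + hy)
}

#' Total correlation (multivariate mutual information)
#'
#' \eqn{TC(X_1, ..., X_q) = \sum_i H(X_i) - H(X_1, ..., X_q)}, the
#' multivariate generalization of mutual information; non-negative, and
#' zero iff the variables are empirically independent.
#'
#' @param xs A list of at least two categorical vectors of equal length.
#' @return Total correlation in bits (non-negative).
#' @export
total_correlation <- function(xs) {
  codes <- codes_from_list(xs)
  if (length(codes) < 2L) {
    stop("'xs' must contain at least two vectors", call. = FALSE)
  }
  marginals <- sum(vapply(codes, entropy_from_codes, numeric(1)))
  clamp_tiny_negative(marginals - entropy_from_codes(joint_codes(codes)))
}

#' Discrete copula entropy
#'
#' For discrete variables the copula entropy equals the negative of the
#' multivariate mutual information, so this returns
#' `-total_correlation(xs)` exactly. It is non-positive, and zero iff the
#' variables are empirically independent.
#'
#' @inheritParams total_correlation
#' @return Copula entropy in bits (non-positive).
#' @export
copula_entropy <- function(xs) {
  -total_correlation(xs)
}
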