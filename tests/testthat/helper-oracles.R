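# Independent oracles used across the suite.
#
# The probability-table oracles compute every information measure by
# direct summation over an explicit joint distribution (outcome rows +
# probabilities), never through the package's sample-based estimators.
# A distribution is "realized as an exact sample" by repeating each
# outcome row in proportion to its probability, so the plug-in estimate
# must agree with the table summation to numerical precision.

# ---- probability-table oracles ----------------------------------------

# Aggregate a joint table onto a subset of variables.
o_project <- function(outcomes, probs, vars) {
  key <- apply(outcomes[, vars, drop = FALSE], 1, paste, collapse = "\r")
  p <- tapply(probs, key, sum)
  as.numeric(p)
}

o_entropy <- function(outcomes, probs, vars) {
  p <- o_project(outcomes, probs, vars)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# I(X;Y) by direct summation of p(x,y) log p(x,y) / (p(x) p(y)).
o_mi <- function(outcomes, probs, vx, vy) {
  keyx <- apply(outcomes[, vx, drop = FALSE], 1, paste, collapse = "\r")
  keyy <- apply(outcomes[, vy, drop = FALSE], 1, paste, collapse = "\r")
  keyxy <- paste(keyx, keyy, sep = "\v")
  pxy <- tapply(probs, keyxy, sum)
  px <- tapply(probs, keyx, sum)
  py <- tapply(probs, keyy, sum)
  # marginal of each joint cell
  cells <- strsplit(names(pxy), "\v", fixed = TRUE)
  s <- 0
  for (i in seq_along(pxy)) {
    p <- pxy[[i]]
    if (p <= 0) next
    s <- s + p * log2(p / (px[[cells[[i]][1]]] * py[[cells[[i]][2]]]))
  }
  s
}

# I(X;Y|Z) = sum_z p(z) sum_xy p(x,y|z) log p(x,y|z) / (p(x|z) p(y|z)).
o_cmi <- function(outcomes, probs, vx, vy, vz) {
  keyz <- apply(outcomes[, vz, drop = FALSE], 1, paste, collapse = "\r")
  s <- 0
  for (z in unique(keyz)) {
    sel <- keyz == z
    pz <- sum(probs[sel])
    if (pz <= 0) next
    s <- s + pz * o_mi(outcomes[sel, , drop = FALSE], probs[sel] / pz, vx, vy)
  }
  s
}

o_jmi <- function(outcomes, probs, vxs, vy) o_mi(outcomes, probs, vxs, vy)

o_ig <- function(outcomes, probs, vx, vy, vz) {
  o_jmi(outcomes, probs, c(vx, vy), vz) -
    o_mi(outcomes, probs, vx, vz) - o_mi(outcomes, probs, vy, vz)
}

o_su <- function(outcomes, probs, vx, vy) {
  hx <- o_entropy(outcomes, probs, vx)
  hy <- o_entropy(outcomes, probs, vy)
  if (hx + hy <= 0) return(0)
  2 * o_mi(outcomes, probs, vx, vy) / (hx + hy)
}

o_tc <- function(outcomes, probs, vars) {
  sum(vapply(vars, function(v) o_entropy(outcomes, probs, v), numeric(1))) -
    o_entropy(outcomes, probs, vars)
}

# ---- enumerated distributions realized as exact samples ----------------

# Random joint distribution over q variables with <= max_levels categories
# each: integer counts on the full outcome grid, probabilities
# proportional to counts.
rand_joint_dist <- function(q, max_levels = 3, max_count = 3) {
  levels <- sample(2:max_levels, q, replace = TRUE)
  grid <- as.matrix(expand.grid(lapply(levels, function(k) 0:(k - 1))))
  counts <- sample(0:max_count, nrow(grid), replace = TRUE)
  if (sum(counts > 0) < 2) {
    counts[sample.int(nrow(grid), 2)] <- 1
  }
  list(outcomes = grid, counts = counts, probs = counts / sum(counts))
}

# Realize the distribution exactly: repeat each outcome row by its count.
realize_sample <- function(dist) {
  rows <- rep(seq_len(nrow(dist$outcomes)), dist$counts)
  m <- dist$outcomes[rows, , drop = FALSE]
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

# ---- brute-force greedy selection oracle -------------------------------

# Re-scores every candidate from scratch each round through the exported
# scorers, recomputing interaction weights as explicit products over the
# selection history. Ties broken towards the lowest column index, as the
# engine documents.
oracle_greedy <- function(fm, M, spec) {
  spec <- criafs::criterion_spec(spec$name, beta = spec$beta,
                                 alpha = spec$alpha)
  nf <- ncol(fm$values)
  cols <- lapply(seq_len(nf), function(j) fm$values[, j])
  cl <- fm$labels
  su_based <- spec$name %in% c("cria", "dwfs", "iwfs", "raiw")
  weighted <- spec$name %in% c("dwfs", "iwfs", "raiw")
  rel <- vapply(cols, function(x) {
    if (su_based) criafs::symmetrical_uncertainty(x, cl)
    else criafs::mutual_information(x, cl)
  }, numeric(1))
  selected <- which.max(rel)
  for (r in seq_len(M - 1L)) {
    candidates <- setdiff(seq_len(nf), selected)
    scores <- vapply(candidates, function(j) {
      w <- 1
      if (weighted) {
        w <- prod(vapply(selected, function(s) {
          criafs::interaction_weight_factor(spec$name, cols[[j]], cols[[s]],
                                            cl)
        }, numeric(1)))
      }
      criafs::score_criterion(spec, cols[[j]], cl,
                              selected = lapply(selected, function(s) cols[[s]]),
                              weight = w, n_features = nf)
    }, numeric(1))
    selected <- c(selected, candidates[which.max(scores)])
  }
  fm$feature_ids[selected]
}

# ---- shared small fixtures ---------------------------------------------

# A deterministic 12-feature, 40-sample discrete fixture with mixed
# relevance/redundancy/interaction structure.
toy_fixture <- function(seed = 42) {
  ds <- with_seed(seed, {
    spec <- criafs::synthetic_spec(
      n_samples = 40, n_classes = 2, n_main = 3, n_redundant = 2,
      n_interaction_pairs = 1, n_noise = 5, label_flip_rate = 0.1,
      feature_noise_rate = 0, seed = seed)
    criafs::make_dataset(spec)
  })
  ds
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
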