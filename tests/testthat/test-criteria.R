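# CRIA scoring, comparator criteria and interaction-weight updates.

test_that("the CRIA interaction factor measures added multivariate dependence", {
  X <- c(0, 0, 1, 1)
  expect_equal(interaction_factor_cria(list(X), c(0, 1, 0, 1), X), 1.0)
  expect_equal(interaction_factor_cria(list(X), X, X), 2.0)
  # selected subset independent of the class: neutral guard value
  expect_equal(interaction_factor_cria(list(c(0, 1, 0, 1)), X, X), 1.0)
  expect_error(interaction_factor_cria(list(), X, X), "non-empty")
})

test_that("score_cria reproduces the hand-worked cases", {
  X <- c(0, 0, 1, 1)
  # relevance 0.343711 exactly cancels redundancy 0.343711
  d <- score_cria(list(X), c(0, 1, 1, 1), X, detail = TRUE)
  expect_equal(d$score, 0.0)
  expect_equal(d$relevance, 0.343711, tolerance = 1e-6)
  expect_equal(d$redundancy, d$relevance)
  expect_equal(d$interaction_factor, 1.311278, tolerance = 1e-6)
  # perfect candidate, irrelevant selected feature: guard makes IF neutral
  expect_equal(score_cria(list(c(0, 1, 0, 1)), X, X), 1.0)
  # candidate independent of everything scores 0
  a <- c(0, 0, 0, 0, 1, 1, 1, 1)
  t <- c(0, 1, 0, 1, 0, 1, 0, 1)
  f <- c(0, 0, 1, 1, 0, 0, 1, 1)
  expect_equal(score_cria(list(a), f, t), 0.0)
})

test_that("the TC-ratio and entropy-expansion routes of the CRIA score agree", {
  with_seed(23, {
    for (i in 1:100) {
      n <- 30
      ns <- sample(1:3, 1)
      selected <- lapply(seq_len(ns), function(j) sample(0:2, n, TRUE))
      f <- sample(0:2, n, TRUE)
      cl <- sample(0:1, n, TRUE)
      h_sel <- vapply(selected, entropy, numeric(1))
      denom <- sum(h_sel) + entropy(cl) - joint_entropy(c(selected, list(cl)))
      if (denom <= 1e-12) next # guard case: expansion undefined
      num <- sum(h_sel) + entropy(f) + entropy(cl) -
        joint_entropy(c(selected, list(f), list(cl)))
      su_route <- symmetrical_uncertainty(f, cl) -
        sum(vapply(selected, function(s) symmetrical_uncertainty(f, s),
                   numeric(1))) / ns
      expect_equal(score_cria(selected, f, cl), su_route * num / denom,
                   tolerance = 1e-10)
    }
  })
})

test_that("comparator criteria reproduce their defining equations", {
  X <- c(0, 1, 0, 1)
  cl <- c(0, 0, 1, 1)
  f <- c(0, 0, 0, 1)
  # mRMR: relevance 0.311278 minus mean redundancy 0.311278
  expect_equal(score_criterion("mrmr", f, cl, list(X)), 0.0)
  # MIFS with beta = 0 reduces to plain MI for any state
  spec0 <- criterion_spec("mifs", beta = 0)
  expect_equal(score_criterion(spec0, f, cl, list(X, cl)),
               mutual_information(f, cl))
  # JMIM over a singleton subset is the joint MI with that feature
  expect_equal(score_criterion("jmim", f, cl, list(X)),
               joint_mutual_information(list(f, X), cl))
  # DCSF and CFR and MRI against their explicit sums on a random state
  with_seed(5, {
    sel <- list(sample(0:2, 20, TRUE), sample(0:1, 20, TRUE))
    g <- sample(0:2, 20, TRUE)
    y <- sample(0:1, 20, TRUE)
    expect_equal(score_criterion("cfr", g, y, sel),
                 sum(sapply(sel, function(s) {
                   conditional_mutual_information(g, y, s) +
                     interaction_gain(g, s, y)
                 })))
    expect_equal(score_criterion("dcsf", g, y, sel),
                 sum(sapply(sel, function(s) {
                   conditional_mutual_information(g, y, s) +
                     conditional_mutual_information(s, y, g) -
                     mutual_information(g, s)
                 })))
    expect_equal(score_criterion("mri", g, y, sel),
                 mutual_information(g, y) +
                   sum(sapply(sel, function(s) {
                     conditional_mutual_information(g, y, s) +
                       conditional_mutual_information(s, y, g)
                   })))
    expect_equal(score_criterion("nmifs", g, y, sel),
                 mutual_information(g, y) -
                   mean(sapply(sel, function(s) {
                     mutual_information(g, s) /
                       min(entropy(g), entropy(s))
                   })))
    # the CMI criterion with its conditional-entropy damping factor
    expect_equal(score_criterion("cmi", g, y, sel),
                 mutual_information(g, y) -
                   conditional_entropy(g, y) / entropy(g) *
                   sum(sapply(sel, function(s) {
                     mutual_information(s, y) * mutual_information(g, s) /
                       (entropy(s) * entropy(y))
                   })))
  })
  expect_error(criterion_spec("relieff"), "unknown criterion")
})

test_that("raiw resolves alpha from the feature count and uses the last pick", {
  with_seed(9, {
    sel <- list(sample(0:1, 24, TRUE), sample(0:1, 24, TRUE))
    f <- sample(0:1, 24, TRUE)
    y <- sample(0:1, 24, TRUE)
    manual <- symmetrical_uncertainty(f, y) *
      (1 - (1 / 50) * symmetrical_uncertainty(f, sel[[2]])) * 0.7
    expect_equal(score_criterion("raiw", f, y, sel, weight = 0.7,
                                 n_features = 50), manual)
    expect_equal(score_criterion(criterion_spec("raiw", alpha = 0.02),
                                 f, y, sel, weight = 0.7), manual)
    expect_error(score_criterion("raiw", f, y, sel), "alpha")
  })
})

test_that("interaction weight factors match the XOR hand computation", {
  fi <- c(0, 0, 1, 1)
  fs <- c(0, 1, 0, 1)
  cl <- c(0, 1, 1, 0) # fi XOR fs
  expect_equal(interaction_weight_factor("iwfs", fi, fs, cl), 1.5)
  expect_equal(interaction_weight_factor("dwfs", fi, fs, cl), 2.0)
  expect_equal(interaction_weight_factor("raiw", fi, fs, cl), 1 + 2 / 3)
  expect_warning(w <- interaction_weight_factor("mrmr", fi, fs, cl),
                 "does not maintain feature weights")
  expect_equal(w, 1)
})

test_that("criterion scores are invariant under relabeling and selected-feature order", {
  with_seed(31, {
    sel <- list(sample(0:2, 30, TRUE), sample(0:1, 30, TRUE))
    f <- sample(0:2, 30, TRUE)
    y <- sample(0:1, 30, TRUE)
    relab <- function(x) c(7L, 3L, 9L)[x + 1]
    for (crit in setdiff(criterion_names(), "raiw")) {
      spec <- criterion_spec(crit)
      base <- score_criterion(spec, f, y, sel, n_features = 10)
      expect_equal(score_criterion(spec, relab(f), y, sel, n_features = 10),
                   base, info = crit)
      # order of previously selected features must not matter
      # (raiw excluded: it singles out the most recent pick by design)
      expect_equal(score_criterion(spec, f, y, rev(sel), n_features = 10),
                   base, info = crit)
    }
  })
})

test_that("an exact duplicate of a selected feature cannot out-score it on relevance-redundancy", {
  with_seed(13, {
    for (i in 1:10) {
      x <- sample(0:2, 40, TRUE)
      y <- sample(0:1, 40, TRUE)
      d <- score_cria(list(x), x, y, detail = TRUE)
      expect_equal(d$redundancy, 1.0)
      expect_lte(d$relevance - d$redundancy, 0)
      expect_lte(d$score, 0)
    }
  })
})
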