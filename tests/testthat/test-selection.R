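# Greedy engines and the IFS curve.

test_that("the main-effect feature is the SU argmax with index tie-breaking", {
  labels <- c(0, 0, 1, 1, 0, 1)
  vals <- cbind(f1 = c(0, 1, 0, 1, 1, 0),
                f2 = labels,               # identical to the class
                f3 = c(1, 1, 0, 0, 1, 1))
  fm <- feature_matrix(vals, labels = labels)
  expect_identical(select_main_effect(fm), "f2")
  # all-indifferent features: lowest column index wins the tie
  vals2 <- cbind(a = c(0, 1, 0, 1), b = c(0, 1, 0, 1), c = c(1, 0, 1, 0))
  fm2 <- feature_matrix(vals2, labels = c(0, 0, 1, 1))
  expect_identical(select_main_effect(fm2), "a")
  # brute-force check on a random fixture
  fm3 <- toy_fixture()$matrix
  su <- vapply(seq_len(ncol(fm3$values)), function(j) {
    symmetrical_uncertainty(fm3$values[, j], fm3$labels)
  }, numeric(1))
  expect_identical(select_main_effect(fm3),
                   fm3$feature_ids[which.max(su)])
  expect_error(select_main_effect(
    feature_matrix(matrix(0:3, 2), labels = c(1, 1))), "two classes")
})

test_that("cria_select handles the M boundary cases and stays deterministic", {
  fm <- toy_fixture()$matrix
  nf <- ncol(fm$values)
  t_all <- cria_select(fm, nf)
  expect_setequal(t_all$feature_id, fm$feature_ids)
  expect_identical(t_all$rank, seq_len(nf))
  t_one <- cria_select(fm, 1)
  expect_identical(t_one$feature_id, select_main_effect(fm))
  expect_identical(t_one$score, t_one$relevance)
  expect_error(cria_select(fm, 0), "positive whole number")
  expect_error(cria_select(fm, nf + 1), "exceeds the number of features")
  # byte-identical traces on repeated runs
  expect_identical(as.data.frame(cria_select(fm, 6)),
                   as.data.frame(cria_select(fm, 6)))
})

test_that("every engine matches the from-scratch greedy oracle on a small fixture", {
  fm <- toy_fixture()$matrix
  for (crit in criterion_names()) {
    spec <- criterion_spec(crit, beta = 0.5)
    trace <- greedy_select(fm, 5, spec)
    expect_identical(trace$feature_id, oracle_greedy(fm, 5, spec),
                     info = crit)
  }
})

test_that("mrmr avoids a redundant duplicate when an informative alternative exists", {
  with_seed(17, {
    labels <- sample(0:1, 200, TRUE)
    strong <- ifelse(runif(200) < 0.05, 1 - labels, labels)
    dupe <- strong
    other <- ifelse(runif(200) < 0.2, 1 - labels, labels)
    noise <- sample(0:1, 200, TRUE)
    fm <- feature_matrix(cbind(strong = strong, dupe = dupe,
                               other = other, noise = noise),
                         labels = labels)
    trace <- greedy_select(fm, 2, "mrmr")
    expect_identical(trace$feature_id[1], "strong")
    # the duplicate's redundancy I(dupe; strong) = H(strong) swamps its
    # relevance, so the weaker-but-fresh feature is picked second
    expect_identical(trace$feature_id[2], "other")
  })
})

test_that("mifs with beta = 0 ranks features by plain mutual information", {
  fm <- toy_fixture()$matrix
  trace <- greedy_select(fm, ncol(fm$values), criterion_spec("mifs", beta = 0))
  mi <- vapply(seq_len(ncol(fm$values)), function(j) {
    mutual_information(fm$values[, j], fm$labels)
  }, numeric(1))
  # stable MI ordering with first-index tie-breaking
  expected <- fm$feature_ids[order(-mi)]
  expect_identical(trace$feature_id, expected)
})

test_that("iwfs per-round scores equal an independent weight-product evaluation", {
  # main feature + XOR pair + noise
  with_seed(29, {
    labels <- sample(0:1, 80, TRUE)
    u <- sample(0:1, 80, TRUE)
    fm <- feature_matrix(cbind(main = ifelse(runif(80) < 0.1,
                                             1 - labels, labels),
                               xa = u, xb = bitwXor(u, labels),
                               noise = sample(0:1, 80, TRUE)),
                         labels = labels)
    trace <- greedy_select(fm, 4, "iwfs")
    # hand-rolled: first pick = SU argmax; then J = w * (1 + SU),
    # w = product of 1 + IG/(H(f)+H(fs)) over the selection history
    cols <- lapply(seq_len(4), function(j) fm$values[, j])
    names(cols) <- fm$feature_ids
    su <- vapply(cols, function(x) symmetrical_uncertainty(x, labels),
                 numeric(1))
    sel <- names(which.max(su))
    for (r in 2:4) {
      cand <- setdiff(names(cols), sel)
      scores <- vapply(cand, function(id) {
        w <- prod(vapply(sel, function(s) {
          1 + interaction_gain(cols[[id]], cols[[s]], labels) /
            (entropy(cols[[id]]) + entropy(cols[[s]]))
        }, numeric(1)))
        w * (1 + su[[id]])
      }, numeric(1))
      pick <- cand[which.max(scores)]
      expect_identical(trace$feature_id[r], pick)
      expect_equal(trace$score[r], unname(scores[pick]), tolerance = 1e-12)
      sel <- c(sel, pick)
    }
  })
})

test_that("selection traces carry unique features, consecutive ranks and the stage-1 rule", {
  fm <- toy_fixture()$matrix
  for (crit in c("cria", "mrmr", "iwfs", "jmim")) {
    trace <- greedy_select(fm, 6, crit)
    expect_identical(trace$rank, 1:6)
    expect_false(anyDuplicated(trace$feature_id) > 0)
    if (crit %in% c("cria", "iwfs")) {
      expect_identical(trace$feature_id[1], select_main_effect(fm))
    }
  }
})

test_that("the IFS curve is flat for a majority-class predictor", {
  fm <- toy_fixture()$matrix
  trace <- cria_select(fm, 5)
  curve <- ifs_curve(fm, trace, classifier_majority(),
                     k_folds = 5, n_repeats = 2, seed = 4)
  expect_equal(nrow(curve), 5)
  maj_frac <- max(table(fm$labels)) / length(fm$labels)
  expect_equal(unique(round(curve$accuracy, 10)), maj_frac)
  expect_identical(attr(curve, "optimal_k"), 1L)
})

test_that("the IFS curve is reproducible under a fixed seed and validates input", {
  fm <- toy_fixture()$matrix
  trace <- cria_select(fm, 4)
  c1 <- ifs_curve(fm, trace, k_folds = 4, n_repeats = 2, seed = 99)
  c2 <- ifs_curve(fm, trace, k_folds = 4, n_repeats = 2, seed = 99)
  expect_identical(c1$accuracy, c2$accuracy)
  expect_error(ifs_curve(fm, trace, k_folds = 1), "at least 2")
  expect_error(ifs_curve(fm, trace, k_folds = 1000), "fewer samples than folds")
  expect_error(ifs_curve(fm, c("nope")), "not in the matrix")
})
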