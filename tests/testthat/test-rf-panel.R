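sep_data <- function(n = 60, seed = 1) {
  # two clearly separated classes on 2 features
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n * 2, mean = 0), n, 2),
               matrix(rnorm(n * 2, mean = 4), n, 2))
    colnames(X) <- c("f1", "f2")
    list(X = X, y = factor(rep(c("control", "AA"), each = n),
                           levels = c("control", "AA")))
  })
}

test_that("forest fitting separates separable data and is deterministic", {
  d <- sep_data()
  m <- fit_rf(d$X, d$y, n_trees = 200, seed = 1)
  expect_lt(m$fit$prediction.error, 0.05)
  m2 <- fit_rf(d$X, d$y, n_trees = 200, seed = 1)
  expect_identical(oob_scores(m, "AA"), oob_scores(m2, "AA"))

  # permuted labels: OOB (Brier) error rises to the chance level
  y_perm <- withr::with_seed(3, sample(d$y))
  mp <- fit_rf(d$X, y_perm, n_trees = 200, seed = 1)
  expect_gt(mp$fit$prediction.error, 0.2)

  expect_error(fit_rf(d$X, factor(rep("AA", nrow(d$X)))), "two classes")
  # every sample is OOB in at least one tree
  expect_true(all(rowSums(m$inbag == 0) > 0))
})

test_that("iterated importance ranks a planted informative feature first", {
  # 1 informative feature (2 SD shift) among 49 noise features, 100 samples
  hits <- vapply(1:4, function(s) {
    X <- withr::with_seed(s, {
      X <- matrix(rnorm(100 * 50), 100, 50)
      X[51:100, 1] <- X[51:100, 1] + 2
      colnames(X) <- sprintf("F%02d", 1:50)
      X
    })
    y <- factor(rep(c("control", "AA"), each = 50), levels = c("control", "AA"))
    r <- iterative_importance(X, y, n_iter = 10, trees_per_iter = 100, seed = s)
    r$feature[1] == "F01"
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # sign semantics: the planted feature is higher in AA
  X <- withr::with_seed(1, {
    X <- matrix(rnorm(100 * 50), 100, 50)
    X[51:100, 1] <- X[51:100, 1] + 2
    colnames(X) <- sprintf("F%02d", 1:50)
    X
  })
  y <- factor(rep(c("control", "AA"), each = 50), levels = c("control", "AA"))
  r <- iterative_importance(X, y, n_iter = 5, trees_per_iter = 100, seed = 1)
  expect_equal(r$sign[r$feature == "F01"], 1)
  expect_gt(r$signed_importance[r$feature == "F01"], 0)

  expect_error(iterative_importance(X, y, n_iter = 1), "n_iter")
})

test_that("label-permuted importances center at zero and dispersion shrinks with more trees", {
  X <- withr::with_seed(5, matrix(rnorm(80 * 20), 80, 20,
                                  dimnames = list(NULL, sprintf("F%02d", 1:20))))
  y <- withr::with_seed(6, factor(sample(rep(c("control", "AA"), each = 40)),
                                  levels = c("control", "AA")))
  r <- iterative_importance(X, y, n_iter = 20, trees_per_iter = 50, seed = 2)
  expect_lt(abs(mean(r$mean_importance)), 0.005)

  # Monte-Carlo variance check: more trees per iteration -> smaller
  # between-iteration dispersion of a feature's importance
  d <- sep_data(n = 40, seed = 7)
  r_small <- iterative_importance(d$X, d$y, n_iter = 15, trees_per_iter = 25,
                                  seed = 3)
  r_big <- iterative_importance(d$X, d$y, n_iter = 15, trees_per_iter = 200,
                                seed = 3)
  expect_lt(mean(r_big$sd_importance), mean(r_small$sd_importance))
})

test_that("panel selection honors its grid, truncation, and forced-size rules", {
  d <- sep_data(n = 40, seed = 8)
  r <- iterative_importance(d$X, d$y, n_iter = 5, trees_per_iter = 50, seed = 1)

  # k_grid = {p}: the panel is all features, ranked
  p_all <- select_panel(r, d$X, d$y, positive = "AA", k_grid = ncol(d$X),
                        n_trees = 100, seed = 1)
  expect_setequal(p_all$feature, colnames(d$X))

  # forced size and truncation: first 5 of the 10 by absolute importance
  X <- withr::with_seed(9, matrix(rnorm(80 * 30), 80, 30,
                                  dimnames = list(NULL, sprintf("F%02d", 1:30))))
  y <- factor(rep(c("control", "AA"), each = 40), levels = c("control", "AA"))
  r30 <- iterative_importance(X, y, n_iter = 5, trees_per_iter = 50, seed = 2)
  p10 <- select_panel(r30, X, y, positive = "AA", force_k = 10, seed = 1)
  expect_equal(nrow(p10), 10)
  expect_equal(head(p10$feature, 5),
               p10$feature[order(abs(p10$signed_importance),
                                 decreasing = TRUE)][1:5])
  # ordering invariant: |importance| descending
  expect_true(all(diff(abs(p10$signed_importance)) <= 1e-12))

  expect_error(select_panel(r30, X, y, positive = "AA", k_grid = numeric(0)),
               "non-empty")
})

test_that("OOB proximities match a brute-force count and satisfy matrix invariants", {
  d <- sep_data(n = 6, seed = 10)  # 12 samples
  rownames(d$X) <- sprintf("s%02d", 1:12)
  m <- fit_rf(d$X, d$y, n_trees = 10, seed = 4)
  prox <- suppressWarnings(oob_proximity(m))

  # enumeration oracle: triple loop over trees and stored leaf assignments
  nodes <- predict(m$fit, data = as.data.frame(m$X),
                   type = "terminalNodes", num.threads = 1)$predictions
  oob <- m$inbag == 0
  for (i in 1:11) for (j in (i + 1):12) {
    both <- which(oob[i, ] & oob[j, ])
    expected <- if (length(both) == 0) 0 else
      mean(nodes[i, both] == nodes[j, both])
    expect_equal(unname(prox[i, j]), expected)
  }
  expect_equal(prox, t(prox))
  expect_true(all(prox >= 0 & prox <= 1))
  expect_true(all(diag(prox) == 1))

  # duplicated sample rows follow identical paths: proximity 1
  Xd <- rbind(d$X, d$X[1, , drop = FALSE])
  rownames(Xd) <- c(rownames(d$X), "dup")
  md <- fit_rf(Xd, factor(c(as.character(d$y), as.character(d$y)[1]),
                          levels = levels(d$y)), n_trees = 200, seed = 5)
  proxd <- suppressWarnings(oob_proximity(md))
  expect_equal(unname(proxd["s01", "dup"]), 1)
})

test_that("PCoA reproduces classical MDS and its geometric degeneracies", {
  # identity proximity: all points mutually equidistant (regular simplex)
  prox_id <- diag(5)
  res <- pcoa(prox_id)
  d_embed <- as.matrix(dist(as.matrix(res$points[-1])))
  off <- d_embed[upper.tri(d_embed)]
  expect_lt(diff(range(off)), 1e-10)

  # hand-built 4x4 proximity vs an independent classical-MDS computation
  prox <- matrix(c(1, .8, .2, .1,
                   .8, 1, .3, .2,
                   .2, .3, 1, .7,
                   .1, .2, .7, 1), 4, 4)
  res4 <- pcoa(prox)
  cmd <- cmdscale(sqrt(1 - prox), k = 3, eig = TRUE)
  ours <- as.matrix(res4$points[paste0("PCo", 1:3)])
  for (k in 1:3) {
    expect_lt(min(max(abs(ours[, k] - cmd$points[, k])),
                  max(abs(ours[, k] + cmd$points[, k]))), 1e-8)
  }
  pos <- cmd$eig[cmd$eig > 1e-9]
  expect_equal(res4$fractions, pos / sum(pos), tolerance = 1e-10)

  # fractions are non-increasing and sum to at most 1
  expect_true(all(diff(res4$fractions) <= 1e-12))
  expect_lte(sum(res4$fractions), 1 + 1e-12)

  expect_warning(pcoa(matrix(1, 4, 4)), "Degenerate")
  expect_error(pcoa(matrix(c(1, 2, 2, 1), 2, 2)), "\\[0, 1\\]")
})

test_that("score evaluation matches the rank-statistic oracle and transform invariance", {
  expect_equal(evaluate_scores(c(1, 2, 3, 10, 11, 12),
                               rep(c("a", "b"), each = 3), "b")$auc_roc, 1)
  expect_equal(evaluate_scores(c(10, 11, 12, 1, 2, 3),
                               rep(c("a", "b"), each = 3), "b")$auc_roc, 0)

  # 20-sample toy: AUC equals the normalized Mann-Whitney U statistic
  for (s in 1:5) {
    scores <- withr::with_seed(s, round(rnorm(20), 1))  # ties likely
    truth <- withr::with_seed(100 + s, sample(rep(c("pos", "neg"), 10)))
    rep_ <- evaluate_scores(scores, truth, positive = "pos")
    expect_equal(rep_$auc_roc, mw_auc(scores, truth == "pos"), tolerance = 1e-12)
    # AUC invariant under strictly monotone transforms of scores
    rep_t <- evaluate_scores(exp(2 * scores), truth, positive = "pos")
    expect_equal(rep_t$auc_roc, rep_$auc_roc, tolerance = 1e-12)
  }

  # operating point: specificity closest to target from above
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  truth <- c("p", "p", "n", "p", "n", "p", "n", "n", "n", "n")
  rep_ <- evaluate_scores(scores, truth, positive = "p", spec_target = 0.70)
  expect_gte(rep_$specificity, 0.70)
  expect_equal(sum(rep_$confusion), 10)
  expect_error(evaluate_scores(1:4, rep("p", 4), "p"), "both")
})

test_that("PPV arithmetic reproduces the combined-screening worked example", {
  # a 70%/90% operating point on 10 cases vs 10 controls: 7 / (7 + 1)
  expect_equal(ppv(0.70, 0.90, 10, 10), 0.875)
  expect_equal(ppv(1, 1, 25, 25), 1)
  expect_equal(ppv(0.5, 0.5, 100, 100), 0.5)  # direct count: 50 / (50 + 50)
  expect_error(ppv(0, 1, 10, 10), "undefined")
  expect_error(ppv(1.2, 0.5, 10, 10), "\\[0, 1\\]")
})

test_that("panel transfer refits consistently and validates its inputs", {
  d <- sep_data(n = 30, seed = 12)
  r <- iterative_importance(d$X, d$y, n_iter = 5, trees_per_iter = 50, seed = 1)
  panel <- select_panel(r, d$X, d$y, positive = "AA", force_k = 2, seed = 1)

  # same contrast: transfer report equals the direct evaluation of the same fit
  tr <- transfer_panel(panel, d$X, d$y, positive = "AA", n_trees = 100, seed = 9)
  direct_fit <- fit_rf(d$X[, panel$feature, drop = FALSE], d$y,
                       n_trees = 100, seed = 9)
  direct <- evaluate_scores(oob_scores(direct_fit, "AA"), d$y, positive = "AA")
  expect_equal(tr$auc_roc, direct$auc_roc)
  expect_equal(tr$sensitivity, direct$sensitivity)

  expect_error(transfer_panel(character(0), d$X, d$y, positive = "AA"), "Empty")
  expect_error(transfer_panel(c("f1", "nope"), d$X, d$y, positive = "AA"),
               "nope")
})

test_that("selection inside training folds leaks nothing to held-out data", {
  # pure-noise cohort: train-side selection inflates training OOB performance,
  # but held-out AUC over seeds stays centered at 0.5
  test_aucs <- vapply(1:6, function(s) {
    X <- withr::with_seed(s, matrix(rnorm(80 * 40), 80, 40,
                                    dimnames = list(NULL, sprintf("F%02d", 1:40))))
    y <- factor(rep(c("control", "AA"), 40), levels = c("control", "AA"))
    tr <- withr::with_seed(1000 + s, sample(80, 60))
    r <- iterative_importance(X[tr, ], y[tr], n_iter = 5, trees_per_iter = 50,
                              seed = s)
    panel <- select_panel(r, X[tr, ], y[tr], positive = "AA", force_k = 5,
                          seed = s)
    m <- fit_rf(X[tr, panel$feature], y[tr], n_trees = 100, seed = s)
    sc <- predict_scores(m, X[-tr, panel$feature, drop = FALSE], "AA")
    mw_auc(sc, y[-tr] == "AA")
  }, numeric(1))
  expect_lt(abs(mean(test_aucs) - 0.5), 0.12)
})
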