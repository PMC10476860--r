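#' Average unsuccessful-search path length of a binary search tree
#'
#' The normalizer `c(n) = 2 H(n-1) - 2 (n-1)/n` used both as the continuation
#' credit at external nodes and to normalize anomaly scores. Harmonic numbers
#' are exact for `n <= 100` and use the `ln + Euler–Mascheroni` approximation
#' above.
#'
#' @param n Subsample size(s).
#' @return `c(n)`, vectorized; 0 for `n <= 1`.
#' @export
path_length_factor <- function(n) {
  vapply(n, function(k) {
    if (k <= 1) return(0)
    h <- if (k - 1 <= 100) sum(1 / seq_len(k - 1)) else log(k - 1) + 0.5772156649015329
    2 * h - 2 * (k - 1) / k
  }, numeric(1))
}

## Grow one isolation tree on rows `idx` of X. Uniform random split feature,
## uniform split point strictly inside the node's observed range; growth stops
## at singletons, duplicate rows (no splittable feature) or the depth cap.
grow_itree <- function(X, idx, depth, max_depth) {
  n <- length(idx)
  if (n <= 1 || depth >= max_depth) return(list(size = n))
  feats <- sample.int(ncol(X))
  for (q in feats) {
    v <- X[idx, q]
    lo <- min(v); hi <- max(v)
    if (hi > lo) {
      s <- runif(1, lo, hi)
      if (s <= lo || s >= hi) s <- (lo + hi) / 2
      return(list(q = q, s = s,
                  left = grow_itree(X, idx[v < s], depth + 1L, max_depth),
                  right = grow_itree(X, idx[v >= s], depth + 1L, max_depth)))
    }
  }
  list(size = n)  # all remaining rows are duplicates
}

#' Fit an Isolation Forest
#'
#' An ensemble of isolation trees, each grown on an independent uniform
#' subsample without replacement, with uniform random split features and
#' uniform split points, capped at depth `ceiling(log2(n_sub))`. Used for
#' one-class screening of cancer cases against controls and for picking
#' representative test subsets.
#'
#' @param X Complete numeric sample-by-feature matrix (or feature table).
#' @param n_trees Number of trees (default 500).
#' @param n_sub Subsample size per tree, `>= 2` (default `min(256, nrow(X))`).
#' @param seed Integer seed; same `(X, seed)` give identical scores.
#' @return An `iforest` model.
#' @export
fit_iforest <- function(X, n_trees = 500, n_sub = min(256L, nrow(X)), seed = 1L) {
  if (is.data.frame(X)) X <- feature_matrix(X)
  if (anyNA(X)) abort("Isolation Forest requires a complete matrix.")
  if (n_trees < 1) abort("`n_trees` must be >= 1.")
  if (n_sub < 2 || n_sub > nrow(X)) abort("`n_sub` must lie in [2, nrow(X)].")
  max_depth <- ceiling(log2(n_sub))
  trees <- withr::with_seed(seed, {
    lapply(seq_len(n_trees), function(t) {
      idx <- sample.int(nrow(X), n_sub)
      grow_itree(X, idx, 0L, max_depth)
    })
  })
  structure(list(trees = trees, n_sub = as.integer(n_sub),
                 n_trees = as.integer(n_trees), n_features = ncol(X),
                 seed = as.integer(seed)),
            class = "iforest")
}

#' @export
print.iforest <- function(x, ...) {
  cat("<iforest> ", x$n_trees, " trees, subsample ", x$n_sub, ", ",
      x$n_features, " features\n", sep = "")
  invisible(x)
}

## Path length of point x through one tree, with c(size) continuation credit
## at external nodes.
itree_path <- function(node, x, depth = 0) {
  if (is.null(node$q)) return(depth + path_length_factor(node$size))
  if (x[node$q] < node$s) itree_path(node$left, x, depth + 1) else
    itree_path(node$right, x, depth + 1)
}

#' Score points with a fitted Isolation Forest
#'
#' Anomaly score `s = 2^(-E(h)/c(n_sub))` where `E(h)` is the path length
#' averaged over trees; `s` lies in (0, 1], equals 0.5 when `E(h) = c(n_sub)`,
#' and approaches 1 for easily isolated (anomalous) points.
#'
#' @param model An `iforest` from [fit_iforest()].
#' @param X Points to score (matrix or feature table; must match the model's
#'   feature count).
#' @return Tibble with `sample_id` (row names or index), `path_length`
#'   (`E(h)`), and `score`.
#' @export
score_iforest <- function(model, X) {
  stopifnot(inherits(model, "iforest"))
  if (is.data.frame(X)) X <- feature_matrix(X)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$n_features) {
    abort(sprintf("Dimension mismatch: model has %d features, input has %d.",
                  model$n_features, ncol(X)))
  }
  cn <- path_length_factor(model$n_sub)
  eh <- vapply(seq_len(nrow(X)), function(i) {
    mean(vapply(model$trees, itree_path, numeric(1), x = X[i, ]))
  }, numeric(1))
  tibble(sample_id = rownames(X) %||% as.character(seq_len(nrow(X))),
         path_length = eh, score = 2^(-eh / cn))
}

#' One-class screening with leave-one-out cross-validation
#'
#' The one-class model for discriminating cancer cases from negative controls
#' without biomarker selection: each control is scored by a forest fit on the
#' remaining controls (leave-one-out), cases are scored against a forest fit
#' on all controls, and the pooled anomaly scores are swept into a ROC. The
#' operating threshold fixes specificity at `spec_target` (closest from
#' above) on the control scores; sensitivity is read off the cases.
#'
#' @param controls,cases Complete matrices (or feature tables) of control and
#'   case samples; at least 10 controls required.
#' @param n_trees Trees per forest.
#' @param n_sub Subsample size; lowered with a warning when it exceeds the
#'   leave-one-out control count.
#' @param spec_target Target specificity of the operating point (default 0.70).
#' @param seed Integer seed.
#' @return A `classifier_report` (see [evaluate_scores()]) with the anomaly
#'   score tibble attached as `$scores`.
#' @export
one_class_loo <- function(controls, cases, n_trees = 150, n_sub = NULL,
                          spec_target = 0.70, seed = 1L) {
  if (is.data.frame(controls)) controls <- feature_matrix(controls)
  if (is.data.frame(cases)) cases <- feature_matrix(cases)
  n_ctrl <- nrow(controls)
  if (n_ctrl < 10) abort("At least 10 controls are required.")
  n_sub <- n_sub %||% min(256L, n_ctrl - 1L)
  if (n_sub > n_ctrl - 1) {
    warn("`n_sub` exceeds the leave-one-out control count; lowering it.")
    n_sub <- n_ctrl - 1L
  }
  ctrl_scores <- vapply(seq_len(n_ctrl), function(i) {
    m <- fit_iforest(controls[-i, , drop = FALSE], n_trees = n_trees,
                     n_sub = n_sub, seed = derive_seed(seed, i))
    score_iforest(m, controls[i, , drop = FALSE])$score
  }, numeric(1))
  full <- fit_iforest(controls, n_trees = n_trees, n_sub = min(n_sub, n_ctrl),
                      seed = derive_seed(seed, 0L))
  case_scores <- score_iforest(full, cases)$score
  scores <- tibble(
    sample_id = c(rownames(controls) %||% paste0("ctrl", seq_len(n_ctrl)),
                  rownames(cases) %||% paste0("case", seq_len(nrow(cases)))),
    truth = factor(rep(c("control", "case"), c(n_ctrl, nrow(cases))),
                   levels = c("control", "case")),
    score = c(ctrl_scores, case_scores)
  )
  report <- evaluate_scores(scores$score, scores$truth, positive = "case",
                            spec_target = spec_target)
  report$scores <- scores
  report$model <- "one-class Isolation Forest (LOO on controls)"
  report
}

#' Representative train/test split via Isolation Forest
#'
#' For each class, an Isolation Forest is fit on the class's samples, the top
#' anomaly-score decile is excluded from test eligibility, and the test
#' samples are drawn stratified across anomaly-score quartiles of the
#' remainder — so the held-out set is typical of its class. All non-test
#' samples of the listed classes form the training set.
#'
#' @param table A complete feature table.
#' @param classes Classes to split (others are ignored).
#' @param n_test_per_class Held-out samples per class.
#' @param n_trees Trees per per-class forest.
#' @param seed Integer seed.
#' @return List with `train` and `test` character vectors of sample ids, plus
#'   `scores` (per-sample anomaly scores used for the split).
#' @export
representative_split <- function(table, classes = c("AA", "control"),
                                 n_test_per_class = 10, n_trees = 100,
                                 seed = 1L) {
  cls <- check_classes(table$class)
  test_ids <- character(0)
  all_ids <- character(0)
  score_tbl <- list()
  for (cl in classes) {
    ids <- table$sample_id[cls == cl]
    if (length(ids) <= n_test_per_class) {
      abort(sprintf("Class %s has %d samples; need more than n_test_per_class = %d.",
                    cl, length(ids), n_test_per_class))
    }
    X <- feature_matrix(table[match(ids, table$sample_id), ])
    m <- fit_iforest(X, n_trees = n_trees, n_sub = min(256L, nrow(X)),
                     seed = derive_seed(seed, match(cl, BREATH_CLASSES)))
    sc <- score_iforest(m, X)
    score_tbl[[cl]] <- dplyr::mutate(sc, class = cl)
    n_out <- ceiling(0.1 * length(ids))
    ord <- order(sc$score, decreasing = TRUE)
    eligible <- ids[ord[-seq_len(n_out)]]  # outlier decile not test-eligible
    if (length(eligible) < n_test_per_class) {
      abort(sprintf("Class %s too small after outlier exclusion.", cl))
    }
    ## stratify test draw across anomaly-score quartiles of the remainder
    strata <- cut(seq_along(eligible), breaks = 4, labels = FALSE)
    per_stratum <- diff(round(seq(0, n_test_per_class, length.out = 5)))
    picked <- withr::with_seed(derive_seed(seed, 100L + match(cl, BREATH_CLASSES)), {
      unlist(lapply(1:4, function(qq) {
        pool <- eligible[strata == qq]
        sample(pool, min(per_stratum[qq], length(pool)))
      }))
    })
    while (length(picked) < n_test_per_class) {
      extra <- setdiff(eligible, picked)[1]
      picked <- c(picked, extra)
    }
    test_ids <- c(test_ids, picked)
    all_ids <- c(all_ids, ids)
  }
  list(train = setdiff(all_ids, test_ids), test = test_ids,
       scores = dplyr::bind_rows(score_tbl))
}
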