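#' Fit a bagged Random-Forest classifier with OOB bookkeeping
#'
#' A thin wrapper around [ranger::ranger()] (probability forest, per-node
#' random feature subsetting of size `sqrt(p)` by default) that retains the
#' training matrix and per-tree bootstrap membership so out-of-bag proximity,
#' permutation importance and out-of-sample projection can be computed. If any
#' sample is in-bag in every tree, the forest is refit with more trees until
#' every sample is OOB at least once.
#'
#' @param X Complete sample-by-feature matrix (or feature table).
#' @param y Class labels (factor; at least two classes present).
#' @param n_trees Number of trees.
#' @param mtry Features tried per split (default `floor(sqrt(ncol(X)))`).
#' @param seed Integer seed (single-threaded for reproducibility).
#' @return A `breath_rf` model.
#' @export
fit_rf <- function(X, y, n_trees = 500, mtry = NULL, seed = 1L) {
  if (is.data.frame(X)) X <- feature_matrix(X)
  if (anyNA(X)) abort("Random Forest requires a complete matrix.")
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) abort("`y` must contain at least two classes.")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(X))))
  df <- as.data.frame(X)
  names(df) <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  for (attempt in 1:4) {
    fit <- ranger::ranger(x = df, y = y, num.trees = n_trees, mtry = mtry,
                          probability = TRUE, keep.inbag = TRUE,
                          seed = seed, num.threads = 1)
    inbag <- do.call(cbind, fit$inbag.counts)
    if (all(rowSums(inbag == 0) > 0)) break
    n_trees <- 2L * n_trees  # rare: some sample never OOB
  }
  structure(list(fit = fit, X = as.matrix(df), y = y, inbag = inbag,
                 n_trees = fit$num.trees, mtry = mtry, seed = as.integer(seed)),
            class = "breath_rf")
}

#' @export
print.breath_rf <- function(x, ...) {
  cat("<breath_rf> ", x$n_trees, " trees on ", nrow(x$X), " samples x ",
      ncol(x$X), " features; classes: ",
      paste(levels(x$y), collapse = ", "),
      sprintf("; OOB error %.3f\n", x$fit$prediction.error), sep = "")
  invisible(x)
}

#' Out-of-bag class-probability scores of a fitted forest
#'
#' @param model A `breath_rf`.
#' @param positive Class whose OOB probability is returned.
#' @return Numeric vector of OOB scores aligned with the training samples.
#' @export
oob_scores <- function(model, positive) {
  stopifnot(inherits(model, "breath_rf"))
  p <- model$fit$predictions
  if (!positive %in% colnames(p)) abort(paste0("Unknown class: ", positive))
  p[, positive]
}

#' Predict positive-class probability for new samples
#'
#' @param model A `breath_rf`.
#' @param X New samples (matrix or feature table with the model's features).
#' @param positive Class whose probability is returned.
#' @return Numeric vector of probabilities.
#' @export
predict_scores <- function(model, X, positive) {
  stopifnot(inherits(model, "breath_rf"))
  if (is.data.frame(X)) X <- feature_matrix(X, colnames(model$X))
  pred <- predict(model$fit, data = as.data.frame(X), num.threads = 1)
  pred$predictions[, positive]
}

#' Iterated permutation importance
#'
#' The internal iterative validation of the marker-discovery model: `n_iter`
#' independent forests are grown with fresh bootstrap seeds, each contributing
#' one out-of-bag permutation-importance draw per feature (accuracy drop when
#' the feature is permuted among OOB samples). Features are summarized by the
#' mean and SD of their draws, and a direction sign is attached from the
#' difference of class means (positive = higher in the positive class, i.e.
#' higher in advanced adenoma for the AA-vs-control contrast).
#'
#' @param X Complete matrix (or feature table).
#' @param y Binary class labels.
#' @param positive Positive-class label (default `"AA"`).
#' @param n_iter Number of forests (>= 2; the study-scale budget is 1,000,
#'   desk-scale runs use 100).
#' @param trees_per_iter Trees per forest.
#' @param seed Integer seed; iteration `i` uses `seed + i`.
#' @return An `importance_ranking` tibble (`feature`, `mean_importance`,
#'   `sd_importance`, `sign`, `signed_importance`), sorted by mean importance
#'   descending, with the full draw matrix in attribute `"draws"`.
#' @export
iterative_importance <- function(X, y, positive = "AA", n_iter = 100,
                                 trees_per_iter = 100, seed = 1L) {
  if (is.data.frame(X)) X <- feature_matrix(X)
  if (n_iter < 2) abort("`n_iter` must be >= 2 (dispersion is undefined otherwise).")
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) abort("`y` must contain at least two classes.")
  df <- as.data.frame(X)
  draws <- vapply(seq_len(n_iter), function(i) {
    ranger::ranger(x = df, y = y, num.trees = trees_per_iter,
                   importance = "permutation", seed = derive_seed(seed, i),
                   num.threads = 1)$variable.importance
  }, numeric(ncol(X)))
  mean_imp <- rowMeans(draws)
  sd_imp <- apply(draws, 1, sd)
  is_pos <- y == positive
  sign_dir <- unname(ifelse(colMeans(X[is_pos, , drop = FALSE]) >=
                              colMeans(X[!is_pos, , drop = FALSE]), 1, -1))
  mean_imp <- unname(mean_imp); sd_imp <- unname(sd_imp)
  out <- tibble(feature = colnames(X), mean_importance = mean_imp,
                sd_importance = sd_imp, sign = sign_dir,
                signed_importance = sign_dir * abs(mean_imp))
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_importance))
  attr(out, "draws") <- draws
  attr(out, "positive") <- positive
  class(out) <- c("importance_ranking", class(out))
  out
}

#' Select a marker panel from an importance ranking
#'
#' For each candidate panel size `k`, the forest is refit on the top-`k`
#' features and the out-of-bag Youden index (max over thresholds of
#' sensitivity + specificity - 1) is recorded; the smallest `k` within one
#' standard error of the best is returned. `force_k` bypasses the search and
#' takes the top `force_k` features directly (the study-scale configuration
#' fixes the panel at 10 compounds).
#'
#' @param ranking An `importance_ranking` computed on training data only.
#' @param X,y Training matrix and labels (same data the ranking used).
#' @param positive Positive-class label.
#' @param k_grid Candidate panel sizes.
#' @param n_trees Trees per refit.
#' @param seed Integer seed.
#' @param force_k Optional fixed panel size.
#' @return A `marker_panel` tibble (`rank`, `feature`, `signed_importance`,
#'   `mean_importance`), ordered by absolute importance descending, with the
#'   OOB size search recorded in attribute `"search"`.
#' @export
select_panel <- function(ranking, X, y, positive = "AA",
                         k_grid = c(2, 3, 5, 8, 10, 15, 20, 30),
                         n_trees = 500, seed = 1L, force_k = NULL) {
  stopifnot(inherits(ranking, "importance_ranking"))
  if (is.data.frame(X)) X <- feature_matrix(X)
  if (is.null(force_k) && length(k_grid) == 0) abort("`k_grid` must be non-empty.")
  ranked <- ranking$feature
  search <- NULL
  if (is.null(force_k)) {
    k_grid <- sort(unique(pmin(k_grid, length(ranked))))
    res <- purrr::map_dfr(k_grid, function(k) {
      m <- fit_rf(X[, ranked[seq_len(k)], drop = FALSE], y,
                  n_trees = n_trees, seed = derive_seed(seed, k))
      sc <- oob_scores(m, positive)
      is_pos <- m$y == positive
      rep <- evaluate_scores(sc, m$y, positive = positive)
      j <- rep$roc$tpr - rep$roc$fpr
      best <- which.max(j)
      sens <- rep$roc$tpr[best]; spec <- 1 - rep$roc$fpr[best]
      se <- sqrt(sens * (1 - sens) / sum(is_pos) +
                   spec * (1 - spec) / sum(!is_pos))
      tibble(k = k, youden = j[best], se = se)
    })
    best <- which.max(res$youden)
    k_sel <- min(res$k[res$youden >= res$youden[best] - res$se[best]])
    search <- res
  } else {
    k_sel <- min(force_k, length(ranked))
  }
  panel <- ranking[seq_len(k_sel), c("feature", "signed_importance", "mean_importance")]
  panel <- dplyr::arrange(panel, dplyr::desc(abs(.data$signed_importance)))
  panel <- dplyr::mutate(panel, rank = dplyr::row_number(), .before = 1)
  attr(panel, "search") <- search
  attr(panel, "seed") <- seed
  attr(panel, "positive") <- attr(ranking, "positive")
  class(panel) <- c("marker_panel", setdiff(class(panel), "importance_ranking"))
  panel
}

#' Out-of-bag proximity matrix of a fitted forest
#'
#' Entry (i, j) is the fraction of trees in which samples i and j are both
#' out-of-bag and fall in the same terminal leaf, over the trees where both
#' are OOB. Pairs never jointly OOB get proximity 0 (with a warning and a
#' count in attribute `"never_jointly_oob"`); the diagonal is 1.
#'
#' @param model A `breath_rf` (fit with OOB bookkeeping).
#' @return Symmetric numeric matrix in \[0, 1\] with sample ids as dimnames.
#' @export
oob_proximity <- function(model) {
  stopifnot(inherits(model, "breath_rf"))
  nodes <- predict(model$fit, data = as.data.frame(model$X),
                   type = "terminalNodes", num.threads = 1)$predictions
  oob <- model$inbag == 0
  n <- nrow(model$X)
  same <- matrix(0, n, n)
  both <- matrix(0, n, n)
  for (t in seq_len(ncol(nodes))) {
    idx <- which(oob[, t])
    if (length(idx) < 2) next
    leaf <- nodes[idx, t]
    eq <- outer(leaf, leaf, "==") * 1
    same[idx, idx] <- same[idx, idx] + eq
    both[idx, idx] <- both[idx, idx] + 1
  }
  never <- sum(both[upper.tri(both)] == 0)
  if (never > 0) {
    warn(sprintf("%d sample pair(s) never jointly out-of-bag; proximity set to 0.",
                 never))
  }
  prox <- ifelse(both > 0, same / both, 0)
  diag(prox) <- 1
  dimnames(prox) <- list(rownames(model$X), rownames(model$X))
  attr(prox, "never_jointly_oob") <- never
  prox
}

#' Proximity of new samples to the training samples
#'
#' Co-leaf fraction of each new sample with each training sample, counted
#' over all trees by default (out-of-bag status is undefined for unseen
#' samples). All-trees proximities sit on a different scale than
#' [oob_proximity()] — in-bag samples help shape their own leaves — which is
#' why PCoA projections built on them are affinely calibrated against the
#' training scores (see [fit_submodel()]). `condition_on_train_oob = TRUE`
#' restricts each column to the training sample's OOB trees instead.
#'
#' @param model A `breath_rf`.
#' @param X_new New samples (matrix or feature table).
#' @param condition_on_train_oob Restrict each column to the training
#'   sample's OOB trees.
#' @return Matrix `nrow(X_new)` x `n_train` of proximities in \[0, 1\].
#' @export
proximity_to_train <- function(model, X_new, condition_on_train_oob = FALSE) {
  stopifnot(inherits(model, "breath_rf"))
  if (is.data.frame(X_new)) X_new <- feature_matrix(X_new, colnames(model$X))
  if (ncol(X_new) != ncol(model$X)) abort("Dimension mismatch with training features.")
  nodes_tr <- predict(model$fit, data = as.data.frame(model$X),
                      type = "terminalNodes", num.threads = 1)$predictions
  nodes_new <- predict(model$fit, data = as.data.frame(X_new),
                       type = "terminalNodes", num.threads = 1)$predictions
  if (is.null(dim(nodes_new))) nodes_new <- matrix(nodes_new, nrow = 1)
  same <- matrix(0, nrow(X_new), nrow(model$X))
  denom <- if (condition_on_train_oob) {
    oob <- model$inbag == 0
    for (t in seq_len(ncol(nodes_tr))) {
      idx <- which(oob[, t])
      same[, idx] <- same[, idx] +
        outer(nodes_new[, t], nodes_tr[idx, t], "==")
    }
    colSums(oob)
  } else {
    for (t in seq_len(ncol(nodes_tr))) {
      same <- same + outer(nodes_new[, t], nodes_tr[, t], "==")
    }
    rep(ncol(nodes_tr), nrow(model$X))
  }
  sweep(same, 2, pmax(denom, 1), "/")
}

#' Refit a marker panel on a new contrast and evaluate it
#'
#' Reuses a selected panel (e.g. the advanced-adenoma panel) for a different
#' contrast, such as CRC vs controls or CRC+AA vs controls: a fresh forest is
#' fit restricted to the panel features and evaluated on its out-of-bag
#' scores at the specificity-anchored operating point.
#'
#' @param panel A `marker_panel` (or character vector of feature ids).
#' @param X,y New-contrast matrix (or feature table) and binary labels.
#' @param positive Positive-class label of the new contrast.
#' @param spec_target Operating-point specificity target.
#' @param n_trees Trees for the refit.
#' @param seed Integer seed.
#' @return A `classifier_report` with the refit model attached as `$model_fit`.
#' @export
transfer_panel <- function(panel, X, y, positive, spec_target = 0.70,
                           n_trees = 500, seed = 1L) {
  features <- if (is.character(panel)) panel else panel$feature
  if (length(features) == 0) abort("Empty panel.")
  if (is.data.frame(X)) X <- feature_matrix(X)
  missing <- setdiff(features, colnames(X))
  if (length(missing) > 0) {
    abort(paste0("Panel feature(s) absent from data: ",
                 paste(missing, collapse = ", ")))
  }
  m <- fit_rf(X[, features, drop = FALSE], y, n_trees = n_trees, seed = seed)
  report <- evaluate_scores(oob_scores(m, positive), m$y, positive = positive,
                            spec_target = spec_target)
  report$model_fit <- m
  report
}
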