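#' Fit one hierarchical submodel (A, B, or the two-class marker model)
#'
#' The three-class procedure builds binary Random-Forest submodels —
#' Model A: advanced adenoma vs the rest (NAA and controls); Model B:
#' non-advanced adenoma vs controls, fit on those two classes only; Model M2:
#' advanced adenoma vs controls — computes each submodel's out-of-bag
#' proximity PCoA, and keeps the first principal-coordinate score per sample.
#' The first axis is oriented so the submodel's positive class has the higher
#' mean score, making the fused feature space stable across runs.
#'
#' @param table A complete feature table (training samples; rows with classes
#'   outside the submodel's contrast are dropped automatically).
#' @param submodel `"A"`, `"B"`, or `"M2"`.
#' @param features Optional feature subset (e.g. a marker panel for M2).
#' @param n_trees Trees for the forest.
#' @param seed Integer seed.
#' @return A `breath_submodel`: list with `id`, `rf`, `prox`, `pcoa`,
#'   `scores` (tibble `sample_id`, `score`), `positive`, `orientation`.
#' @export
fit_submodel <- function(table, submodel = c("A", "B", "M2"), features = NULL,
                         n_trees = 500, seed = 1L) {
  submodel <- match.arg(submodel)
  cls <- check_classes(table$class)
  keep_classes <- switch(submodel,
    A = c("AA", "NAA", "control"),
    B = c("NAA", "control"),
    M2 = c("AA", "control"))
  positive <- switch(submodel, A = "AA", B = "NAA", M2 = "AA")
  sub <- table[cls %in% keep_classes, , drop = FALSE]
  y <- switch(submodel,
    A = factor(ifelse(sub$class == "AA", "AA", "rest"), levels = c("rest", "AA")),
    B = droplevels(factor(sub$class, levels = c("control", "NAA"))),
    M2 = droplevels(factor(sub$class, levels = c("control", "AA"))))
  X <- feature_matrix(sub, features)
  rf <- fit_rf(X, y, n_trees = n_trees, seed = seed)
  prox <- oob_proximity(rf)
  pc <- pcoa(prox)
  score <- pc$points$PCo1
  orientation <- if (mean(score[y == positive]) >= mean(score[y != positive])) 1 else -1
  oriented <- orientation * score
  ## affine calibration of the all-trees projection axis onto the training
  ## (OOB) score scale, so projected out-of-sample scores are commensurate
  proj_raw <- pcoa_project(pc, 1 - proximity_to_train(rf, X))[, 1]
  calibration <- if (sd(proj_raw) > 0) {
    unname(stats::coef(stats::lm(oriented ~ proj_raw)))
  } else c(mean(oriented), 0)
  structure(list(id = submodel, rf = rf, prox = prox, pcoa = pc,
                 scores = tibble(sample_id = sub$sample_id, score = oriented),
                 positive = positive, orientation = orientation,
                 calibration = calibration,
                 classes_seen = keep_classes),
            class = "breath_submodel")
}

#' @export
print.breath_submodel <- function(x, ...) {
  cat("<breath_submodel ", x$id, "> ", nrow(x$scores), " training samples (",
      paste(x$classes_seen, collapse = " vs "), "); PCo1 explains ",
      sprintf("%.1f%%", 100 * x$pcoa$fractions[1]), " of proximity variance\n",
      sep = "")
  invisible(x)
}

#' First-PCo score of new samples under a fitted submodel
#'
#' Out-of-sample proximity of each new sample to the submodel's training
#' samples (co-leaf fraction over all trees), projected onto the stored first
#' principal coordinate and mapped through the submodel's affine calibration
#' onto the training score scale. Projected scores of training samples
#' reproduce their (OOB) training scores only approximately: all-trees and
#' OOB proximities differ systematically, and the calibration absorbs only
#' the affine part of that distortion.
#'
#' @param submodel A `breath_submodel`.
#' @param X_new New samples (matrix or feature table with the submodel's
#'   features).
#' @return Tibble with `sample_id` and `score` (oriented as in training).
#' @export
project_pco <- function(submodel, X_new) {
  stopifnot(inherits(submodel, "breath_submodel"))
  ids <- if (is.data.frame(X_new)) X_new$sample_id else
    rownames(X_new) %||% as.character(seq_len(nrow(X_new)))
  prox_new <- proximity_to_train(submodel$rf, X_new)
  coords <- pcoa_project(submodel$pcoa, 1 - prox_new)
  cal <- submodel$calibration
  tibble(sample_id = ids, score = cal[1] + cal[2] * coords[, 1])
}

#' Midlevel fusion of submodel first-PCo scores
#'
#' Builds the fused 3-column feature matrix (columns fixed in order A, B, M2)
#' for every sample of `table`: samples the submodel scored in training keep
#' their training score; all others (held-out samples, and classes a submodel
#' never saw) are completed via [project_pco()].
#'
#' @param model_a,model_b,model_m2 Fitted `breath_submodel`s A, B, M2.
#' @param table Feature table of all samples to fuse.
#' @return A tibble `sample_id`, `pco_A`, `pco_B`, `pco_M2`.
#' @export
fuse_scores <- function(model_a, model_b, model_m2, table) {
  submodels <- list(A = model_a, B = model_b, M2 = model_m2)
  cols <- purrr::imap(submodels, function(sm, nm) {
    stopifnot(inherits(sm, "breath_submodel"))
    have <- match(table$sample_id, sm$scores$sample_id)
    score <- sm$scores$score[have]
    need <- which(is.na(have))
    if (length(need) > 0) {
      proj <- project_pco(sm, table[need, , drop = FALSE])
      score[need] <- proj$score
    }
    if (anyNA(score)) {
      abort(paste0("Unresolvable fused score for sample(s) ",
                   paste(table$sample_id[is.na(score)], collapse = ", "),
                   " in submodel ", nm, "."))
    }
    score
  })
  tibble(sample_id = table$sample_id, pco_A = cols$A, pco_B = cols$B,
         pco_M2 = cols$M2)
}

#' Fit the final three-class model on fused scores
#'
#' A Random Forest on the fused (A, B, M2) first-PCo columns. Performance is
#' reported on internal validation only: if `valid_ids` are given, the model
#' is fit on the training rows and the confusion matrix comes from predicting
#' the validation rows; otherwise out-of-bag predictions are used. Weighted
#' accuracy is the mean of the three per-class recalls (1/3 = random).
#'
#' @param fused Fused score tibble from [fuse_scores()].
#' @param y Three-class labels (`AA`, `NAA`, `control`) aligned with `fused`.
#' @param train_ids,valid_ids Optional sample-id split for internal
#'   validation.
#' @param n_trees Trees for the forest.
#' @param seed Integer seed.
#' @return A `three_class_report`: list with `confusion` (truth rows),
#'   `per_class_recall`, `weighted_accuracy`, `validation` label, and the
#'   fitted `model`.
#' @export
fit_final <- function(fused, y, train_ids = NULL, valid_ids = NULL,
                      n_trees = 500, seed = 1L) {
  y <- droplevels(check_classes(y))
  X <- as.matrix(fused[c("pco_A", "pco_B", "pco_M2")])
  rownames(X) <- fused$sample_id
  if (!is.null(valid_ids)) {
    train_ids <- train_ids %||% setdiff(fused$sample_id, valid_ids)
    tr <- match(train_ids, fused$sample_id)
    va <- match(valid_ids, fused$sample_id)
    model <- fit_rf(X[tr, , drop = FALSE], y[tr], n_trees = n_trees, seed = seed)
    probs <- predict(model$fit, data = as.data.frame(X[va, , drop = FALSE]),
                     num.threads = 1)$predictions
    pred <- factor(colnames(probs)[max.col(probs, ties.method = "first")],
                   levels = levels(y))
    confusion <- table(truth = y[va], predicted = pred)
    validation <- "internal validation set"
  } else {
    model <- fit_rf(X, y, n_trees = n_trees, seed = seed)
    probs <- model$fit$predictions
    pred <- factor(colnames(probs)[max.col(probs, ties.method = "first")],
                   levels = levels(y))
    confusion <- table(truth = y, predicted = pred)
    validation <- "out-of-bag"
  }
  confusion <- unclass(confusion)
  recalls <- diag(confusion) / rowSums(confusion)
  structure(list(confusion = confusion, per_class_recall = recalls,
                 weighted_accuracy = weighted_accuracy(confusion),
                 validation = validation, model = model),
            class = "three_class_report")
}

#' @export
print.three_class_report <- function(x, ...) {
  cat("<three_class_report> (", x$validation, ")\n", sep = "")
  print(x$confusion)
  cat(sprintf("  per-class recall: %s\n",
              paste(sprintf("%s %.0f%%", names(x$per_class_recall),
                            100 * x$per_class_recall), collapse = ", ")))
  cat(sprintf("  weighted accuracy: %.1f%% (33%% = random)\n",
              100 * x$weighted_accuracy))
  invisible(x)
}
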