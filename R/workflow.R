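#' Configure a full screening-pipeline run
#'
#' Bundles every tunable of the end-to-end experiment: the synthetic cohort
#' (or a user-supplied table), preprocessing choices, batch correction, model
#' budgets and seeds, and operating-point targets. Unknown arguments are
#' rejected. Defaults are the desk-scale study configuration: Figure-style
#' cohort of 382 samples in 2 batches, 20% prevalence filter, Pareto scaling,
#' class-protected parametric batch correction, 100 x 100 importance budget,
#' 10-compound panel, specificity anchored at 70%.
#'
#' @param cohort A [cohort_spec()] (ignored when `table` is supplied).
#' @param table Optional user feature table (complete pipeline input instead
#'   of synthetic generation).
#' @param prevalence_threshold Minimum within-class detection fraction.
#' @param scale_mode `"pareto"` or `"unit"`.
#' @param batch_parametric Parametric empirical-Bayes batch priors.
#' @param use_sva Also estimate surrogate variables (reported, not removed).
#' @param n_test_per_class Held-out test samples per class for the two-class
#'   marker model.
#' @param n_valid_per_class Internal-validation samples per class for the
#'   three-class model.
#' @param panel_k Fixed marker-panel size (`NULL` = one-standard-error search
#'   over `k_grid`).
#' @param k_grid Candidate panel sizes for the search.
#' @param importance_iters,trees_per_iter Iterated-importance budget.
#' @param n_trees Trees for final forests and submodels.
#' @param iforest_trees Trees per Isolation Forest.
#' @param spec_target Operating-point specificity target.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), table = NULL,
                            prevalence_threshold = 0.20,
                            scale_mode = c("pareto", "unit"),
                            batch_parametric = TRUE, use_sva = FALSE,
                            n_test_per_class = 10, n_valid_per_class = 15,
                            panel_k = 10,
                            k_grid = c(2, 3, 5, 8, 10, 15, 20, 30),
                            importance_iters = 100, trees_per_iter = 100,
                            n_trees = 500, iforest_trees = 150,
                            spec_target = 0.70, seed = 1L) {
  scale_mode <- match.arg(scale_mode)
  if (is.null(table)) stopifnot(inherits(cohort, "cohort_spec"))
  if (prevalence_threshold < 0 || prevalence_threshold > 1) {
    abort("`prevalence_threshold` must lie in [0, 1].")
  }
  if (spec_target <= 0 || spec_target >= 1) abort("`spec_target` must lie in (0, 1).")
  structure(list(cohort = cohort, table = table,
                 prevalence_threshold = prevalence_threshold,
                 scale_mode = scale_mode, batch_parametric = batch_parametric,
                 use_sva = use_sva, n_test_per_class = n_test_per_class,
                 n_valid_per_class = n_valid_per_class, panel_k = panel_k,
                 k_grid = k_grid, importance_iters = importance_iters,
                 trees_per_iter = trees_per_iter, n_trees = n_trees,
                 iforest_trees = iforest_trees, spec_target = spec_target,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full screening experiment end to end
#'
#' Generate (or take) a cohort, preprocess (total-intensity normalization,
#' class-prevalence filter, log + scaling), batch-correct, then fit the three
#' models: one-class Isolation-Forest screening of CRC vs controls with LOO
#' cross-validation (Model 1); Random-Forest marker-panel discovery for AA vs
#' controls with a representative Isolation-Forest test split, OOB-proximity
#' PCoA, and panel transfer to CRC and CRC+AA contrasts (Model 2); and the
#' hierarchical midlevel-fusion three-class model (Model 3). Fully
#' deterministic under the config's master seed.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list: `cohort_counts`, `cascade`, `model1`,
#'   `model2` (panel, OOB + test reports, PCoA fractions, PPV arithmetic,
#'   marker recovery when ground truth is known), `transfer` (CRC and CRC+AA),
#'   `model3` (submodel reports, fused report, PCoA fractions), `config`,
#'   `config_hash`, `timings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  timings <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    val
  }

  truth <- NULL
  if (is.null(config$table)) {
    cohort <- tick("generate", generate_cohort(config$cohort,
                                               seed = derive_seed(seed, 1L)))
    raw <- cohort$table
    truth <- cohort$truth
  } else {
    raw <- config$table
  }

  tab <- tick("preprocess", {
    raw |>
      normalize_total() |>
      prevalence_filter(config$prevalence_threshold) |>
      scale_features(config$scale_mode)
  })
  tab <- tick("batch_correct", correct_batch(tab, parametric = config$batch_parametric))
  sva_scores <- if (config$use_sva) {
    surrogate_variables(tab, seed = derive_seed(seed, 9L))
  } else NULL

  cls <- check_classes(tab$class)

  ## Model 1: one-class CRC screening against controls
  model1 <- tick("model1", one_class_loo(
    tab[cls == "control", ], tab[cls == "CRC", ],
    n_trees = config$iforest_trees, spec_target = config$spec_target,
    seed = derive_seed(seed, 2L)))

  ## Model 2: AA vs control marker panel
  split <- tick("split", representative_split(
    tab, c("AA", "control"), n_test_per_class = config$n_test_per_class,
    n_trees = config$iforest_trees, seed = derive_seed(seed, 3L)))
  train <- tab[match(split$train, tab$sample_id), ]
  test <- tab[match(split$test, tab$sample_id), ]
  y_train <- factor(ifelse(train$class == "AA", "AA", "control"),
                    levels = c("control", "AA"))
  ranking <- tick("importance", iterative_importance(
    train, y_train, positive = "AA", n_iter = config$importance_iters,
    trees_per_iter = config$trees_per_iter, seed = derive_seed(seed, 4L)))
  panel <- tick("panel", select_panel(
    ranking, train, y_train, positive = "AA", k_grid = config$k_grid,
    n_trees = config$n_trees, seed = derive_seed(seed, 5L),
    force_k = config$panel_k))
  m2 <- tick("model2", fit_rf(feature_matrix(train, panel$feature), y_train,
                              n_trees = config$n_trees,
                              seed = derive_seed(seed, 6L)))
  m2_oob <- evaluate_scores(oob_scores(m2, "AA"), y_train, positive = "AA",
                            spec_target = config$spec_target)
  y_test <- factor(ifelse(test$class == "AA", "AA", "control"),
                   levels = c("control", "AA"))
  m2_test <- evaluate_scores(predict_scores(m2, test, "AA"), y_test,
                             positive = "AA", spec_target = config$spec_target)
  m2_prox <- oob_proximity(m2)
  m2_pcoa <- pcoa(m2_prox)
  n_pos <- sum(y_test == "AA"); n_neg <- sum(y_test != "AA")
  ppv_breath_fit <- ppv(m2_test$sensitivity, m2_test$specificity, n_pos, n_neg)
  recovery <- if (!is.null(truth) && length(truth$marker_ids) > 0) {
    sum(panel$feature %in% truth$marker_ids)
  } else NA_integer_

  ## Panel transfer: CRC vs control (top-5 compounds), CRC+AA vs control
  crc_ctrl <- tab[cls %in% c("CRC", "control"), ]
  transfer_crc <- tick("transfer_crc", transfer_panel(
    head(panel$feature, 5), crc_ctrl,
    factor(ifelse(crc_ctrl$class == "CRC", "CRC", "control"),
           levels = c("control", "CRC")),
    positive = "CRC", spec_target = config$spec_target,
    n_trees = config$n_trees, seed = derive_seed(seed, 7L)))
  both <- tab[cls %in% c("CRC", "AA", "control"), ]
  transfer_both <- tick("transfer_crc_aa", transfer_panel(
    panel$feature, both,
    factor(ifelse(both$class == "control", "control", "case"),
           levels = c("control", "case")),
    positive = "case", spec_target = config$spec_target,
    n_trees = config$n_trees, seed = derive_seed(seed, 8L)))

  ## Model 3: hierarchical fusion over AA / NAA / control
  three <- tab[cls %in% c("AA", "NAA", "control"), ]
  vsplit <- tick("valid_split", representative_split(
    three, c("AA", "NAA", "control"),
    n_test_per_class = config$n_valid_per_class,
    n_trees = config$iforest_trees, seed = derive_seed(seed, 10L)))
  tr3 <- three[match(vsplit$train, three$sample_id), ]
  model_a <- tick("submodel_a", fit_submodel(tr3, "A", n_trees = config$n_trees,
                                             seed = derive_seed(seed, 11L)))
  model_b <- tick("submodel_b", fit_submodel(tr3, "B", n_trees = config$n_trees,
                                             seed = derive_seed(seed, 12L)))
  model_m2s <- tick("submodel_m2", fit_submodel(
    tr3, "M2", features = panel$feature, n_trees = config$n_trees,
    seed = derive_seed(seed, 13L)))
  report_a <- evaluate_scores(oob_scores(model_a$rf, "AA"), model_a$rf$y,
                              positive = "AA", spec_target = config$spec_target)
  report_b <- evaluate_scores(oob_scores(model_b$rf, "NAA"), model_b$rf$y,
                              positive = "NAA", spec_target = config$spec_target)
  fused <- tick("fuse", fuse_scores(model_a, model_b, model_m2s, three))
  final <- tick("final", fit_final(
    fused, three$class, train_ids = vsplit$train, valid_ids = vsplit$test,
    n_trees = config$n_trees, seed = derive_seed(seed, 14L)))
  final_pcoa <- pcoa(oob_proximity(final$model))

  cascade <- exclusion_cascade(screening_roster())

  report <- structure(list(
    cohort_counts = table(cls),
    n_features_raw = length(feature_cols(raw)),
    n_features_filtered = length(feature_cols(tab)),
    cascade = cascade,
    model1 = model1,
    model2 = list(panel = panel, oob = m2_oob, test = m2_test,
                  pcoa_fractions = m2_pcoa$fractions,
                  train_n = table(y_train), test_n = table(y_test),
                  ppv_fit_only = n_pos / (n_pos + n_neg),
                  ppv_breath_fit = ppv_breath_fit,
                  markers_recovered = recovery,
                  n_markers_planted = if (is.null(truth)) NA_integer_ else
                    length(truth$marker_ids)),
    transfer = list(crc = transfer_crc, crc_aa = transfer_both),
    model3 = list(model_a = report_a, model_b = report_b, final = final,
                  pcoa_fractions = final_pcoa$fractions),
    sva = sva_scores,
    config = config,
    config_hash = rlang::hash(config)
  ), class = "run_report")
  attr(report, "timings") <- timings
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> synthetic screening cohort, ", sum(x$cohort_counts),
      " samples (", paste(sprintf("%s=%d", names(x$cohort_counts),
                                  as.integer(x$cohort_counts)), collapse = ", "),
      ")\n", sep = "")
  cat(sprintf("  features: %d raw -> %d after 20%% prevalence filter\n",
              x$n_features_raw, x$n_features_filtered))
  cat(sprintf("  Model 1 (CRC one-class): AUC %.3f, sens %.1f%% at spec %.1f%%\n",
              x$model1$auc_roc, 100 * x$model1$sensitivity,
              100 * x$model1$specificity))
  cat(sprintf("  Model 2 (AA panel, k = %d): OOB sens %.0f%%/spec %.0f%%; test AUC-ROC %.3f, AUC-PR %.3f\n",
              nrow(x$model2$panel), 100 * x$model2$oob$sensitivity,
              100 * x$model2$oob$specificity, x$model2$test$auc_roc,
              x$model2$test$auc_pr))
  cat(sprintf("  Model 3 (fusion): weighted accuracy %.1f%% (%s)\n",
              100 * x$model3$final$weighted_accuracy, x$model3$final$validation))
  invisible(x)
}

#' Build the screening-participation roster with exclusion flags
#'
#' A synthetic stand-in for the study-entry bookkeeping: `n_enrolled`
#' participants, of whom disjoint groups carry one exclusion flag each
#' (unretrievable hospital records, inadequate bowel preparation, history of
#' IBD, incomplete colonoscopy, failed breath measurement), in that order.
#'
#' @param n_enrolled Total participants.
#' @param exclusions Named integer vector of per-flag counts (flags become
#'   logical roster columns).
#' @return Roster tibble: `sample_id` plus one logical column per flag.
#' @export
screening_roster <- function(n_enrolled = 448,
                             exclusions = c(missing_records = 10,
                                            low_bowel_prep = 3,
                                            ibd = 2,
                                            incomplete_colonoscopy = 3,
                                            failed_measurement = 48)) {
  if (sum(exclusions) > n_enrolled) abort("More exclusions than participants.")
  roster <- tibble(sample_id = sprintf("P%03d", seq_len(n_enrolled)))
  at <- 0
  for (flag in names(exclusions)) {
    v <- rep(FALSE, n_enrolled)
    k <- exclusions[[flag]]
    if (k > 0) v[at + seq_len(k)] <- TRUE
    roster[[flag]] <- v
    at <- at + k
  }
  roster
}

#' Apply exclusion rules to a participant roster
#'
#' Rules are applied in the declared order; each participant is counted under
#' the first rule that excludes them, and the kept roster is the unflagged
#' remainder. Permuting the rule order can change per-rule counts but never
#' the kept set.
#'
#' @param roster Tibble with `sample_id` and one logical column per flag.
#' @param rules Character vector of flag column names, in application order
#'   (default: all logical columns in table order).
#' @return List with `kept` (roster rows excluded by no rule) and `counts`
#'   (named integer vector of first-rule exclusions).
#' @export
exclusion_cascade <- function(roster, rules = NULL) {
  flags <- names(roster)[vapply(roster, is.logical, logical(1))]
  rules <- rules %||% flags
  unknown <- setdiff(rules, names(roster))
  if (length(unknown) > 0) {
    abort(paste0("Unknown exclusion flag(s): ", paste(unknown, collapse = ", ")))
  }
  excluded_by <- rep(NA_character_, nrow(roster))
  for (r in rules) {
    hit <- is.na(excluded_by) & roster[[r]]
    excluded_by[hit] <- r
  }
  counts <- vapply(rules, function(r) sum(excluded_by == r, na.rm = TRUE),
                   integer(1))
  list(kept = roster[is.na(excluded_by), , drop = FALSE],
       counts = counts)
}
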