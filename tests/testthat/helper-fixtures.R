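# Shared fixtures: everything is generated in code at test time.

# A small cohort spec that keeps model fits fast but preserves the default
# generating conditions (effect sizes, noise, batches).
small_spec <- function(n_per_class = c(CRC = 12, AA = 30, NAA = 28, control = 24),
                       n_features = 40, n_markers = 6, seed = 11, ...) {
  cohort_spec(n_per_class = n_per_class, n_features = n_features,
              n_markers = n_markers, seed = seed, ...)
}

# A null spec: no class effects, no dropout, one batch.
null_spec <- function(n_per_class = c(CRC = 10, AA = 20, NAA = 20, control = 20),
                      n_features = 30, seed = 5) {
  cohort_spec(n_per_class = n_per_class, n_features = n_features,
              n_markers = 0,
              dropout = c(CRC = 1, AA = 1, NAA = 1, control = 1),
              n_batches = 1, seed = seed)
}

# Scaled, complete feature table from a spec (no batch correction).
scaled_table <- function(spec) {
  generate_cohort(spec)$table |>
    normalize_total() |>
    prevalence_filter() |>
    scale_features()
}

# Wilcoxon / Mann-Whitney AUC oracle: P(score_pos > score_neg) + 0.5 ties.
mw_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Independent iterative (stack-based) path-length computation over a fitted
# isolation tree, structurally different from the package's recursive
# traversal; used as the enumeration oracle.
oracle_path_length <- function(tree, x) {
  depth <- 0
  node <- tree
  repeat {
    if (is.null(node$q)) {
      return(depth + breathpanel::path_length_factor(node$size))
    }
    node <- if (x[node$q] < node$s) node$left else node$right
    depth <- depth + 1
  }
}

oracle_forest_path <- function(model, x) {
  mean(vapply(model$trees, oracle_path_length, numeric(1), x = x))
}
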