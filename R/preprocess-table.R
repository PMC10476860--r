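#' Total-intensity normalization
#'
#' Divides each sample's detected feature abundances by that sample's total
#' detected abundance, so every row of detected values sums to 1. Missing
#' values (not detected) stay missing. Idempotent.
#'
#' @param table A feature table.
#' @return The normalized feature table.
#' @export
normalize_total <- function(table) {
  feats <- feature_cols(table)
  m <- feature_matrix(table)
  totals <- rowSums(m, na.rm = TRUE)
  empty <- totals == 0 | rowSums(!is.na(m)) == 0
  if (any(empty)) {
    abort(paste0("Sample(s) with no detected features: ",
                 paste(table$sample_id[empty], collapse = ", ")))
  }
  table[feats] <- as_tibble(m / totals)
  table
}

#' Class-prevalence feature filter
#'
#' Keeps a feature if and only if it is detected in at least `threshold`
#' (inclusive) of the samples of at least one disease class. Feature order is
#' preserved; idempotent, and the retained set shrinks weakly as `threshold`
#' increases.
#'
#' @param table A feature table with valid class labels.
#' @param threshold Minimum within-class detection fraction (default 0.20).
#' @return The filtered feature table.
#' @export
prevalence_filter <- function(table, threshold = 0.20) {
  cls <- check_classes(table$class)
  feats <- feature_cols(table)
  det <- !is.na(feature_matrix(table))
  present <- levels(cls)[table(cls) > 0]
  frac <- vapply(present, function(cl) {
    colMeans(det[cls == cl, , drop = FALSE])
  }, numeric(length(feats)))
  keep <- apply(matrix(frac, ncol = length(present)) >= threshold, 1, any)
  table[c(META_COLS, feats[keep])]
}

#' Log-transform, impute, center and scale features
#'
#' Missing values are imputed as half the feature's minimum detected value,
#' then values are natural-log transformed, mean-centered per feature, and
#' scaled: unit-variance (`"unit"`) or Pareto (`"pareto"`, divide by the square
#' root of the feature SD — the default, which keeps each scaled column's
#' variance equal to its pre-scaling SD). Zero-variance features are centered
#' only, with a warning.
#'
#' @param table A feature table (typically normalized and prevalence-filtered).
#' @param mode `"pareto"` or `"unit"`.
#' @return The scaled feature table (complete: no missing values).
#' @export
scale_features <- function(table, mode = c("pareto", "unit")) {
  mode <- match.arg(mode)
  feats <- feature_cols(table)
  m <- feature_matrix(table)
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing)) {
    abort(paste0("Feature(s) with no detected values (filter first): ",
                 paste(feats[all_missing], collapse = ", ")))
  }
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- min(m[!nas, j]) / 2
  }
  m <- log(m)
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  zero_var <- s == 0
  if (any(zero_var)) {
    warn(paste0("Zero-variance feature(s) centered only: ",
                paste(feats[zero_var], collapse = ", ")))
  }
  divisor <- ifelse(zero_var, 1, switch(mode, unit = s, pareto = sqrt(s)))
  m <- sweep(sweep(m, 2, mu), 2, divisor, "/")
  table[feats] <- as_tibble(m)
  table
}
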