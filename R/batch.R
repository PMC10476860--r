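#' Empirical-Bayes batch correction (ComBat)
#'
#' Removes per-batch location and scale effects from a complete (scaled,
#' imputed) feature table by empirical-Bayes shrinkage of the per-batch
#' estimates, with disease class protected as a covariate by default so
#' biological signal is not erased. The computation is delegated to
#' [sva::ComBat()]; this wrapper handles the tabular interface, validates the
#' batch design, and is the identity when the table has a single batch.
#'
#' @param table A complete feature table (no missing values) with a `batch`
#'   column; every batch must have at least 2 samples.
#' @param protect_class Include class indicators as protected covariates
#'   (default `TRUE`). Requires class not to be confounded 1:1 with batch.
#' @param parametric Use the parametric empirical-Bayes priors (normal on
#'   location, inverse-gamma on scale); `FALSE` selects the nonparametric
#'   weighting.
#' @return The batch-corrected feature table (same shape and ids).
#' @export
correct_batch <- function(table, protect_class = TRUE, parametric = TRUE) {
  feats <- feature_cols(table)
  m <- feature_matrix(table)
  if (anyNA(m)) abort("Batch correction requires a complete matrix; scale/impute first.")
  batch <- factor(table$batch)
  if (nlevels(batch) < 2) return(table)
  sizes <- table(batch)
  if (any(sizes < 2)) {
    abort(paste0("Singleton batch(es): ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  mod <- NULL
  if (protect_class) {
    cls <- droplevels(check_classes(table$class))
    if (nlevels(cls) > 1) {
      if (all(rowSums(table(cls, batch) > 0) == 1)) {
        abort("Class is confounded 1:1 with batch; cannot protect it.")
      }
      mod <- model.matrix(~cls)
    }
  }
  ## ComBat drops features with zero within-batch variance from correction;
  ## features x samples orientation as it expects.
  corrected <- suppressMessages(
    sva::ComBat(dat = t(m), batch = batch, mod = mod, par.prior = parametric)
  )
  table[feats] <- as_tibble(t(corrected))
  table
}

#' Surrogate variable analysis by residual SVD
#'
#' Estimates hidden (unmodelled) structure in a complete feature table: the
#' table is residualized on the primary design, the residual matrix is
#' decomposed by SVD, and the number of surrogate variables is chosen by a
#' permutation test (Buja–Eyuboglu style) comparing each component's variance
#' fraction against permuted residuals, unless `n_sv` is given. Scores are
#' orthogonal to the primary design by construction.
#'
#' @param table A complete feature table.
#' @param design Primary model formula over metadata columns (default
#'   `~ class`), whose effects are removed before looking for hidden factors.
#' @param n_sv Number of surrogate variables; `NULL` (default) selects it by
#'   permutation.
#' @param n_perm Number of residual permutations for selection.
#' @param alpha Per-component significance level of the permutation test.
#' @param seed Integer seed for the permutations.
#' @return Numeric matrix (samples x surrogate variables, possibly 0 columns)
#'   with columns `SV1`, `SV2`, ...; sample ids as row names.
#' @export
surrogate_variables <- function(table, design = ~class, n_sv = NULL,
                                n_perm = 20, alpha = 0.05, seed = 1L) {
  m <- feature_matrix(table)
  if (anyNA(m)) abort("Surrogate variable analysis requires a complete matrix.")
  X <- model.matrix(design, data = table)
  max_sv <- min(nrow(m), ncol(m)) - ncol(X)
  if (!is.null(n_sv) && n_sv >= min(nrow(m), ncol(m))) {
    abort("`n_sv` must be smaller than min(samples, features).")
  }
  hat <- X %*% solve(crossprod(X), t(X))
  R <- m - hat %*% m
  sv <- svd(R)
  frac <- sv$d^2 / sum(sv$d^2)
  if (is.null(n_sv)) {
    perm_frac <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        Rp <- apply(R, 2, sample)
        Rp <- Rp - hat %*% Rp
        dp <- svd(Rp, nu = 0, nv = 0)$d
        dp^2 / sum(dp^2)
      }, numeric(length(frac)))
    })
    n_sv <- 0L
    for (k in seq_len(max(max_sv, 0))) {
      p_k <- (1 + sum(perm_frac[k, ] >= frac[k])) / (n_perm + 1)
      if (p_k <= alpha) n_sv <- k else break
    }
  }
  scores <- sv$u[, seq_len(n_sv), drop = FALSE] %*%
    diag(sv$d[seq_len(n_sv)], nrow = n_sv)
  dimnames(scores) <- list(table$sample_id,
                           if (n_sv > 0) paste0("SV", seq_len(n_sv)))
  scores
}
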