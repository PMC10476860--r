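#' Principal coordinate analysis of a proximity matrix
#'
#' Classical multidimensional scaling of Random-Forest proximities: distances
#' are `d = sqrt(1 - proximity)` (which guarantees a Euclidean-embeddable
#' squared-distance matrix `1 - proximity`), the squared distances are
#' double-centered, and the eigendecomposition yields coordinates (eigenvectors
#' scaled by the square roots of the positive eigenvalues) and
#' explained-variance fractions computed over positive eigenvalues only.
#'
#' @param prox Symmetric proximity matrix with unit diagonal and entries in
#'   \[0, 1\] (e.g. from [oob_proximity()]).
#' @param n_axes Number of coordinate axes to return (default: all positive).
#' @return A `pcoa_result`: list with `points` (tibble `sample_id`, `PCo1`,
#'   ...), `eigenvalues`, `fractions` (explained variance per returned axis),
#'   and the centering statistics needed for out-of-sample projection.
#' @export
pcoa <- function(prox, n_axes = NULL) {
  prox <- as.matrix(prox)
  n <- nrow(prox)
  if (ncol(prox) != n) abort("Proximity matrix must be square.")
  if (max(abs(prox - t(prox))) > 1e-8) abort("Proximity matrix must be symmetric.")
  if (any(prox < -1e-8 | prox > 1 + 1e-8)) abort("Proximities must lie in [0, 1].")
  if (any(abs(diag(prox) - 1) > 1e-8)) abort("Proximity diagonal must be 1.")
  ids <- rownames(prox) %||% as.character(seq_len(n))
  D2 <- 1 - prox
  rm_ <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  eig <- eigen(B, symmetric = TRUE)
  tol <- 1e-9 * max(abs(eig$values), 1e-12)
  pos <- which(eig$values > tol)
  if (length(pos) == 0) {
    warn("Degenerate embedding: no positive eigenvalues (all proximities equal).")
    pts <- tibble(sample_id = ids)
    return(structure(list(points = pts, eigenvalues = eig$values,
                          fractions = numeric(0), vectors = eig$vectors[, 0],
                          values_pos = numeric(0), d2_colmeans = rm_,
                          d2_mean = gm, sample_id = ids),
                     class = "pcoa_result"))
  }
  keep <- pos[seq_len(min(n_axes %||% length(pos), length(pos)))]
  lambda <- eig$values[keep]
  coords <- sweep(eig$vectors[, keep, drop = FALSE], 2, sqrt(lambda), "*")
  colnames(coords) <- paste0("PCo", seq_along(keep))
  structure(list(
    points = dplyr::bind_cols(tibble(sample_id = ids), as_tibble(coords)),
    eigenvalues = eig$values,
    fractions = lambda / sum(eig$values[pos]),
    vectors = eig$vectors[, keep, drop = FALSE],
    values_pos = lambda,
    d2_colmeans = rm_, d2_mean = gm, sample_id = ids
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("<pcoa_result> ", length(x$sample_id), " samples, ",
      length(x$fractions), " positive axes; explained variance: ",
      paste(sprintf("%.1f%%", 100 * head(x$fractions, 3)), collapse = ", "),
      if (length(x$fractions) > 3) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Project new points into an existing PCoA space
#'
#' Standard out-of-sample (Gower) projection: the new point's squared
#' distances to the training points are double-centered against the stored
#' centering statistics and regressed onto the stored eigenvectors.
#'
#' @param res A `pcoa_result`.
#' @param d2_new Matrix (new x train) of squared distances from each new point
#'   to every training point.
#' @return Coordinate matrix (new x axes).
#' @export
pcoa_project <- function(res, d2_new) {
  stopifnot(inherits(res, "pcoa_result"))
  if (is.null(dim(d2_new))) d2_new <- matrix(d2_new, nrow = 1)
  if (ncol(d2_new) != length(res$sample_id)) {
    abort("`d2_new` must have one column per training sample.")
  }
  n <- length(res$sample_id)
  b <- -0.5 * (d2_new -
                 outer(rep(1, nrow(d2_new)), res$d2_colmeans) -
                 rowMeans(d2_new) + res$d2_mean)
  coords <- b %*% res$vectors
  sweep(coords, 2, sqrt(res$values_pos), "/")
}
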