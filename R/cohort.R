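#' Specify a synthetic breath-VOC screening cohort
#'
#' Defines the generating model for a synthetic TD-GC-MS breath cohort:
#' per-class sample counts, number of VOC features, planted marker compounds
#' with signed class effects, instrument batches with location/scale effects,
#' within-class noise, and detection dropout. Defaults mirror a FIT-positive
#' colorectal screening cohort of 382 patients in four diagnostic classes
#' (30 CRC, 138 advanced adenoma, 130 non-advanced adenoma, 84 negative
#' controls) measured in 2 study centers.
#'
#' Abundances are log-normal: class and batch effects act additively on the
#' natural-log scale, i.e. multiplicatively on the raw peak-area scale. The
#' batch model is `log A = mu_f + effect(class, f) + gamma[batch, f] +
#' delta[batch, f] * eps`, with `gamma ~ N(0, batch_location_sd)` and
#' `log delta ~ N(0, batch_scale_sd)` — exactly the location/scale model
#' that empirical-Bayes batch correction assumes.
#'
#' @param n_per_class Named integer vector of sample counts for classes
#'   `CRC`, `AA`, `NAA`, `control`.
#' @param n_features Number of VOC features.
#' @param n_markers Number of planted marker features (default 10).
#' @param effect_sizes Optional `n_markers x 4` matrix of signed log-scale
#'   abundance shifts relative to control, columns named by class. The default
#'   plants markers with AA effect magnitude 1.0 (six positive = higher in
#'   advanced adenoma, four negative = higher in controls), CRC effects 1.2x
#'   the AA effect with the same signs, and NAA effects 0.4x.
#' @param dropout Named vector of per-class, per-feature detection
#'   probabilities in \[0, 1\] (1 = always detected).
#' @param dropout_mode `"bernoulli"` (independent detection per class, the
#'   default) or `"censor"` (missing-not-at-random: a value is undetected when
#'   its raw abundance falls below the feature's `censor_quantile` quantile).
#' @param censor_quantile Censoring quantile for `dropout_mode = "censor"`.
#' @param n_batches Number of instrument batches (samples assigned round-robin
#'   within class so batch is not confounded with class).
#' @param batch_location_sd,batch_scale_sd SD of per-batch additive log-scale
#'   location effects and of log multiplicative scale effects.
#' @param noise_sd Within-class log-scale noise SD.
#' @param seed Integer seed; identical spec + seed gives a bit-identical cohort.
#' @return A `cohort_spec` object (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_per_class = c(CRC = 30L, AA = 138L, NAA = 130L, control = 84L),
                        n_features = 200L,
                        n_markers = 10L,
                        effect_sizes = NULL,
                        dropout = c(CRC = 0.85, AA = 0.85, NAA = 0.85, control = 0.85),
                        dropout_mode = c("bernoulli", "censor"),
                        censor_quantile = 0.05,
                        n_batches = 2L,
                        batch_location_sd = 0.4,
                        batch_scale_sd = 0.1,
                        noise_sd = 0.5,
                        seed = 1L) {
  dropout_mode <- match.arg(dropout_mode)
  if (is.null(names(n_per_class)) || !setequal(names(n_per_class), BREATH_CLASSES)) {
    abort("`n_per_class` must be named with classes CRC, AA, NAA, control.")
  }
  n_per_class <- as.integer(n_per_class[BREATH_CLASSES])
  names(n_per_class) <- BREATH_CLASSES
  if (any(n_per_class <= 0)) abort("All class counts must be > 0.")
  if (n_features <= 0 || n_batches <= 0) abort("Counts must be > 0.")
  if (n_markers < 0 || n_markers > n_features) {
    abort("`n_markers` must lie in [0, n_features].")
  }
  if (is.null(names(dropout)) || !all(BREATH_CLASSES %in% names(dropout))) {
    abort("`dropout` must be named with classes CRC, AA, NAA, control.")
  }
  dropout <- dropout[BREATH_CLASSES]
  if (any(dropout < 0 | dropout > 1)) abort("Detection probabilities must lie in [0, 1].")
  if (noise_sd < 0 || batch_location_sd < 0 || batch_scale_sd < 0) {
    abort("Dispersion parameters must be >= 0.")
  }
  if (is.null(effect_sizes)) {
    effect_sizes <- default_effect_sizes(n_markers)
  } else {
    effect_sizes <- as.matrix(effect_sizes)
    if (nrow(effect_sizes) != n_markers || !all(BREATH_CLASSES %in% colnames(effect_sizes))) {
      abort("`effect_sizes` must be an n_markers x 4 matrix with columns CRC, AA, NAA, control.")
    }
    effect_sizes <- effect_sizes[, BREATH_CLASSES, drop = FALSE]
  }
  structure(
    list(n_per_class = n_per_class, n_features = as.integer(n_features),
         n_markers = as.integer(n_markers), effect_sizes = effect_sizes,
         dropout = dropout, dropout_mode = dropout_mode,
         censor_quantile = censor_quantile, n_batches = as.integer(n_batches),
         batch_location_sd = batch_location_sd, batch_scale_sd = batch_scale_sd,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

## Signed AA effects of magnitude 1 (six up in AA, four down), CRC same
## direction but 1.2x (panel transfers to cancer), NAA attenuated at 0.4x.
default_effect_sizes <- function(n_markers) {
  if (n_markers == 0) {
    return(matrix(numeric(0), 0, 4, dimnames = list(NULL, BREATH_CLASSES)))
  }
  signs <- rep(c(1, -1), times = c(ceiling(0.6 * n_markers),
                                   n_markers - ceiling(0.6 * n_markers)))
  aa <- signs * 1.0
  cbind(CRC = 1.2 * aa, AA = aa, NAA = 0.4 * aa, control = 0)[, BREATH_CLASSES,
                                                              drop = FALSE]
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", sum(x$n_per_class), " samples (",
      paste(sprintf("%s=%d", names(x$n_per_class), x$n_per_class), collapse = ", "),
      "), ", x$n_features, " features, ", x$n_markers, " markers, ",
      x$n_batches, " batch(es), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic breath-VOC cohort with known ground truth
#'
#' Draws a sample-by-feature peak-area table from the generating model of a
#' [cohort_spec()], together with the ground truth needed to score recovery
#' downstream (which features are markers, their effect signs, class and batch
#' assignments).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to the seed stored in `spec`.
#' @return A `breath_cohort`: a list with
#'   \describe{
#'     \item{table}{feature table (tibble: `sample_id`, `class`, `batch`, one
#'       numeric column per feature; `NA` = not detected).}
#'     \item{features}{feature metadata tibble (`feature`, `rt` seconds,
#'       `mz` nominal bin, `mu` baseline log-abundance).}
#'     \item{truth}{ground-truth list (`marker_ids`, `marker_signs`,
#'       `effect_sizes`, `class`, `batch` as named vectors).}
#'     \item{spec}{the generating spec.}
#'   }
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(seed, {
    n <- sum(spec$n_per_class)
    p <- spec$n_features
    classes <- factor(rep(names(spec$n_per_class), spec$n_per_class),
                      levels = BREATH_CLASSES)
    ## round-robin within class so batch is never confounded with class
    batch <- unlist(lapply(spec$n_per_class, function(k) {
      rep_len(seq_len(spec$n_batches), k)
    }), use.names = FALSE)
    batch <- factor(paste0("B", batch), levels = paste0("B", seq_len(spec$n_batches)))
    sample_id <- sprintf("S%03d", seq_len(n))

    feat_id <- sprintf("F%03d", seq_len(p))
    feat_meta <- assign_feature_positions(p, feat_id)
    mu <- runif(p, 1, 4)
    feat_meta$mu <- mu

    marker_idx <- if (spec$n_markers > 0) sort(sample.int(p, spec$n_markers)) else integer(0)
    effect <- matrix(0, nrow = nlevels(classes), ncol = p,
                     dimnames = list(BREATH_CLASSES, feat_id))
    if (spec$n_markers > 0) {
      effect[, marker_idx] <- t(spec$effect_sizes)
    }

    gamma <- matrix(rnorm(spec$n_batches * p, 0, spec$batch_location_sd),
                    spec$n_batches, p)
    delta <- exp(matrix(rnorm(spec$n_batches * p, 0, spec$batch_scale_sd),
                        spec$n_batches, p))
    if (spec$n_batches == 1) { gamma[] <- 0; delta[] <- 1 }

    eps <- matrix(rnorm(n * p, 0, spec$noise_sd), n, p)
    bi <- as.integer(batch)
    log_ab <- matrix(mu, n, p, byrow = TRUE) +
      effect[as.character(classes), , drop = FALSE] +
      gamma[bi, , drop = FALSE] +
      delta[bi, , drop = FALSE] * eps
    raw <- exp(log_ab)

    detected <- if (spec$dropout_mode == "bernoulli") {
      pdet <- spec$dropout[as.character(classes)]
      matrix(rbinom(n * p, 1, rep(pdet, p)), n, p) == 1
    } else {
      thr <- apply(raw, 2, quantile, probs = spec$censor_quantile)
      sweep(raw, 2, thr, ">=")
    }
    raw[!detected] <- NA_real_

    colnames(raw) <- feat_id
    table <- dplyr::bind_cols(
      tibble(sample_id = sample_id, class = classes, batch = batch),
      as_tibble(raw)
    )
    truth <- list(
      marker_ids = feat_id[marker_idx],
      marker_signs = setNames(sign(spec$effect_sizes[, "AA"]), feat_id[marker_idx]),
      effect_sizes = spec$effect_sizes,
      class = setNames(as.character(classes), sample_id),
      batch = setNames(as.character(batch), sample_id)
    )
    structure(list(table = table, features = feat_meta, truth = truth, spec = spec),
              class = "breath_cohort")
  })
}

## Place features on the chromatographic plane: nominal m/z channels from a
## 40-250 pool, retention times on a 30 s grid within 60-1080 s so co-channel
## peaks stay resolvable, plus sub-grid jitter.
assign_feature_positions <- function(p, feat_id) {
  mz_pool <- sample(40:250)
  mz <- rep_len(mz_pool, p)
  rt <- numeric(p)
  slots <- seq(60, 1080, by = 30)
  for (ch in unique(mz)) {
    idx <- which(mz == ch)
    rt[idx] <- sort(sample(slots, length(idx))) + runif(length(idx), -5, 5)
  }
  tibble(feature = feat_id, rt = rt, mz = as.integer(mz))
}

#' @export
print.breath_cohort <- function(x, ...) {
  cat("<breath_cohort> ", nrow(x$table), " samples x ", length(feature_cols(x$table)),
      " features; ", length(x$truth$marker_ids), " planted markers; ",
      nlevels(x$table$batch), " batch(es)\n", sep = "")
  invisible(x)
}
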