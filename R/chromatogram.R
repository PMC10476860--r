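#' Construct a chromatogram object
#'
#' A chromatogram is the raw instrument output for one breath sample: an
#' intensity grid over retention time (rows) and nominal m/z channels
#' (columns).
#'
#' @param rt Strictly increasing numeric vector of retention times (seconds).
#' @param mz Integer vector of nominal m/z channel labels.
#' @param intensity Nonnegative numeric matrix, `length(rt)` x `length(mz)`.
#' @param sample_id Sample identifier.
#' @return A `chromatogram` object.
#' @export
chromatogram <- function(rt, mz, intensity, sample_id = "sample") {
  intensity <- as.matrix(intensity)
  if (any(diff(rt) <= 0)) abort("`rt` must be strictly increasing.")
  if (!all(is.finite(intensity)) || any(intensity < 0)) {
    abort("Intensities must be finite and >= 0.")
  }
  if (nrow(intensity) != length(rt) || ncol(intensity) != length(mz)) {
    abort("`intensity` must be length(rt) x length(mz).")
  }
  colnames(intensity) <- as.character(mz)
  structure(list(rt = as.numeric(rt), mz = as.integer(mz),
                 intensity = intensity, sample_id = sample_id),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat("<chromatogram> ", x$sample_id, ": ", length(x$rt), " RT points (",
      round(min(x$rt), 1), "-", round(max(x$rt), 1), " s) x ",
      length(x$mz), " m/z channels; TIC ", signif(sum(x$intensity), 4),
      "\n", sep = "")
  invisible(x)
}

#' @method as_tibble chromatogram
#' @export
as_tibble.chromatogram <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    rt = rep(x$rt, times = length(x$mz)),
    mz = rep(x$mz, each = length(x$rt)),
    intensity = as.vector(x$intensity)
  )
}

#' Render a sample's feature abundances as a synthetic chromatogram
#'
#' Each detected feature becomes a Gaussian retention-time peak at its assigned
#' RT (with per-sample jitter) in its m/z channel, with peak area proportional
#' to abundance, on top of a slowly decaying baseline with additive noise —
#' emulating a TD-GC-TOF-MS trace.
#'
#' @param abundances Named nonnegative vector of feature abundances (names =
#'   feature ids; `NA` treated as absent).
#' @param features Feature metadata tibble with columns `feature`, `rt`, `mz`
#'   (as produced by [generate_cohort()]).
#' @param rt_grid Retention-time grid (seconds), strictly increasing.
#' @param peak_sd Gaussian peak SD in seconds.
#' @param rt_jitter_sd Per-sample retention-time shift SD (seconds); one shift
#'   common to all peaks of the sample plus small per-peak jitter.
#' @param baseline_amp Amplitude of the exponential-decay baseline (0 = none).
#' @param noise_sd Additive intensity noise SD (0 = none).
#' @param sample_id Sample identifier.
#' @param seed Integer seed; same inputs + seed give identical output.
#' @return A [chromatogram()].
#' @export
generate_chromatogram <- function(abundances, features,
                                  rt_grid = seq(0, 1200, by = 0.5),
                                  peak_sd = 2, rt_jitter_sd = 0.5,
                                  baseline_amp = 0.05, noise_sd = 0.01,
                                  sample_id = "sample", seed = 1L) {
  stopifnot(all(c("feature", "rt", "mz") %in% names(features)))
  ab <- abundances[features$feature]
  ab[is.na(ab)] <- 0
  if (any(ab < 0)) abort("Abundances must be nonnegative.")
  withr::with_seed(seed, {
    mz_channels <- sort(unique(features$mz))
    intensity <- matrix(0, length(rt_grid), length(mz_channels))
    shift <- rnorm(1, 0, rt_jitter_sd)
    jit <- rnorm(length(ab), 0, rt_jitter_sd / 4)
    for (k in seq_along(ab)) {
      if (ab[k] == 0) next
      col <- match(features$mz[k], mz_channels)
      center <- features$rt[k] + shift + jit[k]
      ## unit-area Gaussian density times area
      intensity[, col] <- intensity[, col] +
        ab[k] * exp(-0.5 * ((rt_grid - center) / peak_sd)^2) /
          (peak_sd * sqrt(2 * pi))
    }
    if (baseline_amp > 0) {
      base <- baseline_amp * (exp(-rt_grid / (max(rt_grid) / 3)) + 0.2)
      intensity <- intensity + base
    }
    if (noise_sd > 0) {
      intensity <- intensity + matrix(rnorm(length(intensity), 0, noise_sd),
                                      nrow(intensity))
    }
    intensity[intensity < 0] <- 0
    chromatogram(rt_grid, mz_channels, intensity, sample_id = sample_id)
  })
}

#' Render every sample of a cohort as a chromatogram
#'
#' @param cohort A `breath_cohort` from [generate_cohort()].
#' @param ... Passed to [generate_chromatogram()].
#' @param seed Base seed; sample `i` uses `seed + i`.
#' @return Named list of [chromatogram()] objects.
#' @export
cohort_chromatograms <- function(cohort, ..., seed = cohort$spec$seed) {
  stopifnot(inherits(cohort, "breath_cohort"))
  feats <- feature_cols(cohort$table)
  out <- lapply(seq_len(nrow(cohort$table)), function(i) {
    ab <- unlist(cohort$table[i, feats])
    generate_chromatogram(ab, cohort$features, ...,
                          sample_id = cohort$table$sample_id[i],
                          seed = derive_seed(seed, i))
  })
  setNames(out, cohort$table$sample_id)
}
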