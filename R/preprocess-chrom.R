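#' Smooth a chromatogram with a Savitzky–Golay filter
#'
#' Polynomial least-squares smoothing applied independently to each m/z
#' channel; negative filter output is clipped at zero.
#'
#' @param chrom A [chromatogram()].
#' @param window Odd filter window length (grid points), must exceed
#'   `polyorder` and not exceed the trace length.
#' @param polyorder Polynomial order.
#' @return The smoothed [chromatogram()].
#' @export
denoise <- function(chrom, window = 9, polyorder = 3) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (window %% 2 == 0 || window <= polyorder) {
    abort("`window` must be odd and greater than `polyorder`.")
  }
  if (window > length(chrom$rt)) {
    abort("`window` must not exceed the number of RT points.")
  }
  sm <- apply(chrom$intensity, 2, signal::sgolayfilt, p = polyorder, n = window)
  sm[sm < 0] <- 0
  chromatogram(chrom$rt, chrom$mz, sm, chrom$sample_id)
}

## Asymmetric least-squares baseline for one trace: minimize
## sum_i w_i (y_i - z_i)^2 + lambda ||D2 z||^2 with w_i = p above the
## baseline and 1 - p below, iterating weights to convergence.
als_baseline <- function(y, lambda, p, max_iter = 20, tol = 1e-8) {
  m <- length(y)
  D <- Matrix::diff(Matrix::Diagonal(m), differences = 2)
  H <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(x = w)
    z <- as.numeric(Matrix::solve(W + H, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (max(abs(w_new - w)) < tol) { converged <- TRUE; break }
    w <- w_new
  }
  if (!converged) {
    warn("ALS baseline did not converge; returning last iterate.")
  }
  z
}

#' Correct baseline drift by asymmetric penalized least squares
#'
#' Estimates a slowly varying baseline per m/z channel (second-difference
#' penalty `lambda`, asymmetry `p`: points above the baseline get weight `p`,
#' points below `1 - p`) and subtracts it; the result is clipped at zero.
#'
#' @param chrom A [chromatogram()].
#' @param lambda Smoothness penalty, > 0 (larger = stiffer baseline).
#' @param p Asymmetry in (0, 1); small values let peaks sit above the baseline.
#' @param max_iter Maximum reweighting iterations (warns and keeps the best
#'   iterate on non-convergence).
#' @return The baseline-corrected [chromatogram()].
#' @export
correct_baseline <- function(chrom, lambda = 1e5, p = 0.01, max_iter = 20) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (lambda <= 0) abort("`lambda` must be > 0.")
  if (p <= 0 || p >= 1) abort("`p` must lie in (0, 1).")
  corrected <- apply(chrom$intensity, 2, function(y) {
    if (all(y == 0)) return(y)
    y - als_baseline(y, lambda, p, max_iter)
  })
  corrected[corrected < 0] <- 0
  chromatogram(chrom$rt, chrom$mz, corrected, chrom$sample_id)
}

## Trapezoidal integral of y over x.
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Pick peaks from a denoised, baseline-corrected chromatogram
#'
#' Strict local maxima per m/z channel are kept when their signal-to-noise
#' ratio (apex height over the channel's noise floor, estimated robustly from
#' first differences) reaches `snr_min` and their full width at half maximum
#' spans at least `min_width` grid points. Peak area is the trapezoidal
#' integral between the flanking local minima.
#'
#' @param chrom A [chromatogram()].
#' @param snr_min Minimum signal-to-noise ratio.
#' @param min_width Minimum width at half maximum, in grid points.
#' @param noise Optional fixed noise floor overriding the per-channel estimate.
#' @return A peak-list tibble: `sample_id`, `mz`, `rt_apex`, `area`, `height`,
#'   `snr`. May have zero rows.
#' @export
pick_peaks <- function(chrom, snr_min = 3, min_width = 3, noise = NULL) {
  stopifnot(inherits(chrom, "chromatogram"))
  out <- lapply(seq_along(chrom$mz), function(j) {
    y <- chrom$intensity[, j]
    rt <- chrom$rt
    noise_j <- noise %||% (mad(diff(y)) / sqrt(2))
    d <- diff(sign(diff(y)))
    apexes <- which(d == -2) + 1L
    if (length(apexes) == 0) return(NULL)
    minima <- c(1L, which(d == 2) + 1L, length(y))
    rows <- lapply(apexes, function(a) {
      h <- y[a]
      snr_a <- if (noise_j > 0) h / noise_j else Inf
      if (h <= 0 || snr_a < snr_min) return(NULL)
      ## full width at half maximum in grid points
      half <- h / 2
      l <- a; while (l > 1 && y[l - 1] >= half) l <- l - 1L
      r <- a; while (r < length(y) && y[r + 1] >= half) r <- r + 1L
      if ((r - l + 1L) < min_width) return(NULL)
      lb <- max(minima[minima < a])
      rb <- min(minima[minima > a])
      area <- trapz(rt[lb:rb], y[lb:rb])
      if (area <= 0) return(NULL)
      tibble(sample_id = chrom$sample_id, mz = chrom$mz[j], rt_apex = rt[a],
             area = area, height = h, snr = snr_a)
    })
    dplyr::bind_rows(rows)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(sample_id = character(), mz = integer(), rt_apex = numeric(),
                  area = numeric(), height = numeric(), snr = numeric())
  }
  res
}

#' Align peak lists across samples into a feature table
#'
#' Peaks are grouped across samples by exact nominal-m/z match and
#' single-linkage chaining on retention time: within an m/z channel, peaks
#' sorted by RT start a new feature whenever the gap to the previous peak
#' exceeds `rt_tol`. One feature per cluster; a sample without a member gets a
#' missing value, and multiple peaks of one sample in a cluster are summed.
#'
#' @param peaks A peak-list tibble covering >= 2 samples (rows from
#'   [pick_peaks()] bound together), or a list of per-sample peak tibbles.
#' @param rt_tol Retention-time linkage tolerance in seconds.
#' @param meta Optional sample metadata tibble (`sample_id`, `class`, `batch`)
#'   joined onto the result.
#' @return A feature table tibble (`sample_id`, `class`, `batch`, feature
#'   columns named `M<mz>T<rt>`); attribute `"features"` holds the consensus
#'   feature metadata tibble.
#' @export
align_features <- function(peaks, rt_tol = 2, meta = NULL) {
  if (is.list(peaks) && !is.data.frame(peaks)) peaks <- dplyr::bind_rows(peaks)
  if (length(unique(peaks$sample_id)) < 2) {
    abort("Alignment requires peaks from at least 2 samples.")
  }
  peaks <- dplyr::arrange(peaks, .data$mz, .data$rt_apex)
  peaks <- dplyr::group_by(peaks, .data$mz)
  peaks <- dplyr::mutate(peaks,
    cluster = cumsum(c(TRUE, diff(.data$rt_apex) > rt_tol)))
  peaks <- dplyr::ungroup(peaks)
  peaks <- dplyr::group_by(peaks, .data$mz, .data$cluster)
  peaks <- dplyr::mutate(peaks, rt_consensus = median(.data$rt_apex))
  peaks <- dplyr::ungroup(peaks)
  peaks$feature <- sprintf("M%03dT%04d", peaks$mz, round(peaks$rt_consensus))
  feat_meta <- dplyr::distinct(
    dplyr::select(peaks, "feature", rt = "rt_consensus", "mz"))
  feat_meta <- dplyr::arrange(feat_meta, .data$mz, .data$rt)
  wide <- tidyr::pivot_wider(
    dplyr::select(peaks, "sample_id", "feature", "area"),
    names_from = "feature", values_from = "area",
    values_fn = sum, values_fill = NA)
  wide <- wide[c("sample_id", feat_meta$feature)]
  if (!is.null(meta)) {
    wide <- dplyr::left_join(meta[intersect(names(meta), META_COLS)], wide,
                             by = "sample_id")
  } else {
    wide <- dplyr::mutate(wide,
      class = factor(NA_character_, levels = BREATH_CLASSES),
      batch = factor("B1"), .after = "sample_id")
  }
  attr(wide, "features") <- feat_meta
  wide
}
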