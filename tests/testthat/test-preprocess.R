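make_trace <- function(y, rt = seq_along(y) - 1, mz = 50L, id = "s1") {
  chromatogram(rt, mz, matrix(y, ncol = 1), sample_id = id)
}

test_that("smoothing preserves constants and attenuates impulses as the filter dictates", {
  const <- make_trace(rep(3, 101))
  expect_equal(denoise(const)$intensity, const$intensity, tolerance = 1e-10)

  # convolution oracle: an impulse comes out as the filter's central
  # coefficient times its height
  y <- rep(0, 101); y[51] <- 10
  sm <- denoise(make_trace(y), window = 9, polyorder = 3)
  coef_center <- signal::sgolay(p = 3, n = 9)[5, 5]
  expect_equal(unname(sm$intensity[51, 1]), 10 * coef_center, tolerance = 1e-8)
  expect_lt(sm$intensity[51, 1], 10)

  # a Gaussian wider than the window keeps its apex within one grid step
  g <- exp(-0.5 * ((0:100 - 50) / 10)^2)
  smg <- denoise(make_trace(g), window = 9, polyorder = 3)
  expect_lte(abs(which.max(smg$intensity[, 1]) - which.max(g)), 1)

  expect_error(denoise(make_trace(rep(1, 5)), window = 9), "exceed")
  expect_error(denoise(make_trace(rep(1, 50)), window = 4), "odd")
})

test_that("asymmetric least-squares baseline removes drift but keeps peak area", {
  zero <- make_trace(rep(0, 200))
  expect_equal(correct_baseline(zero)$intensity, zero$intensity)

  # pure linear ramp: the baseline absorbs essentially everything
  ramp <- seq(0, 10, length.out = 200)
  res <- correct_baseline(make_trace(ramp), lambda = 1e5, p = 0.01)
  expect_lt(max(abs(res$intensity)), 0.01 * diff(range(ramp)))

  # ramp plus a narrow peak of known area: area preserved within 5%
  rt <- seq(0, 199)
  peak <- 5 * exp(-0.5 * ((rt - 100) / 3)^2) / (3 * sqrt(2 * pi))
  y <- ramp + peak
  corr <- correct_baseline(make_trace(y), lambda = 1e5, p = 0.01)
  area <- sum(diff(rt) * (head(corr$intensity[, 1], -1) + corr$intensity[-1, 1]) / 2)
  expect_lt(abs(area - 5) / 5, 0.05)

  expect_error(correct_baseline(zero, lambda = -1), "lambda")
  expect_error(correct_baseline(zero, p = 1.5), "p")
})

test_that("peak picking finds well-separated peaks with correct areas and respects SNR", {
  flat <- make_trace(rep(0, 300))
  expect_equal(nrow(pick_peaks(flat)), 0)

  rt <- seq(0, 299)
  two <- exp(-0.5 * ((rt - 80) / 3)^2) / (3 * sqrt(2 * pi)) +
    exp(-0.5 * ((rt - 220) / 3)^2) / (3 * sqrt(2 * pi))
  pk <- pick_peaks(make_trace(two), noise = 0.001)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$rt_apex), c(80, 220))
  expect_true(all(abs(pk$area - 1) < 0.02))

  # constructed SNR boundary: height / noise just below vs just above
  one <- exp(-0.5 * ((rt - 150) / 3)^2)  # height 1
  below <- pick_peaks(make_trace(one), snr_min = 3, noise = 1 / 2.99)
  above <- pick_peaks(make_trace(one), snr_min = 3, noise = 1 / 3.01)
  expect_equal(nrow(below), 0)
  expect_equal(nrow(above), 1)
})

test_that("alignment clusters peaks by m/z and RT tolerance", {
  base <- tibble::tibble(sample_id = "s1",
                         mz = c(50L, 50L, 70L), rt_apex = c(100, 200, 100),
                         area = c(1, 2, 3), height = 1, snr = 10)
  other <- dplyr::mutate(base, sample_id = "s2", rt_apex = rt_apex + 0.5)
  tab <- align_features(list(base, other), rt_tol = 2)
  expect_equal(length(feature_cols(tab)), 3)
  expect_false(anyNA(feature_matrix(tab)))

  # two peaks, same m/z, separated by 2 * rt_tol: distinct features
  a <- tibble::tibble(sample_id = "s1", mz = 50L, rt_apex = 100,
                      area = 1, height = 1, snr = 10)
  b <- tibble::tibble(sample_id = "s2", mz = 50L, rt_apex = 100 + 4,
                      area = 1, height = 1, snr = 10)
  tab2 <- align_features(list(a, b), rt_tol = 2)
  expect_equal(length(feature_cols(tab2)), 2)
  expect_equal(sum(is.na(feature_matrix(tab2))), 2)

  expect_error(align_features(list(base), rt_tol = 2), "2 samples")
})

test_that("chromatogram pipeline recovers the generated features end to end", {
  spec <- cohort_spec(n_per_class = c(CRC = 2, AA = 3, NAA = 3, control = 2),
                      n_features = 20, n_markers = 3,
                      dropout = c(CRC = 1, AA = 1, NAA = 1, control = 1),
                      n_batches = 1, seed = 21)
  co <- generate_cohort(spec)
  chroms <- cohort_chromatograms(co, rt_grid = seq(0, 1150, by = 0.5),
                                 rt_jitter_sd = 0.3, baseline_amp = 0.02,
                                 noise_sd = 0.002)
  peaks <- dplyr::bind_rows(lapply(chroms, function(ch) {
    pick_peaks(correct_baseline(denoise(ch)), snr_min = 20, noise = 0.002)
  }))
  meta <- co$table[c("sample_id", "class", "batch")]
  tab <- align_features(peaks, rt_tol = 2, meta = meta)
  expect_equal(length(feature_cols(tab)), spec$n_features)
  # per-feature rank correlation of recovered areas with true abundances
  feats <- attr(tab, "features")
  truth_m <- feature_matrix(co$table)
  rec_m <- feature_matrix(tab)
  rho <- vapply(seq_len(nrow(feats)), function(j) {
    k <- which.min(abs(co$features$rt - feats$rt[j]) +
                     1000 * (co$features$mz != feats$mz[j]))
    suppressWarnings(cor(rec_m[, j], truth_m[tab$sample_id, k],
                         method = "spearman", use = "complete.obs"))
  }, numeric(1))
  expect_gt(median(rho, na.rm = TRUE), 0.9)
})

test_that("total-intensity normalization scales rows to unit sum and is invariant", {
  tab <- tibble::tibble(sample_id = c("a", "b"),
                        class = factor(c("AA", "control"),
                                       levels = c("CRC", "AA", "NAA", "control")),
                        batch = factor("B1"),
                        F1 = c(2, 10), F2 = c(2, NA), F3 = c(NA, 30))
  norm <- normalize_total(tab)
  expect_equal(unlist(norm[1, c("F1", "F2")], use.names = FALSE), c(0.5, 0.5))
  m <- feature_matrix(norm)
  expect_equal(unname(rowSums(m, na.rm = TRUE)), c(1, 1))
  expect_true(is.na(norm$F3[1]))

  # scaling one raw sample by 10x leaves its normalized row unchanged
  tab10 <- tab; tab10[1, c("F1", "F2", "F3")] <- tab[1, c("F1", "F2", "F3")] * 10
  expect_equal(normalize_total(tab10), norm)
  # idempotence
  expect_equal(normalize_total(norm), norm)

  empty <- tab; empty[1, c("F1", "F2", "F3")] <- NA_real_
  expect_error(normalize_total(empty), "a")
})

test_that("prevalence filter keeps features at >= threshold in any one class", {
  # toy table, 4 classes x 5 samples each, known detection pattern
  classes <- rep(c("CRC", "AA", "NAA", "control"), each = 5)
  n <- length(classes)
  det <- cbind(
    all = rep(1, n),                             # everywhere
    aa_only_20 = as.numeric(classes == "AA") * c(rep(0, 5), 1, rep(0, 14)),
    never = rep(0, n),
    crc_40 = as.numeric(classes == "CRC") * rep(c(1, 1, 0, 0, 0), 4)
  )
  vals <- ifelse(det == 1, 1.0, NA_real_)
  tab <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                   class = factor(classes, levels = c("CRC", "AA", "NAA", "control")),
                   batch = factor("B1")),
    tibble::as_tibble(vals))
  kept <- feature_cols(prevalence_filter(tab, 0.20))
  # brute-force counting oracle
  oracle_kept <- colnames(det)[apply(sapply(unique(classes), function(cl) {
    colMeans(det[classes == cl, , drop = FALSE])
  }), 1, max) >= 0.20]
  expect_setequal(kept, oracle_kept)
  expect_true("aa_only_20" %in% kept)   # detected in exactly 20% of AA
  expect_false("never" %in% kept)

  # idempotence and threshold monotonicity
  once <- prevalence_filter(tab, 0.20)
  expect_identical(prevalence_filter(once, 0.20), once)
  for (th in c(0.1, 0.3, 0.5, 0.9)) {
    expect_true(all(feature_cols(prevalence_filter(tab, th + 0.1)) %in%
                      feature_cols(prevalence_filter(tab, th))))
  }
})

test_that("scaling centers, imputes half-minimum, and honors the mode", {
  spec <- small_spec(seed = 31)
  tab <- generate_cohort(spec)$table |> normalize_total() |> prevalence_filter()
  unit <- scale_features(tab, "unit")
  mu <- colMeans(feature_matrix(unit))
  v <- apply(feature_matrix(unit), 2, var)
  expect_true(all(abs(mu) < 1e-12))
  expect_true(all(abs(v - 1) < 1e-12))

  # Pareto identity: post-scaling variance equals pre-scaling SD
  m_pre <- feature_matrix(tab)
  for (j in seq_len(ncol(m_pre))) {
    nas <- is.na(m_pre[, j])
    if (any(nas)) m_pre[nas, j] <- min(m_pre[!nas, j]) / 2
  }
  sd_pre <- apply(log(m_pre), 2, sd)
  pareto <- scale_features(tab, "pareto")
  v_post <- apply(feature_matrix(pareto), 2, var)
  expect_equal(unname(v_post), unname(sd_pre), tolerance = 1e-10)

  const <- tab; const$const_feat <- 2.5
  expect_warning(sc <- scale_features(const), "Zero-variance")
  expect_true(all(sc$const_feat == 0))
})
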