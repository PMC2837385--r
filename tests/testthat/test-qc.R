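toy_expr <- function(values, snr = NULL, flags = NULL, scale = "log2") {
  expr_set(values, snr = snr, flags = flags, scale = scale)
}

test_that("flag masking is strict at the 8191 boundary", {
  v <- matrix(1:6 + 0, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  fl <- matrix(0L, 2, 3)
  fl[1, 1] <- 9000L
  fl[2, 2] <- 8191L  # exactly at the boundary: retained
  e <- mask_flagged(toy_expr(v, flags = fl))
  expect_true(is.na(e$values[1, 1]))
  expect_false(is.na(e$values[2, 2]))
  expect_equal(sum(is.na(e$values)), 1)
  # all-zero flags: identity
  e0 <- mask_flagged(toy_expr(v, flags = matrix(0L, 2, 3)))
  expect_identical(e0$values, v)
  expect_error(mask_flagged(toy_expr(v)), "flag")
})

test_that("replicate resolution keeps the array with most detected probes", {
  G <- 50
  set.seed(20)
  v <- matrix(rnorm(G * 4), G, 4,
              dimnames = list(sprintf("p%02d", 1:G), paste0("a", 1:4)))
  snr <- matrix(10, G, 4)
  snr[seq_len(G - 10), 1] <- 1   # 10 probes detected
  snr[seq_len(G - 20), 2] <- 1   # 20 probes detected
  snr[seq_len(G - 30), 3] <- 1   # 30 probes detected
  ann <- annotation_table(
    data.frame(sample_id = paste0("a", 1:4),
               subject_id = c("u1", "u1", "u1", "u2"),
               x = c(0, 1, 0, 1)), c(x = "exposure"))
  res <- resolve_replicates(toy_expr(v, snr = snr), ann)
  # brute-force oracle: count S/N > 3 per array, keep the max
  counts <- stats::setNames(colSums(snr > 3), colnames(v))
  expect_equal(sample_ids(res$expr), c(names(which.max(counts[1:3])), "a4"))
  expect_equal(res$report$n_arrays_out, 2)
  expect_equal(res$report$replicate_resolutions$kept, "a3")
  # single array per subject untouched
  single <- resolve_replicates(toy_expr(v[, 4, drop = FALSE],
                                        snr = snr[, 4, drop = FALSE]),
                               ann[4, ])
  expect_equal(ncol(single$expr$values), 1)
  # ties broken by input order
  snr_tie <- matrix(10, G, 4)
  res_tie <- resolve_replicates(toy_expr(v, snr = snr_tie), ann)
  expect_equal(res_tie$report$replicate_resolutions$kept, "a1")
})

test_that("array filter removes arrays under 40% detection, boundary kept", {
  G <- 100
  v <- matrix(1, G, 3, dimnames = list(sprintf("p%03d", 1:G), c("lo", "at", "hi")))
  snr <- matrix(10, G, 3)
  snr[1:61, 1] <- 2   # 39% at or above threshold
  snr[1:60, 2] <- 2   # exactly 40%
  res <- filter_arrays(toy_expr(v, snr = snr))
  expect_equal(sample_ids(res$expr), c("at", "hi"))
  expect_equal(res$report$excluded_arrays$sample_id, "lo")
  # fully detected arrays: identity
  res2 <- filter_arrays(toy_expr(v, snr = matrix(10, G, 3)))
  expect_equal(ncol(res2$expr$values), 3)
})

test_that("probe filter drops probes detected in under half the samples", {
  n <- 100
  v <- matrix(1, 3, n, dimnames = list(c("p49", "p50", "pall"),
                                       sprintf("S%03d", 1:n)))
  snr <- matrix(10, 3, n)
  snr[1, 1:51] <- 3    # S/N > 3 in 49% only (threshold is strict)
  snr[2, 1:50] <- 1    # exactly 50%: kept
  res <- filter_probes(toy_expr(v, snr = snr))
  expect_equal(probe_ids(res$expr), c("p50", "pall"))
  expect_equal(res$report$excluded_probes$probe_id, "p49")
  # 5 of 10 samples detected is kept
  v10 <- matrix(1, 1, 10, dimnames = list("q", sprintf("T%02d", 1:10)))
  s10 <- matrix(c(rep(10, 5), rep(1, 5)), 1)
  expect_equal(nrow(filter_probes(toy_expr(v10, snr = s10))$expr$values), 1)
})

test_that("quantile normalization averages order statistics", {
  v <- cbind(a1 = c(0, 2, 4), a2 = c(2, 4, 6))
  rownames(v) <- c("p1", "p2", "p3")
  e <- quantile_normalize(toy_expr(v))
  expect_equal(unname(e$values), cbind(c(1, 3, 5), c(1, 3, 5)))
  # idempotent once distributions match
  e2 <- quantile_normalize(e)
  expect_equal(e2$values, e$values)
  # raw-scale input is log2-transformed first
  eraw <- quantile_normalize(toy_expr(2^v, scale = "raw"))
  expect_equal(eraw$values, e$values)
  expect_equal(eraw$scale, "log2")
})

test_that("quantile normalization equalizes distributions and keeps the grand mean", {
  set.seed(21)
  v <- matrix(rnorm(200 * 6, sd = 2) + rep(rnorm(6, sd = 1), each = 200), 200, 6,
              dimnames = list(sprintf("p%03d", 1:200), sprintf("S%d", 1:6)))
  e <- quantile_normalize(toy_expr(v))
  sorted <- apply(e$values, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1])
  expect_equal(mean(e$values), mean(v), tolerance = 1e-10)
})

test_that("missing-aware quantile normalization matches a rank-interpolation oracle", {
  set.seed(22)
  v <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(sprintf("p%02d", 1:60), sprintf("S%d", 1:4)))
  v[cbind(c(3, 17, 44), c(1, 2, 4))] <- NA
  e <- quantile_normalize(toy_expr(v))
  # missingness preserved
  expect_identical(is.na(e$values), is.na(v))
  # oracle: build the reference as the mean of per-array quantiles on a
  # common grid, then map each observed value through its rank
  grid <- seq(0, 1, length.out = nrow(v))
  ref <- rowMeans(sapply(1:4, function(j)
    stats::quantile(v[, j], grid, na.rm = TRUE, names = FALSE, type = 7)))
  for (j in 1:4) {
    obs <- which(!is.na(v[, j]))
    pr <- (rank(v[obs, j]) - 1) / (length(obs) - 1)
    expect_equal(unname(e$values[obs, j]),
                 stats::approx(grid, ref, xout = pr)$y, tolerance = 1e-8)
  }
  # an all-missing array is an error
  v[, 2] <- NA
  expect_error(quantile_normalize(toy_expr(v)), "missing")
})

test_that("kNN imputation: identity, exact twins, untouched observations", {
  set.seed(23)
  v <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(sprintf("p%02d", 1:30), sprintf("S%d", 1:8)))
  e0 <- knn_impute(toy_expr(v))
  expect_identical(e0$values, v)
  # duplicate a probe, mask one of its cells: k = 1 recovers the twin exactly
  v2 <- rbind(v, twin = v[5, ])
  v2["twin", 3] <- NA
  e1 <- knn_impute(toy_expr(v2), k = 1)
  expect_equal(e1$values["twin", 3], v[5, 3])
  # default k is 10 and observed cells are never altered
  v3 <- v
  v3[2, 4] <- NA
  expect_identical(formals(knn_impute)$k, 10)
  e3 <- knn_impute(toy_expr(v3))
  expect_false(anyNA(e3$values))
  expect_identical(e3$values[-2, ], v[-2, ])
  expect_identical(e3$values[2, -4], v[2, -4])
})

test_that("kNN imputation approximates masked values and weights by distance", {
  set.seed(24)
  base <- rnorm(12)
  # probes are noisy copies of a shared profile; neighbours are informative
  v <- t(sapply(1:40, function(i) base + rnorm(12, sd = 0.1)))
  dimnames(v) <- list(sprintf("p%02d", 1:40), sprintf("S%02d", 1:12))
  truth <- v[7, 5]
  v[7, 5] <- NA
  e <- knn_impute(toy_expr(v), k = 10)
  expect_equal(e$values[7, 5], truth, tolerance = 0.25)
  # no co-observed neighbours: falls back to the probe mean, reported
  v4 <- matrix(c(1, 2, NA, NA, NA, 6), 2, 3, byrow = TRUE,
               dimnames = list(c("full", "lonely"), c("S1", "S2", "S3")))
  v4["full", 3] <- NA
  e4 <- knn_impute(toy_expr(v4), k = 2)
  expect_equal(e4$values["lonely", 1], 6)
  expect_true(length(attr(e4, "fallback")) >= 1)
})

test_that("the full cascade reconciles counts and respects stage order", {
  cfg <- cohort_config(n_samples = 50, n_probes = 200, n_replicate_pairs = 4,
                       frac_undetected = 0.3, flag_fail_fraction = 0.02,
                       seed = 25)
  sim <- simulate_cohort(cfg)
  qc <- qc_preprocess(sim$expr, sim$annotations)
  rep <- qc$report
  expect_equal(rep$n_arrays_in, 54)
  expect_equal(rep$n_arrays_out, rep$n_arrays_in - nrow(rep$excluded_arrays))
  expect_equal(rep$n_probes_out, rep$n_probes_in - nrow(rep$excluded_probes))
  expect_equal(ncol(qc$expr$values), rep$n_arrays_out)
  expect_equal(nrow(qc$expr$values), rep$n_probes_out)
  expect_false(anyNA(qc$expr$values))
  expect_equal(qc$expr$scale, "log2")
  # replicates resolved: one array per subject remains
  expect_false(anyDuplicated(qc$annotations$subject_id) > 0)
})
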