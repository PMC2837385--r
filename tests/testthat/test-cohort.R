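test_that("configuration invariants are enforced", {
  expect_error(cohort_config(sd_resid = -1), "non-negative")
  expect_error(cohort_config(covariate_prevalences = c(smoking = 1.2)), "prevalences")
  expect_error(cohort_config(n_samples = 10, n_lots = 20) |>
                 generate_annotations(), "n_lots")
  expect_error(cohort_config(effect_fraction = c(nosuch = 0.1)), "unknown")
})

test_that("covariate prevalences are honoured, including degenerate ones", {
  cfg <- cohort_config(n_samples = 286, n_probes = 10,
                       covariate_prevalences = c(smoking = 0, fasting = 28 / 286,
                                                 ht = 0.3),
                       effect_fraction = c(smoking = 0, fasting = 0, ht = 0),
                       seed = 1)
  ann <- generate_annotations(cfg)
  expect_equal(nrow(ann), 286)
  # zero prevalence: every sample is a non-smoker
  expect_true(all(ann$smoking == 0))
  # realized counts within the binomial 99% interval around the target
  for (v in c("fasting", "ht")) {
    pr <- cfg$covariate_prevalences[[v]]
    ci <- stats::qbinom(c(0.005, 0.995), 286, pr)
    expect_gte(sum(ann[[v]]), ci[1])
    expect_lte(sum(ann[[v]]), ci[2])
  }
  # fasting expectation matches the cohort it emulates (28 of 286)
  expect_equal(286 * cfg$covariate_prevalences[["fasting"]], 28)
})

test_that("technical structure: crossed balanced batches, freezing within 3 days", {
  cfg <- cohort_config(n_samples = 120, n_probes = 10, seed = 4)
  ann <- generate_annotations(cfg)
  expect_equal(nlevels(ann$lot), cfg$n_lots)
  expect_equal(nlevels(ann$extraction_date), cfg$n_extraction_dates)
  expect_true(all(ann$freeze_days >= 0 & ann$freeze_days <= 3))
  # crossed, not nested: some lot appears on several extraction dates
  expect_gt(max(rowSums(table(ann$lot, ann$extraction_date) > 0)), 1)
  roles <- variable_roles(ann)
  expect_setequal(names(roles)[roles == "technical-random"],
                  c("lot", "extraction_date"))
})

test_that("null generator yields baseline plus residual noise and empty truth", {
  cfg <- cohort_config(n_samples = 30, n_probes = 50, sd_lot = 0,
                       sd_extraction = 0, beta_freeze = 0,
                       effect_fraction = c(smoking = 0, fasting = 0),
                       sd_resid = 0.3, n_replicate_pairs = 0, seed = 5)
  ann <- generate_annotations(cfg)
  gen <- generate_expression(ann, cfg)
  expect_true(all(lengths(gen$truth$affected_probes) == 0))
  expect_equal(gen$truth$variance_fraction_technical, 0)
  expect_equal(gen$truth$variance_fraction_biological, 0)
  lv <- log2(gen$expr$values)
  # row-centered values are iid residuals: pooled SD close to sd_resid
  expect_equal(stats::sd(lv - rowMeans(lv)), 0.3, tolerance = 0.02)
})

test_that("affected probe counts are deterministic in the configured fraction", {
  cfg <- cohort_config(n_samples = 40, n_probes = 1000,
                       effect_fraction = c(smoking = 0.1, fasting = 0.25),
                       n_replicate_pairs = 0, seed = 6)
  ann <- generate_annotations(cfg)
  gen <- generate_expression(ann, cfg)
  expect_length(gen$truth$affected_probes$smoking, 100)
  expect_length(gen$truth$affected_probes$fasting, 250)
  expect_true(all(gen$truth$affected_probes$smoking %in% probe_ids(gen$expr)))
})

test_that("realized variance fractions track the calibrated design at G = 2000", {
  cfg <- cohort_config(n_samples = 150, n_probes = 2000,
                       n_replicate_pairs = 0, seed = 7)
  cfg <- calibrate_variance_fractions(cfg, technical = 0.465, biological = 0.081)
  gen <- generate_expression(generate_annotations(cfg), cfg)
  expect_lt(abs(gen$truth$variance_fraction_technical - 0.465), 0.03)
  expect_lt(abs(gen$truth$variance_fraction_biological - 0.081), 0.03)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- cohort_config(n_samples = 40, n_probes = 80, n_replicate_pairs = 3,
                       seed = 8)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$expr$snr, b$expr$snr)
  expect_identical(a$expr$flags, b$expr$flags)
  expect_identical(as.data.frame(a$annotations), as.data.frame(b$annotations))
})

test_that("detection layer: zero failure fraction leaves everything detected", {
  cfg <- cohort_config(n_samples = 20, n_probes = 100, frac_undetected = 0,
                       flag_fail_fraction = 0, n_replicate_pairs = 0, seed = 9)
  gen <- generate_expression(generate_annotations(cfg), cfg)
  expr <- simulate_detection(gen$expr, cfg)
  expect_true(all(expr$flags <= 8191))
  expect_true(all(expr$snr > 3))
})

test_that("detection layer drives the probe filter at the configured rate", {
  cfg <- cohort_config(n_samples = 40, n_probes = 400, frac_undetected = 0.3,
                       flag_fail_fraction = 0, n_replicate_pairs = 0, seed = 10)
  gen <- generate_expression(generate_annotations(cfg), cfg)
  expr <- simulate_detection(gen$expr, cfg)
  # roughly the configured fraction of cells sits below the S/N threshold
  expect_equal(mean(expr$snr < 3), 0.3, tolerance = 0.05)
})

test_that("replicate spiking appends arrays and records pairs", {
  cfg <- cohort_config(n_samples = 289, n_probes = 30, n_replicate_pairs = 0,
                       seed = 11)
  gen <- generate_expression(generate_annotations(cfg), cfg)
  expr <- simulate_detection(gen$expr, cfg)
  ann <- generate_annotations(cfg)  # same seed-derived table shape
  ident <- spike_replicates(expr, ann, n_pairs = 0)
  expect_identical(ident$expr$values, expr$values)
  rep <- spike_replicates(expr, ann, n_pairs = 15, seed = 12)
  expect_equal(ncol(rep$expr$values), 304)  # 289 subjects + 15 replicates
  expect_equal(nrow(rep$replicate_pairs), 15)
  expect_equal(nrow(rep$annotations), 304)
  # replicate arrays share the subject identity of their originals
  m <- match(rep$replicate_pairs$sample_2, rep$annotations$sample_id)
  m0 <- match(rep$replicate_pairs$sample_1, rep$annotations$sample_id)
  expect_identical(rep$annotations$subject_id[m], rep$annotations$subject_id[m0])
  expect_error(spike_replicates(expr, ann, n_pairs = 500), "exceeds")
})

test_that("cohort truth validates its fractions", {
  expect_error(cohort_truth(list(), 0.7, 0.6, data.frame()), "jointly exceed")
  tr <- cohort_truth(list(), 0.4, 0.1, data.frame())
  expect_s3_class(tr, "cohort_truth")
})
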