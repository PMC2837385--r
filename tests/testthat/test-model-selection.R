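test_that("the candidate pool mirrors the standard cohort layout", {
  ann <- cohort_annotation(40, seed = 70)
  pool <- candidate_pool(ann, screen = passed_screen())
  expect_length(c(pool$fixed_candidates, pool$random_candidates), 8)
  expect_setequal(pool$random_candidates, c("lot", "extraction_date"))
  expect_true("ht:med" %in% pool$fixed_candidates)
  expect_equal(pool$hierarchy[["ht:med"]], c("ht", "med"))
  # with the full six-covariate cohort the pool holds 10 variables
  cfg <- cohort_config(n_samples = 30, n_probes = 5, seed = 71)
  ann10 <- generate_annotations(cfg)
  pool10 <- candidate_pool(ann10, screen = passed_screen())
  expect_length(c(pool10$fixed_candidates, pool10$random_candidates), 10)
})

test_that("profiled-ML mixed fits agree with an independent lme4 fit", {
  skip_if_not_installed("lme4")
  set.seed(72)
  ann <- cohort_annotation(60, n_lots = 4, n_dates = 6, seed = 72)
  df <- as.data.frame(ann)
  lot_eff <- rnorm(4, 0, 0.8)
  xd_eff <- rnorm(6, 0, 0.5)
  cases <- list(
    list(fixed = c("smoking", "freeze_days"),
         random = c("lot", "extraction_date")),
    list(fixed = "smoking", random = "lot"),
    list(fixed = character(), random = "extraction_date"))
  for (cs in cases) {
    y <- 2 + 0.6 * df$smoking + lot_eff[df$lot] + xd_eff[df$extraction_date] +
      rnorm(60, 0, 0.5)
    f <- fit_mixed_bic(y, cs$fixed, cs$random, ann)
    dat <- df
    dat$.y <- y
    fml <- stats::as.formula(paste(
      ".y ~", paste(c(if (length(cs$fixed)) cs$fixed else "1",
                      sprintf("(1 | %s)", cs$random)), collapse = " + ")))
    m <- suppressMessages(lme4::lmer(fml, data = dat, REML = FALSE))
    expect_equal(f$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-5)
    expect_equal(f$bic, stats::BIC(m), tolerance = 1e-4)
    expect_equal(f$n_params, attr(stats::logLik(m), "df"))
  }
})

test_that("balanced one-way ML variance components match a direct likelihood oracle", {
  set.seed(73)
  a <- 4; m <- 6; n <- a * m
  g <- factor(rep(1:a, each = m))
  y <- rnorm(a, 0, 1.2)[g] + rnorm(n, 0, 0.7)
  ann <- annotation_table(data.frame(sample_id = sprintf("S%02d", 1:n), g = g),
                          c(g = "technical-random"))
  f <- fit_mixed_bic(y, character(), "g", ann)
  # oracle: maximize the exact multivariate normal likelihood numerically
  Z <- stats::model.matrix(~ g - 1)
  negll <- function(par) {
    V <- exp(par[1]) * tcrossprod(Z) + exp(par[2]) * diag(n)
    mu <- rep(sum(solve(V, y)) / sum(solve(V, rep(1, n))), n)
    0.5 * (determinant(V)$modulus + crossprod(y - mu, solve(V, y - mu)) +
             n * log(2 * pi))
  }
  opt <- stats::optim(c(0, 0), negll, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  expect_equal(f$loglik, -as.numeric(opt$value), tolerance = 1e-5)
})

test_that("degenerate random components collapse to zero variance", {
  set.seed(74)
  n <- 30
  g <- factor(rep(1:3, each = 10))
  ann <- annotation_table(data.frame(sample_id = sprintf("S%02d", 1:n), g = g),
                          c(g = "technical-random"))
  y <- rnorm(n)  # identical group means, pure within-noise
  f <- fit_mixed_bic(y, character(), "g", ann)
  expect_equal(unname(f$gamma["g"]), 0)
  # and the likelihood equals the plain intercept-only ML fit
  rss <- sum((y - mean(y))^2)
  expect_equal(f$loglik, -n / 2 * (log(2 * pi * rss / n) + 1), tolerance = 1e-6)
})

test_that("fixed-effects-only BIC matches the hand formula on a 6-sample toy", {
  y <- c(1.2, 0.8, 2.1, 1.9, 3.2, 2.7)
  ann <- annotation_table(data.frame(sample_id = paste0("s", 1:6),
                                     x = c(0, 0, 1, 1, 2, 2)),
                          c(x = "biological"))
  f <- fit_mixed_bic(y, "x", character(), ann)
  X <- cbind(1, ann$x)
  rss <- sum(stats::lm.fit(X, y)$residuals^2)
  ll <- -6 / 2 * (log(2 * pi * rss / 6) + 1)
  expect_equal(f$loglik, ll)
  expect_equal(f$n_params, 3)  # two coefficients + residual variance
  expect_equal(f$bic, -2 * ll + 3 * log(6))
})

test_that("forward-backward search equals exhaustive best-BIC search", {
  set.seed(75)
  n <- 60
  for (rep in 1:6) {
    df <- data.frame(sample_id = sprintf("S%02d", 1:n),
                     a = rbinom(n, 1, 0.5), b = rnorm(n),
                     g = factor(sample(rep_len(1:4, n))))
    ann <- annotation_table(df, c(a = "exposure", b = "biological",
                                  g = "technical-random"))
    pool <- structure(list(fixed_candidates = c("a", "b"),
                           random_candidates = "g",
                           biological = c("a", "b"), hierarchy = list()),
                      class = "candidate_pool")
    y <- 0.9 * df$a * (rep %% 2) + 0.7 * df$b * (rep %% 3 == 0) +
      rnorm(4, 0, 0.5 * (rep > 3))[df$g] + rnorm(n, 0, 0.6)
    got <- forward_backward_select(y, pool, ann)
    oracle <- exhaustive_best_bic(y, pool, ann)
    expect_setequal(c(got$selected_fixed, got$selected_random),
                    oracle$selected)
    expect_equal(got$bic, oracle$bic, tolerance = 1e-8)
  }
})

test_that("selection respects the interaction hierarchy", {
  set.seed(76)
  n <- 120
  df <- data.frame(sample_id = sprintf("S%03d", 1:n),
                   ht = rbinom(n, 1, 0.5), med = rbinom(n, 1, 0.5))
  ann <- annotation_table(df, c(ht = "exposure", med = "exposure",
                                "ht:med" = "interaction"))
  pool <- candidate_pool(ann, screen = passed_screen(character()))
  # strong pure interaction: the model must still contain both parents
  y <- 1.5 * df$ht * df$med + rnorm(n, 0, 0.5)
  m <- forward_backward_select(y, pool, ann)
  if ("ht:med" %in% m$selected_fixed)
    expect_true(all(c("ht", "med") %in% m$selected_fixed))
  expect_true("ht:med" %in% m$selected_fixed)
})

test_that("the selected model never loses to intercept-only or single-variable models", {
  set.seed(77)
  ann <- cohort_annotation(50, seed = 77)
  pool <- candidate_pool(ann, screen = passed_screen())
  y <- 0.8 * ann$smoking + rnorm(50, 0, 0.7)
  m <- forward_backward_select(y, pool, ann)
  cand <- c(pool$fixed_candidates, pool$random_candidates)
  b0 <- fit_mixed_bic(y, character(), character(), ann)$bic
  expect_lte(m$bic, b0)
  for (v in setdiff(cand, "ht:med")) {
    b1 <- fit_mixed_bic(y, setdiff(v, pool$random_candidates),
                        intersect(v, pool$random_candidates), ann)$bic
    expect_lte(m$bic, b1 + 1e-9)
  }
  # deterministic: identical rerun
  m2 <- forward_backward_select(y, pool, ann)
  expect_identical(m$selected_fixed, m2$selected_fixed)
  expect_identical(m$bic, m2$bic)
})

test_that("association matrix summarizes selections consistently", {
  set.seed(78)
  cfg <- cohort_config(n_samples = 60, n_probes = 30, n_replicate_pairs = 0,
                       frac_undetected = 0, flag_fail_fraction = 0,
                       effect_fraction = c(smoking = 0.5),
                       effect_size = c(smoking = 1.5), sd_resid = 0.5,
                       seed = 79)
  sim <- simulate_cohort(cfg)
  e <- quantile_normalize(sim$expr)
  pool <- candidate_pool(sim$annotations, screen = passed_screen())
  assoc <- build_association_matrix(e, pool, sim$annotations)
  A <- assoc$matrix
  expect_equal(unname(assoc$summary$per_variable_counts), unname(colSums(A)))
  expect_equal(assoc$summary$mean_selected, mean(rowSums(A)))
  expect_equal(assoc$summary$n_probes, 30)
  # strong planted smoking effects are recovered
  affected <- sim$truth$affected_probes$smoking
  expect_gte(mean(A[affected, "smoking"]), 0.9)
})

test_that("uniquely associated probes honour the array-lot exemption", {
  vars <- c("smoking", "fasting", "ht", "freeze_days", "lot", "extraction_date")
  A <- rbind(
    p1 = c(1, 0, 0, 0, 1, 0),  # smoking + lot -> uniquely smoking
    p2 = c(1, 1, 0, 0, 0, 0),  # smoking + fasting -> not unique
    p3 = c(0, 1, 0, 0, 0, 0),  # fasting alone -> uniquely fasting
    p4 = c(1, 0, 0, 1, 1, 0),  # smoking + freeze_days -> not unique
    p5 = c(0, 0, 0, 0, 1, 0))  # lot only -> unique to nothing
  colnames(A) <- vars
  assoc <- structure(list(matrix = A,
                          pool = list(biological = c("smoking", "fasting", "ht"))),
                     class = "association_result")
  u <- unique_biological(assoc)
  expect_equal(u$smoking, "p1")
  expect_equal(u$fasting, "p3")
  expect_equal(u$ht, character())
  expect_error(unique_biological(assoc, variables = "nosuch"), "unknown")
  # brute-force oracle on random association matrices
  set.seed(80)
  for (r in 1:20) {
    M <- matrix(rbinom(6 * 6, 1, 0.4), 6, 6,
                dimnames = list(paste0("q", 1:6), vars))
    as2 <- structure(list(matrix = M,
                          pool = list(biological = c("smoking", "fasting", "ht"))),
                     class = "association_result")
    got <- unique_biological(as2)
    for (v in c("smoking", "fasting", "ht")) {
      oracle <- rownames(M)[apply(M, 1, function(row) {
        sel <- vars[row == 1]
        setequal(setdiff(sel, "lot"), v)
      })]
      expect_setequal(got[[v]], oracle)
    }
  }
})
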