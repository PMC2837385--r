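# Shared fixtures, built in code under fixed seeds.

# A small named probe x sample matrix of pure noise.
noise_matrix <- function(G, n, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(stats::rnorm(G * n, sd = sd), G, n,
         dimnames = list(sprintf("p%04d", seq_len(G)),
                         sprintf("S%03d", seq_len(n))))
}

# Annotation with one binary covariate.
binary_annotation <- function(n, p = 0.5, seed = 2, name = "grp",
                              role = "exposure") {
  set.seed(seed)
  df <- data.frame(sample_id = sprintf("S%03d", seq_len(n)))
  df[[name]] <- stats::rbinom(n, 1, p)
  annotation_table(df, stats::setNames(role, name))
}

# Annotation with two crossed batch factors, a degradation covariate and
# binary biological covariates; mirrors the standard cohort layout.
cohort_annotation <- function(n, n_lots = 4, n_dates = 5, seed = 3) {
  set.seed(seed)
  df <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    lot = factor(sprintf("lot%02d", sample(rep_len(seq_len(n_lots), n)))),
    extraction_date = factor(sprintf("xd%02d",
                                     sample(rep_len(seq_len(n_dates), n)))),
    freeze_days = stats::runif(n, 0, 3),
    smoking = stats::rbinom(n, 1, 0.25),
    fasting = stats::rbinom(n, 1, 0.1),
    ht = stats::rbinom(n, 1, 0.3),
    med = stats::rbinom(n, 1, 0.5))
  annotation_table(df, c(lot = "technical-random",
                         extraction_date = "technical-random",
                         freeze_days = "technical-fixed",
                         smoking = "exposure", fasting = "biological",
                         ht = "exposure", med = "exposure",
                         "ht:med" = "interaction"))
}

# A screen_result stand-in admitting the standard technical survivors.
passed_screen <- function(passed = c(lot = "random",
                                     extraction_date = "random",
                                     freeze_days = "fixed")) {
  structure(list(passed = passed), class = "screen_result")
}

# Independent brute-force BH step-up, straight from the definition:
# q_(i) = min_{j >= i} min(1, n p_(j) / j), by explicit backward loop.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(n)
  qs[n] <- min(1, ps[n])
  if (n > 1) for (i in (n - 1):1) qs[i] <- min(qs[i + 1], min(1, n * ps[i] / i))
  q <- numeric(n)
  q[o] <- qs
  q
}

# Independent enumeration oracle for the single-probe global test with a
# binary outcome at tiny n: enumerate the distinct label assignments via
# combinations; each corresponds to k!(n-k)! raw permutations, so
# proportions over assignments equal proportions over all n! permutations.
enumeration_oracle_p <- function(x, y) {
  n <- length(y)
  xs <- (x - mean(x)) / stats::sd(x)
  q_obs <- sum(xs * (y - mean(y)))^2
  combs <- utils::combn(n, sum(y == 1))
  qs <- apply(combs, 2, function(idx) {
    yp <- rep(0, n)
    yp[idx] <- 1
    sum(xs * (yp - mean(yp)))^2
  })
  mean(qs >= q_obs - 1e-12)
}

# Brute-force utility maximization over all |z| cutpoints (independent of
# the packaged scan): returns the selected count and utility.
brute_force_core <- function(z, q, w_tp = 2, w_fp = 1) {
  o <- order(-abs(z), seq_along(z))
  fdr <- cummax(q[o])
  best_u <- 0; best_k <- 0L
  for (k in seq_along(o)) {
    u <- w_tp * k * (1 - fdr[k]) - w_fp * k * fdr[k]
    if (u > best_u) { best_u <- u; best_k <- k }
  }
  list(k = best_k, u = best_u)
}

# Exhaustive best-BIC model search over all subsets of a candidate pool
# (respecting interaction hierarchy), scoring with fit_mixed_bic.
exhaustive_best_bic <- function(y, pool, annotations) {
  cand <- c(pool$fixed_candidates, pool$random_candidates)
  is_random <- cand %in% pool$random_candidates
  best <- NULL
  for (mask in 0:(2^length(cand) - 1)) {
    sel <- cand[bitwAnd(mask, 2^(seq_along(cand) - 1)) > 0]
    ok <- all(vapply(names(pool$hierarchy), function(int)
      !(int %in% sel) || all(pool$hierarchy[[int]] %in% sel), TRUE))
    if (!ok) next
    f <- fit_mixed_bic(y, fixed = sel[!is_random[match(sel, cand)]],
                       random = sel[is_random[match(sel, cand)]],
                       annotations = annotations)
    if (is.null(best) || f$bic < best$bic)
      best <- list(selected = sel, bic = f$bic)
  }
  best
}
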