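#' Extra-sum-of-squares statistic for whole-matrix association
#'
#' Compares two nested per-probe ordinary least squares models across all
#' probes at once:
#' \deqn{T = \frac{\sum_g (RSS_g^{reduced} - RSS_g^{full})}{\sum_g RSS_g^{full}}}
#' The ratio of summed extra sum of squares to summed full residual sum of
#' squares is invariant to probe duplication and to common rescaling of all
#' probes, and is calibrated by permutation in [permutation_test()].
#'
#' @param expr an [expr_set()] (log2, complete) or a numeric probe x sample
#'   matrix.
#' @param annotations an [annotation_table()].
#' @param full_terms,reduced_terms character vectors of term labels;
#'   `reduced_terms` must be a subset of `full_terms` (the reduced model
#'   may be empty = intercept only). Categorical variables are
#'   dummy-encoded against a first-level reference.
#' @return The non-negative statistic `T`, with the design column names of
#'   both models attached as attributes.
#' @export
extra_ss_statistic <- function(expr, annotations, full_terms,
                               reduced_terms = character()) {
  Y <- expr_values(expr)
  ann <- if (inherits(expr, "expr_set")) align_annotations(annotations, expr)
         else annotations
  if (!all(reduced_terms %in% full_terms))
    stop("reduced_terms must be a subset of full_terms")
  Xf <- build_design(ann, full_terms)
  Xr <- build_design(ann, reduced_terms)
  rss <- fit_rss(Y, Xf, Xr)
  stat <- (sum(rss$reduced) - sum(rss$full)) / sum(rss$full)
  attr(stat, "full_design") <- colnames(Xf)
  attr(stat, "reduced_design") <- colnames(Xr)
  stat
}

expr_values <- function(expr) {
  Y <- if (inherits(expr, "expr_set")) expr$values else as.matrix(expr)
  if (anyNA(Y)) stop("expression matrix has missing values; impute first")
  Y
}

# Per-probe residual sums of squares under two designs. Y is probes x
# samples; returns per-probe vectors.
fit_rss <- function(Y, Xf, Xr) {
  tY <- t(Y)
  rf <- qr.resid(qr(Xf), tY)
  rr <- qr.resid(qr(Xr), tY)
  list(full = colSums(rf^2), reduced = colSums(rr^2))
}

#' Permutation test for the extra-sum-of-squares statistic
#'
#' Calibrates [extra_ss_statistic()] by the Freedman-Lane scheme: the
#' reduced-model residuals of every probe are permuted over samples (one
#' common permutation per iteration, preserving the probe correlation
#' structure), the reduced-model fit is added back, and the statistic is
#' recomputed. When the reduced model is intercept-only this reduces to a
#' plain sample-label permutation. The p-value uses the add-one rule
#' `p = (1 + #\{T* >= T\}) / (n_perm + 1)`.
#'
#' @inheritParams extra_ss_statistic
#' @param n_perm number of permutations (default 10000, enough to resolve
#'   p-values on the 1e-4 scale).
#' @param seed integer seed for the permutation stream.
#' @return An `ancova_result`: list with `statistic`, `perm_p`, `n_perm`,
#'   `tested_terms` (full minus reduced), `adjusted_terms` (reduced),
#'   `seed`.
#' @export
permutation_test <- function(expr, annotations, full_terms,
                             reduced_terms = character(),
                             n_perm = 10000, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  Y <- expr_values(expr)
  ann <- if (inherits(expr, "expr_set")) align_annotations(annotations, expr)
         else annotations
  if (!all(reduced_terms %in% full_terms))
    stop("reduced_terms must be a subset of full_terms")
  Xf <- build_design(ann, full_terms)
  Xr <- build_design(ann, reduced_terms)
  qf <- qr(Xf); qr_r <- qr(Xr)
  tY <- t(Y)
  fit_r <- qr.fitted(qr_r, tY)
  res_r <- tY - fit_r
  rss_f <- colSums(qr.resid(qf, tY)^2)
  rss_r <- colSums(res_r^2)
  t_obs <- (sum(rss_r) - sum(rss_f)) / sum(rss_f)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(tY)
  t_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    ystar <- fit_r + res_r[sample.int(n), , drop = FALSE]
    rss_fs <- colSums(qr.resid(qf, ystar)^2)
    rss_rs <- colSums(qr.resid(qr_r, ystar)^2)
    t_perm[b] <- (sum(rss_rs) - sum(rss_fs)) / sum(rss_fs)
  }
  structure(list(statistic = as.numeric(t_obs),
                 perm_p = (1 + sum(t_perm >= t_obs)) / (n_perm + 1),
                 n_perm = n_perm,
                 tested_terms = setdiff(full_terms, reduced_terms),
                 adjusted_terms = reduced_terms,
                 seed = seed),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("global ANCOVA: T = %.4g, permuted p = %.4g (%d permutations)\n",
              x$statistic, x$perm_p, x$n_perm))
  cat("  tested:", paste(x$tested_terms, collapse = ", "), "\n")
  if (length(x$adjusted_terms))
    cat("  adjusted for:", paste(x$adjusted_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Screen candidate technical variables by global ANCOVA
#'
#' Runs, for each candidate, a univariate test (the candidate against the
#' intercept-only model) and a multivariate drop-one test (the full joint
#' technical model against the model without the candidate). Candidates
#' whose multivariate permuted p-value falls below `alpha` are returned,
#' labelled with the role they will play downstream: `random` for
#' categorical batch factors tagged `technical-random`, `fixed` otherwise.
#'
#' @param expr an [expr_set()] (log2, complete).
#' @param annotations an [annotation_table()].
#' @param candidate_technical character vector of candidate variable names.
#' @param alpha multivariate screening level (default 0.001).
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @return A `screen_result`: list with `table` (data.frame: variable,
#'   univariate_p, multivariate_p, role, passed), `passed` (named roles of
#'   surviving variables), and the per-variable `ancova_result`s.
#' @export
screen_variables <- function(expr, annotations, candidate_technical,
                             alpha = 0.001, n_perm = 1000, seed = NULL) {
  if (length(candidate_technical) == 0) stop("empty candidate list")
  roles <- variable_roles(annotations)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2 * length(candidate_technical))
  uni <- multi <- vector("list", length(candidate_technical))
  for (i in seq_along(candidate_technical)) {
    v <- candidate_technical[i]
    uni[[i]] <- permutation_test(expr, annotations, full_terms = v,
                                 n_perm = n_perm, seed = seeds[2 * i - 1])
    multi[[i]] <- permutation_test(expr, annotations,
                                   full_terms = candidate_technical,
                                   reduced_terms = setdiff(candidate_technical, v),
                                   n_perm = n_perm, seed = seeds[2 * i])
  }
  role_of <- function(v) {
    ann <- as.data.frame(annotations)
    if (identical(roles[[v]], "technical-random") &&
        (is.factor(ann[[v]]) || is.character(ann[[v]]))) "random" else "fixed"
  }
  tab <- data.frame(variable = candidate_technical,
                    univariate_p = vapply(uni, `[[`, 0, "perm_p"),
                    multivariate_p = vapply(multi, `[[`, 0, "perm_p"),
                    role = vapply(candidate_technical, role_of, ""),
                    stringsAsFactors = FALSE)
  tab$passed <- tab$multivariate_p < alpha
  passed <- stats::setNames(tab$role[tab$passed], tab$variable[tab$passed])
  structure(list(table = tab, passed = passed, alpha = alpha,
                 univariate = stats::setNames(uni, candidate_technical),
                 multivariate = stats::setNames(multi, candidate_technical)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("technical variable screen (multivariate alpha = %g):\n", x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Test an interaction between two covariates on the whole matrix
#'
#' Drops the product term from the joint model (both main effects plus
#' their interaction, plus any adjustment terms) and calibrates the extra
#' sum of squares by Freedman-Lane permutation.
#'
#' @param expr an [expr_set()] (log2, complete).
#' @param annotations an [annotation_table()].
#' @param var1,var2 the interacting variable names.
#' @param adjust additional adjustment terms kept in both models.
#' @param n_perm,seed see [permutation_test()].
#' @return An `ancova_result` for the interaction term.
#' @export
test_interaction <- function(expr, annotations, var1, var2,
                             adjust = character(), n_perm = 10000,
                             seed = NULL) {
  full <- c(adjust, var1, var2, paste0(var1, ":", var2))
  reduced <- c(adjust, var1, var2)
  permutation_test(expr, annotations, full, reduced, n_perm = n_perm,
                   seed = seed)
}
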