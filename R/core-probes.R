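# Internal global-test engine.
#
# Residualizes the outcome and the probe rows on the adjustment design,
# standardizes probe rows, and computes the per-probe quadratic statistic
# Q_i = (x_i . r)^2 for the observed outcome and for a permutation null
# over outcome-residual permutations. For a factor outcome with more than
# two levels, Q_i is the maximum per-class statistic over level indicators
# (experimental). Returns everything the scoring, core-selection and
# comparative machinery needs.
gt_engine <- function(expr, annotations, outcome, probe_set = NULL,
                      adjust = character(), n_perm = 1000, seed = NULL,
                      exact = FALSE) {
  Y <- expr_values(expr)
  ann <- if (inherits(expr, "expr_set")) align_annotations(annotations, expr)
         else annotations
  if (is.null(probe_set)) probe_set <- rownames(Y)
  miss <- setdiff(probe_set, rownames(Y))
  if (length(miss))
    stop("probe(s) not in expression matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  n <- ncol(Y)
  Z <- build_design(ann, adjust)
  qz <- qr(Z)

  yv <- ann[[outcome]]
  if (is.null(yv)) stop("unknown outcome variable: ", outcome)
  if (is.character(yv) || is.logical(yv)) yv <- factor(yv)
  if (is.factor(yv) && nlevels(yv) > 2) {
    Ymat <- stats::model.matrix(~ yv - 1)
  } else {
    if (is.factor(yv)) yv <- as.integer(yv) - 1L
    Ymat <- matrix(as.numeric(yv), ncol = 1)
  }
  R0 <- qr.resid(qz, Ymat)
  if (all(abs(R0) < 1e-12)) stop("constant outcome after residualization")

  Xr <- qr.resid(qz, t(Y[probe_set, , drop = FALSE]))
  sds <- sqrt(colSums(Xr^2) / (n - 1))
  keep_sd <- sds > 0
  Xr[, keep_sd] <- sweep(Xr[, keep_sd, drop = FALSE], 2, sds[keep_sd], "/")
  Xr[, !keep_sd] <- 0
  tX <- t(Xr)  # probes x samples

  q_of <- function(Rmat) {
    # per-probe statistic for one outcome column set (max over classes)
    qs <- (tX %*% Rmat)^2
    if (ncol(qs) > 1) apply(qs, 1, max) else qs[, 1]
  }
  Q_obs <- q_of(R0)

  if (exact) {
    if (n > 9) stop("exact enumeration supported for n <= 9 samples")
    perms <- all_permutations(n)
    B <- nrow(perms)
    Qp <- matrix(0, length(probe_set), B)
    for (b in seq_len(B)) Qp[, b] <- q_of(R0[perms[b, ], , drop = FALSE])
  } else {
    if (n_perm < 1) stop("n_perm must be at least 1")
    if (!is.null(seed)) set.seed(seed)
    B <- n_perm
    if (ncol(R0) == 1) {
      Rp <- matrix(0, n, B)
      for (b in seq_len(B)) Rp[, b] <- R0[sample.int(n), 1]
      Qp <- (tX %*% Rp)^2
    } else {
      Qp <- matrix(0, length(probe_set), B)
      for (b in seq_len(B)) Qp[, b] <- q_of(R0[sample.int(n), , drop = FALSE])
    }
  }
  list(probe_set = probe_set, Q_obs = Q_obs, Q_perm = Qp, n_perm = B,
       exact = exact, seed = seed, outcome = outcome, adjust = adjust,
       Xr = Xr, R0 = R0)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub], nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

#' Global-test scores for a probe set
#'
#' Scores the joint association between a probe set and an outcome. Each
#' probe contributes \eqn{Q_i = (\sum_j x_{ij} r_j)^2}, where `r` is the
#' outcome residualized on the adjustment design and `x_i` the probe row
#' residualized on the same design and standardized; the set statistic is
#' the mean of the per-probe contributions. A permutation null over
#' outcome-residual permutations supplies moments (E, SD), z-scores
#' `z = (Q - E)/SD` per probe and for the set, and permutation p-values
#' with the add-one rule. With `exact = TRUE` (n <= 9) every permutation
#' is enumerated and p-values are exact proportions.
#'
#' @param expr an [expr_set()] (log2, complete) or probe x sample matrix.
#' @param annotations an [annotation_table()].
#' @param outcome outcome variable name (binary 0/1 or two-level factor;
#'   factors with more levels use the maximum per-class statistic,
#'   experimental).
#' @param probe_set probe ids (default: all probes).
#' @param adjust adjustment term labels residualized out of outcome and
#'   probes.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param exact enumerate all permutations instead (n <= 9).
#' @return A `global_test_score`: list with `set_Q`, `set_z`, `set_p`,
#'   `per_probe_Q`, `per_probe_z`, `per_probe_p` (named by probe),
#'   `n_perm`, `seed`, `outcome`, `adjust`.
#' @export
global_test_scores <- function(expr, annotations, outcome, probe_set = NULL,
                               adjust = character(), n_perm = 1000,
                               seed = NULL, exact = FALSE) {
  eng <- gt_engine(expr, annotations, outcome, probe_set, adjust,
                   n_perm, seed, exact)
  score_from_engine(eng, seq_along(eng$probe_set))
}

# Assemble a global_test_score for a subset of engine rows.
score_from_engine <- function(eng, idx) {
  Q <- eng$Q_obs[idx]
  Qp <- eng$Q_perm[idx, , drop = FALSE]
  B <- eng$n_perm
  E <- rowMeans(Qp)
  SD <- sqrt(rowSums((Qp - E)^2) / (B - 1))
  z <- ifelse(SD > 0, (Q - E) / SD, 0)
  # >= up to relative rounding noise: permutations reproducing the observed
  # assignment must count as ties, not fall on either side by 1 ulp
  thr <- Q - (abs(Q) * 1e-9 + 1e-12)
  qset <- colMeans(Qp)
  thr_set <- mean(Q) - (abs(mean(Q)) * 1e-9 + 1e-12)
  if (eng$exact) {
    p <- rowMeans(Qp >= thr)
    set_p <- mean(qset >= thr_set)
  } else {
    p <- (1 + rowSums(Qp >= thr)) / (B + 1)
    set_p <- (1 + sum(qset >= thr_set)) / (B + 1)
  }
  e_set <- mean(qset); sd_set <- stats::sd(qset)
  structure(list(set_Q = mean(Q),
                 set_z = if (sd_set > 0) (mean(Q) - e_set) / sd_set else 0,
                 set_p = set_p,
                 per_probe_Q = stats::setNames(Q, eng$probe_set[idx]),
                 per_probe_z = stats::setNames(z, eng$probe_set[idx]),
                 per_probe_p = stats::setNames(p, eng$probe_set[idx]),
                 n_perm = B, exact = eng$exact, seed = eng$seed,
                 outcome = eng$outcome, adjust = eng$adjust),
            class = "global_test_score")
}

#' @export
print.global_test_score <- function(x, ...) {
  cat(sprintf("global test: %d probes vs '%s' | Q = %.4g, z = %.2f, p = %.3g (%s)\n",
              length(x$per_probe_Q), x$outcome, x$set_Q, x$set_z, x$set_p,
              if (x$exact) "exact" else sprintf("%d perms", x$n_perm)))
  invisible(x)
}

#' Weighted core-probe selection from global-test z-scores
#'
#' Converts the per-probe z-scores to two-sided p-values, adjusts them by
#' the Benjamini-Hochberg step-up, and scans every achievable |z| cutpoint
#' `t`. Writing `S(t)` for the number of probes at or above the cutpoint
#' and `FDR(t)` for the adjusted value at the cutpoint, the utility
#' \deqn{U(t) = w_{tp} S(t) (1 - FDR(t)) - w_{fp} S(t) FDR(t)}
#' weighs estimated true positives against estimated false positives; the
#' returned threshold maximizes U (ties resolved toward the larger, i.e.
#' stricter, cutpoint; the empty selection with U = 0 is always
#' achievable).
#'
#' @param scores a `global_test_score` from [global_test_scores()].
#' @param w_tp,w_fp true/false positive weights (defaults 2 and 1).
#' @param p_method `"normal"` (default) derives per-probe p-values as
#'   `2 pnorm(-|z|)`; `"perm"` uses the permutation p-values instead.
#' @return A `core_selection`: list `variable`, `threshold` (|z| cutoff;
#'   `Inf` when nothing is selected), `fdr_at_threshold`, `core_probes`,
#'   `utility`, `n_selected`.
#' @export
select_core_weighted <- function(scores, w_tp = 2, w_fp = 1,
                                 p_method = c("normal", "perm")) {
  p_method <- match.arg(p_method)
  z <- scores$per_probe_z
  if (length(z) == 0) stop("empty score set")
  p <- switch(p_method,
              normal = 2 * stats::pnorm(-abs(z)),
              perm = scores$per_probe_p)
  q <- stats::p.adjust(p, method = "BH")
  ord <- order(-abs(z), seq_along(z))
  fdr_path <- cummax(q[ord])  # FDR at each achievable cutpoint
  S <- seq_along(ord)
  U <- w_tp * S * (1 - fdr_path) - w_fp * S * fdr_path
  best <- which.max(c(0, U)) - 1L  # 0 = select nothing; first max = strictest
  if (best == 0L) {
    sel <- character()
    thr <- Inf
    fdr <- NA_real_
    util <- 0
  } else {
    sel <- names(z)[ord[seq_len(best)]]
    thr <- abs(z)[ord[best]]
    fdr <- fdr_path[best]
    util <- U[best]
  }
  structure(list(variable = scores$outcome, threshold = thr,
                 fdr_at_threshold = fdr, core_probes = sel,
                 utility = util, n_selected = length(sel),
                 w_tp = w_tp, w_fp = w_fp, p_method = p_method),
            class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  cat(sprintf("core_selection '%s': %d probes at |z| >= %.3g (FDR %.3g)\n",
              x$variable, x$n_selected, x$threshold,
              if (is.na(x$fdr_at_threshold)) NA else x$fdr_at_threshold))
  invisible(x)
}

#' Direction of association for core probes
#'
#' The sign of the covariance between each probe (residualized on the
#' adjustment design) and the residualized outcome: positive means the
#' probe is up-regulated in the outcome's level-1 group.
#'
#' @param expr an [expr_set()] or probe x sample matrix (log2, complete).
#' @param annotations an [annotation_table()].
#' @param outcome binary outcome variable name.
#' @param core_probes probe ids to orient.
#' @param adjust adjustment term labels.
#' @return Named character vector: `"up-in-level-1"`, `"up-in-level-0"` or
#'   `"undetermined"` (zero covariance).
#' @export
association_direction <- function(expr, annotations, outcome, core_probes,
                                  adjust = character()) {
  Y <- expr_values(expr)
  ann <- if (inherits(expr, "expr_set")) align_annotations(annotations, expr)
         else annotations
  Z <- build_design(ann, adjust)
  qz <- qr(Z)
  yv <- ann[[outcome]]
  if (is.factor(yv) || is.character(yv)) yv <- as.integer(factor(yv)) - 1L
  r <- qr.resid(qz, as.numeric(yv))
  Xr <- qr.resid(qz, t(Y[core_probes, , drop = FALSE]))
  cv <- as.numeric(crossprod(Xr, r))
  # a probe whose residual signal is numerically null has no direction
  raw_scale <- sqrt(rowSums(Y[core_probes, , drop = FALSE]^2)) + 1
  null_probe <- sqrt(colSums(Xr^2)) <= 1e-8 * raw_scale
  dir <- ifelse(null_probe | cv == 0, "undetermined",
                ifelse(cv > 0, "up-in-level-1", "up-in-level-0"))
  stats::setNames(dir, core_probes)
}
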