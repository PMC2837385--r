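#' Candidate variable pool for per-probe model selection
#'
#' Collects the variables offered to the per-probe forward-backward BIC
#' search: biological and exposure covariates (plus any declared
#' interaction) as fixed candidates, screened technical covariates as
#' fixed or random candidates according to their role. With the standard
#' cohort (age class, fasting, BMI class, smoking, HT, MED, the HT:MED
#' interaction, time-to-freezing, array lot, extraction date) the pool
#' holds 10 variables.
#'
#' @param annotations an [annotation_table()].
#' @param screen optional `screen_result` from [screen_variables()]; its
#'   surviving technical variables enter the pool with their screened
#'   roles. When absent, all `technical-random` variables enter as random
#'   candidates and all `technical-fixed` variables as fixed candidates.
#' @return A `candidate_pool`: list `fixed_candidates`, `random_candidates`,
#'   `biological` (the biological/exposure/interaction subset of the fixed
#'   candidates) and `hierarchy` (interaction -> required main effects).
#' @export
candidate_pool <- function(annotations, screen = NULL) {
  roles <- variable_roles(annotations)
  bio <- variables_with_role(annotations, c("biological", "exposure"))
  inter <- variables_with_role(annotations, "interaction")
  if (is.null(screen)) {
    tech_random <- variables_with_role(annotations, "technical-random")
    tech_fixed <- variables_with_role(annotations, "technical-fixed")
  } else {
    tech_random <- names(screen$passed)[screen$passed == "random"]
    tech_fixed <- names(screen$passed)[screen$passed == "fixed"]
  }
  hierarchy <- lapply(inter, function(v) strsplit(v, ":", fixed = TRUE)[[1]])
  names(hierarchy) <- inter
  structure(list(fixed_candidates = c(bio, inter, tech_fixed),
                 random_candidates = tech_random,
                 biological = c(bio, inter),
                 hierarchy = hierarchy),
            class = "candidate_pool")
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat(sprintf("candidate_pool (%d variables)\n",
              length(x$fixed_candidates) + length(x$random_candidates)))
  cat("  fixed :", paste(x$fixed_candidates, collapse = ", "), "\n")
  cat("  random:", paste(x$random_candidates, collapse = ", "), "\n")
  invisible(x)
}

#' Shared fit cache for repeated per-probe model fits
#'
#' Stores design decompositions and fitted mixed-model structures keyed by
#' model signature, so that fitting the same candidate model to thousands
#' of probes reuses the expensive setup (`lme4::refit()` for mixed models,
#' a cached QR factorization for fixed-effects-only models).
#'
#' @return An environment usable as the `cache` argument of
#'   [fit_mixed_bic()] and the selection functions.
#' @export
new_fit_cache <- function() new.env(parent = emptyenv())

# Profiled ML deviance for a linear mixed model with crossed random
# intercepts. Given variance ratios gamma_k = sigma_k^2 / sigma_e^2, the
# fixed effects and residual variance profile out in closed form via the
# penalized least squares system (Sylvester identity for the
# determinant):
#   -2 loglik(gamma) = n log(2 pi sigma^2(gamma)) + log|I + Z* Z*'| + n
# with Z* the gamma-scaled indicator matrix, sigma^2(gamma) = PLS/n.
# pre holds precomputed crossproducts; lg is log(gamma).
lmm_profiled_dev <- function(lg, pre) {
  s <- sqrt(exp(pmin(pmax(lg[pre$block], -40), 40)))
  M11 <- pre$ZtZ * tcrossprod(s)
  diag(M11) <- diag(M11) + 1
  ch11 <- chol(M11)
  logdet <- 2 * sum(log(diag(ch11)))
  M <- rbind(cbind(M11, s * pre$ZtX),
             cbind(t(s * pre$ZtX), pre$XtX))
  rhs <- c(s * pre$Zty, pre$Xty)
  ch <- chol(M)
  pls <- pre$yty - sum(forwardsolve(t(ch), rhs)^2)
  pls <- max(pls, 1e-12)
  pre$n * log(2 * pi * pls / pre$n) + logdet + pre$n
}

#' Fit one candidate model to a probe and return its ML BIC
#'
#' Fits a linear model with the named fixed effects and crossed random
#' intercepts for each random variable, by maximum likelihood (not REML,
#' so BIC values are comparable across different fixed-effect sets). The
#' fixed effects and the residual variance are profiled out in closed
#' form, and the deviance is optimized numerically over the log variance
#' ratios of the random components; variance estimates are floored at 0
#' (a degenerate grouping collapses to the corresponding fixed-effects
#' likelihood). The parameter count is the number of fixed-effect
#' coefficients (including the intercept) plus one residual variance plus
#' one variance per random component, and
#' `bic = -2 loglik + n_params log(n)`.
#'
#' @param y numeric per-sample expression vector.
#' @param fixed,random character vectors of variable names (either may be
#'   empty; random variables must be categorical).
#' @param annotations an [annotation_table()] aligned with `y`.
#' @param cache optional [new_fit_cache()] reusing design decompositions
#'   across probes.
#' @param fallback if a mixed fit fails on a degenerate fixture (e.g. a
#'   non-positive-definite system), refit with the random variables as
#'   fixed factors and flag the result (`fallback = TRUE` in the output)
#'   instead of erroring.
#' @return list `loglik`, `n_params`, `bic`, `fallback`, and for mixed
#'   fits `gamma` (variance ratios at the optimum).
#' @export
fit_mixed_bic <- function(y, fixed, random, annotations, cache = NULL,
                          fallback = TRUE) {
  n <- length(y)
  stopifnot(nrow(annotations) == n)
  get_cached <- function(key, make) {
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    val <- make()
    if (!is.null(cache)) cache[[key]] <- val
    val
  }
  fkey <- paste0("F|", paste(sort(fixed), collapse = "+"))
  qx <- get_cached(fkey, function() qr(build_design(annotations, fixed)))
  if (length(random) == 0) {
    rss <- sum(qr.resid(qx, y)^2)
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    k <- qx$rank + 1
    return(list(loglik = ll, n_params = k, bic = -2 * ll + k * log(n),
                fallback = FALSE))
  }
  random <- sort(random)
  X <- get_cached(paste0("X|", fkey), function() qr.X(qx))
  Z_parts <- lapply(random, function(v)
    get_cached(paste0("Z|", v), function() {
      f <- annotations[[v]]
      if (!is.factor(f)) f <- factor(f)
      stats::model.matrix(~ f - 1)
    }))
  rkey <- paste0("R|", paste(random, collapse = "+"))
  Z <- get_cached(rkey, function() do.call(cbind, Z_parts))
  block <- rep(seq_along(random), vapply(Z_parts, ncol, 0L))
  pre <- list(
    ZtZ = get_cached(paste0("ZtZ|", rkey), function() crossprod(Z)),
    ZtX = get_cached(paste0("ZtX|", rkey, "|", fkey),
                     function() crossprod(Z, X)),
    XtX = get_cached(paste0("XtX|", fkey), function() crossprod(X)),
    Zty = crossprod(Z, y)[, 1], Xty = crossprod(X, y)[, 1],
    yty = sum(y * y), n = n, block = block)
  k_r <- length(random)
  dev <- tryCatch({
    if (k_r == 1) {
      opt <- stats::optimize(lmm_profiled_dev, c(-25, 15), pre = pre)
      list(value = opt$objective, par = opt$minimum)
    } else {
      opt <- stats::optim(rep(0, k_r), lmm_profiled_dev, pre = pre,
                          method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-10))
      list(value = opt$value, par = opt$par)
    }
  }, error = function(e) e)
  if (inherits(dev, "error")) {
    if (!fallback) stop("mixed model fit failed: ", conditionMessage(dev))
    res <- fit_mixed_bic(y, fixed = c(fixed, random), random = character(),
                         annotations = annotations, cache = cache)
    res$fallback <- TRUE
    return(res)
  }
  # a ratio this small is a boundary estimate: variance component 0
  gamma <- exp(dev$par)
  gamma[gamma < 1e-8] <- 0
  ll <- -dev$value / 2
  k <- qx$rank + k_r + 1
  list(loglik = ll, n_params = k, bic = -2 * ll + k * log(n),
       fallback = FALSE, gamma = stats::setNames(gamma, random))
}

#' Forward-backward BIC selection of a per-probe model
#'
#' Starting from the intercept-only model, alternately adds the single
#' candidate yielding the largest BIC decrease and removes any selected
#' variable whose removal decreases BIC, until no move improves BIC. Any
#' BIC decrease counts (strict improvement threshold 0); ties are resolved
#' by candidate order in the pool. An interaction is only addable once
#' both its main effects are selected, and a main effect cannot be dropped
#' while its interaction remains. A candidate move whose fit fails is
#' skipped with a warning. The search is deterministic given the data.
#'
#' @param y numeric per-sample expression vector.
#' @param pool a [candidate_pool()].
#' @param annotations an [annotation_table()] aligned with `y`.
#' @param cache optional [new_fit_cache()] shared across probes.
#' @param probe_id identifier carried into the result.
#' @return A `probe_model`: list `probe_id`, `selected_fixed`,
#'   `selected_random`, `bic`, `loglik`, `n_params`, `fallback`.
#' @export
forward_backward_select <- function(y, pool, annotations, cache = NULL,
                                    probe_id = NA_character_) {
  candidates <- c(pool$fixed_candidates, pool$random_candidates)
  is_random <- stats::setNames(candidates %in% pool$random_candidates, candidates)
  sel <- character()
  eval_model <- function(vars) {
    tryCatch(fit_mixed_bic(y, fixed = vars[!is_random[vars]],
                           random = vars[is_random[vars]],
                           annotations = annotations, cache = cache),
             error = function(e) {
               warning("skipping move (", conditionMessage(e), ")",
                       call. = FALSE)
               NULL
             })
  }
  cur <- eval_model(character())
  addable <- function(v, sel) {
    if (v %in% sel) return(FALSE)
    par <- pool$hierarchy[[v]]
    is.null(par) || all(par %in% sel)
  }
  droppable <- function(v, sel) {
    for (int in names(pool$hierarchy))
      if (int %in% sel && int != v && v %in% pool$hierarchy[[int]]) return(FALSE)
    TRUE
  }
  repeat {
    moved <- FALSE
    # backward sweep: drop while some removal improves BIC
    repeat {
      drops <- sel[vapply(sel, droppable, TRUE, sel = sel)]
      if (!length(drops)) break
      fits <- lapply(drops, function(v) eval_model(setdiff(sel, v)))
      bics <- vapply(fits, function(f) if (is.null(f)) Inf else f$bic, 0)
      best <- which.min(bics)
      if (length(bics) && bics[best] < cur$bic) {
        sel <- setdiff(sel, drops[best])
        cur <- fits[[best]]
        moved <- TRUE
      } else break
    }
    # forward step: best single addition
    adds <- candidates[vapply(candidates, addable, TRUE, sel = sel)]
    if (length(adds)) {
      fits <- lapply(adds, function(v) eval_model(c(sel, v)))
      bics <- vapply(fits, function(f) if (is.null(f)) Inf else f$bic, 0)
      best <- which.min(bics)
      if (bics[best] < cur$bic) {
        sel <- c(sel, adds[best])
        cur <- fits[[best]]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  structure(list(probe_id = probe_id,
                 selected_fixed = sel[!is_random[sel]],
                 selected_random = sel[is_random[sel]],
                 bic = cur$bic, loglik = cur$loglik,
                 n_params = cur$n_params,
                 fallback = isTRUE(cur$fallback)),
            class = "probe_model")
}

#' @export
print.probe_model <- function(x, ...) {
  cat(sprintf("probe_model %s: BIC %.2f, fixed {%s}, random {%s}%s\n",
              x$probe_id, x$bic,
              paste(x$selected_fixed, collapse = ", "),
              paste(x$selected_random, collapse = ", "),
              if (x$fallback) " [fixed-factor fallback]" else ""))
  invisible(x)
}

#' Run per-probe BIC selection for every probe and summarize
#'
#' Applies [forward_backward_select()] to each probe of the matrix and
#' assembles the binary probes x candidate-variables association matrix,
#' with the standard summaries: per-variable probe counts, mean and SD of
#' the number of variables selected per probe, the fraction of probes
#' selecting each technical variable, and the fraction associated with at
#' least two biological/exposure variables. Probes whose selection fails
#' are reported and excluded from the summaries.
#'
#' @param expr an [expr_set()] (log2, complete) or probe x sample matrix.
#' @param pool a [candidate_pool()].
#' @param annotations an [annotation_table()].
#' @param verbose print progress every 500 probes.
#' @return An `association_result`: list `matrix` (binary, probes x
#'   variables), `summary` (list), `models` (per-probe `probe_model`s),
#'   `failed` (probe ids).
#' @export
build_association_matrix <- function(expr, pool, annotations,
                                     verbose = FALSE) {
  Y <- expr_values(expr)
  ann <- if (inherits(expr, "expr_set")) align_annotations(annotations, expr)
         else annotations
  vars <- c(pool$fixed_candidates, pool$random_candidates)
  G <- nrow(Y)
  A <- matrix(0L, G, length(vars), dimnames = list(rownames(Y), vars))
  cache <- new_fit_cache()
  models <- vector("list", G)
  failed <- character()
  for (g in seq_len(G)) {
    m <- tryCatch(forward_backward_select(Y[g, ], pool, ann, cache = cache,
                                          probe_id = rownames(Y)[g]),
                  error = function(e) NULL)
    if (is.null(m)) {
      failed <- c(failed, rownames(Y)[g])
      next
    }
    models[[g]] <- m
    A[g, c(m$selected_fixed, m$selected_random)] <- 1L
    if (verbose && g %% 500 == 0)
      message(sprintf("  selection: %d / %d probes", g, G))
  }
  ok <- !rownames(A) %in% failed
  counts <- colSums(A[ok, , drop = FALSE])
  per_probe <- rowSums(A[ok, , drop = FALSE])
  bio_cols <- intersect(pool$biological, vars)
  n_bio <- rowSums(A[ok, bio_cols, drop = FALSE])
  tech_cols <- setdiff(vars, bio_cols)
  summary <- list(
    n_probes = sum(ok),
    per_variable_counts = counts,
    mean_selected = mean(per_probe),
    sd_selected = stats::sd(per_probe),
    frac_technical = counts[tech_cols] / sum(ok),
    frac_at_least_two_biological = mean(n_bio >= 2),
    frac_at_least_two = mean(per_probe >= 2))
  structure(list(matrix = A, summary = summary, models = models,
                 failed = failed, pool = pool),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("association_result: %d probes, %.2f variables/probe (SD %.2f)\n",
              s$n_probes, s$mean_selected, s$sd_selected))
  print(s$per_variable_counts)
  invisible(x)
}

#' Probes uniquely associated with a single biological variable
#'
#' A probe counts as uniquely associated with biological/exposure variable
#' `v` when its selected variable set, after removing the permitted
#' technical terms (by default only the array lot, which most probes pick
#' up), equals exactly `{v}`.
#'
#' @param assoc an `association_result` (or its binary matrix with a pool
#'   supplied).
#' @param variables biological variables to report (default: all in the
#'   pool). Unknown names error.
#' @param permitted technical variables whose membership does not spoil
#'   uniqueness (default `"lot"`).
#' @return Named list mapping each variable to its uniquely associated
#'   probe ids.
#' @export
unique_biological <- function(assoc, variables = NULL, permitted = "lot") {
  A <- assoc$matrix
  pool <- assoc$pool
  if (is.null(variables)) variables <- intersect(pool$biological, colnames(A))
  unknown <- setdiff(c(variables, permitted), colnames(A))
  if (length(unknown))
    stop("unknown variable name(s): ", paste(unknown, collapse = ", "))
  strip <- setdiff(colnames(A), permitted)
  out <- lapply(variables, function(v) {
    others <- setdiff(strip, v)
    rownames(A)[A[, v] == 1L & rowSums(A[, others, drop = FALSE]) == 0L]
  })
  names(out) <- variables
  out
}
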