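#' Eigengene decomposition of a complete expression matrix
#'
#' Singular value decomposition of the probe-centered matrix. Eigengenes
#' are the right-singular vectors — principal expression patterns over
#' samples; because every probe row is centered, each eigengene sums to
#' zero over samples. The eigenvalue shares are the squared singular
#' values normalized to sum 1, i.e. the fraction of total variation each
#' eigengene carries.
#'
#' @param expr an [expr_set()] (log2, complete) or numeric probe x sample
#'   matrix.
#' @param center center each probe row first (default TRUE).
#' @return list `eigengenes` (samples x K matrix), `shares` (length-K
#'   non-negative weights summing to 1).
#' @export
eigengenes <- function(expr, center = TRUE) {
  Y <- expr_values(expr)
  if (center) Y <- Y - rowMeans(Y)
  sv <- svd(Y)
  pos <- sv$d > max(sv$d) * 1e-12
  d2 <- sv$d[pos]^2
  list(eigengenes = sv$v[, pos, drop = FALSE], shares = d2 / sum(d2))
}

#' EigenR2: variance fraction of expression explained by a variable set
#'
#' A high-dimensional analogue of the classic R2 statistic: each eigengene
#' of the probe-centered expression matrix is regressed on the design of
#' the named variables by ordinary least squares, and the per-eigengene R2
#' values are averaged with eigenvalue-share weights:
#' \deqn{eigenR2 = \sum_k share_k \, R^2_k.}
#' All eigengenes with non-zero share are used and the per-eigengene R2 is
#' unadjusted by default; on null designs this carries a small-sample
#' positive bias of about p/(n-1) per eigengene (p = non-intercept design
#' columns), which `adjusted = TRUE` removes via the usual
#' degrees-of-freedom correction.
#'
#' @param expr an [expr_set()] (log2, complete) or probe x sample matrix.
#' @param annotations an [annotation_table()].
#' @param variables character vector of term labels to test jointly.
#' @param adjusted use adjusted R2 per eigengene (default FALSE).
#' @param center probe-wise centering before decomposition (default TRUE).
#' @return An `eigen_r2_result`: list with `eigen_r2`, `per_eigengene_r2`,
#'   `eigenvalue_shares`, `variables`, `adjusted`.
#' @export
eigen_r2 <- function(expr, annotations, variables, adjusted = FALSE,
                     center = TRUE) {
  Y <- expr_values(expr)
  ann <- if (inherits(expr, "expr_set")) align_annotations(annotations, expr)
         else annotations
  X <- build_design(ann, variables)
  n <- ncol(Y)
  if (ncol(X) > n) stop("design has more columns than samples")
  eg <- eigengenes(Y, center = center)
  V <- eg$eigengenes
  qx <- qr(X)
  res <- qr.resid(qx, V)
  tss <- colSums((V - rep(colMeans(V), each = nrow(V)))^2)
  rss <- colSums(res^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  if (adjusted) {
    p <- ncol(X) - 1  # non-intercept columns
    df_den <- n - 1 - p
    if (df_den <= 0) stop("not enough residual degrees of freedom for adjusted R2")
    r2 <- 1 - (1 - r2) * (n - 1) / df_den
  }
  r2 <- pmin(pmax(r2, if (adjusted) -Inf else 0), 1)
  structure(list(eigen_r2 = sum(eg$shares * r2),
                 per_eigengene_r2 = r2,
                 eigenvalue_shares = eg$shares,
                 variables = variables,
                 adjusted = adjusted),
            class = "eigen_r2_result")
}

#' @export
print.eigen_r2_result <- function(x, ...) {
  cat(sprintf("eigenR2 = %.3f (%s R2, %d eigengenes) for: %s\n",
              x$eigen_r2, if (x$adjusted) "adjusted" else "unadjusted",
              length(x$eigenvalue_shares),
              paste(x$variables, collapse = ", ")))
  invisible(x)
}
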