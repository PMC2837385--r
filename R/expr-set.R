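#' Expression set container
#'
#' Bundles a probe-by-sample intensity matrix with the parallel per-cell
#' signal-to-noise (S/N) and quality-flag matrices produced by array image
#' analysis. Missing measurements are carried as `NA` in `values`; the
#' missingness mask is therefore always `is.na(values)` and survives every
#' downstream operation until imputation.
#'
#' @param values numeric probe x sample matrix. Rows are probes, columns are
#'   arrays. `scale` records whether the values are raw intensities or
#'   already log2.
#' @param snr numeric matrix of per-cell signal-to-noise ratios, same
#'   dimensions as `values`, or `NULL`.
#' @param flags non-negative integer matrix of per-cell quality codes, same
#'   dimensions as `values`, or `NULL`. Values above 8191 mark unusable
#'   measurements.
#' @param probe_ids,sample_ids optional identifier vectors; default to the
#'   dimnames of `values`.
#' @param scale `"raw"` or `"log2"`.
#'
#' @return An object of class `expr_set`: a list with elements `values`,
#'   `snr`, `flags` and `scale`, with unique row/column names on all
#'   matrices.
#' @export
expr_set <- function(values, snr = NULL, flags = NULL,
                     probe_ids = rownames(values),
                     sample_ids = colnames(values),
                     scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(probe_ids)) probe_ids <- sprintf("probe_%05d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(ncol(values)))
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(probe_ids)) stop("duplicate probe ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  dimnames(values) <- list(probe_ids, sample_ids)
  check_mat <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!all(dim(m) == dim(values)))
      stop(sprintf("'%s' matrix dimensions differ from 'values'", what))
    dimnames(m) <- dimnames(values)
    m
  }
  out <- structure(
    list(values = values,
         snr = check_mat(snr, "snr"),
         flags = check_mat(flags, "flags"),
         scale = scale),
    class = "expr_set")
  out
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  S/N: %s, flags: %s, missing cells: %d\n",
              if (is.null(x$snr)) "absent" else "present",
              if (is.null(x$flags)) "absent" else "present",
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' @rdname expr_set
#' @param x an `expr_set`.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname expr_set
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname expr_set
#' @export
missing_mask <- function(x) is.na(x$values)

#' Subset an expression set
#'
#' `[` keeps the value, S/N and flag matrices aligned.
#'
#' @param x an `expr_set`.
#' @param i,j probe / sample indices (any form `[` accepts).
#' @param ... ignored.
#' @export
`[.expr_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  expr_set(x$values[i, j, drop = FALSE],
           snr = if (!is.null(x$snr)) x$snr[i, j, drop = FALSE],
           flags = if (!is.null(x$flags)) x$flags[i, j, drop = FALSE],
           scale = x$scale)
}
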