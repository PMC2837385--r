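#' Sample annotation table with variable roles
#'
#' A per-sample covariate table in which every analysis variable carries a
#' role tag that drives its downstream treatment:
#' \describe{
#'   \item{`technical-random`}{categorical batch factor (array lot, RNA
#'     extraction date) — a random intercept in the per-probe mixed models.}
#'   \item{`technical-fixed`}{fixed technical covariate (e.g. time between
#'     blood collection and freezing, in days).}
#'   \item{`biological`}{inter-individual variable (age class, BMI class,
#'     fasting status).}
#'   \item{`exposure`}{exposure variable (smoking, hormone therapy,
#'     medication use).}
#'   \item{`interaction`}{a product term, written `"a:b"`.}
#' }
#'
#' @param data a data.frame with one row per array, containing a
#'   `sample_id` column (unique) and optionally `subject_id` (used to
#'   resolve technical replicates; defaults to `sample_id`).
#' @param roles named character vector mapping variable names (columns of
#'   `data`, or `"a:b"` interaction labels whose parents are columns) to a
#'   role.
#'
#' @return An `annotation_table`: the data.frame with a `roles` attribute.
#' @export
annotation_table <- function(data, roles) {
  data <- as.data.frame(data)
  if (!"sample_id" %in% names(data)) stop("annotation needs a 'sample_id' column")
  data$sample_id <- as.character(data$sample_id)
  if (anyDuplicated(data$sample_id)) stop("duplicate sample ids in annotation")
  if (!"subject_id" %in% names(data)) data$subject_id <- data$sample_id
  valid <- c("technical-random", "technical-fixed", "biological",
             "exposure", "interaction")
  if (is.null(names(roles)) || any(!nzchar(names(roles))))
    stop("'roles' must be a named character vector")
  bad <- setdiff(roles, valid)
  if (length(bad))
    stop("unknown role tag(s): ", paste(unique(bad), collapse = ", "))
  for (v in names(roles)) {
    parts <- strsplit(v, ":", fixed = TRUE)[[1]]
    miss <- setdiff(parts, names(data))
    if (length(miss))
      stop("role declared for unknown variable(s): ", paste(miss, collapse = ", "))
  }
  attr(data, "roles") <- roles
  class(data) <- c("annotation_table", "data.frame")
  data
}

#' @rdname annotation_table
#' @param x an `annotation_table`.
#' @export
variable_roles <- function(x) attr(x, "roles")

#' Variables holding a given role
#'
#' @param x an `annotation_table`.
#' @param role one or more role tags.
#' @return character vector of variable names.
#' @export
variables_with_role <- function(x, role) {
  r <- variable_roles(x)
  names(r)[r %in% role]
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("annotation_table: %d arrays, %d subjects\n",
              nrow(x), length(unique(x$subject_id))))
  r <- variable_roles(x)
  for (role in unique(r))
    cat(sprintf("  %-17s %s\n", role, paste(names(r)[r == role], collapse = ", ")))
  invisible(x)
}

# Align annotation rows to the sample order of an expr_set; errors on
# samples absent from either side.
align_annotations <- function(annotations, expr) {
  ids <- sample_ids(expr)
  miss <- setdiff(ids, annotations$sample_id)
  if (length(miss))
    stop("annotation missing sample(s): ", paste(utils::head(miss, 5), collapse = ", "))
  out <- annotations[match(ids, annotations$sample_id), , drop = FALSE]
  attr(out, "roles") <- variable_roles(annotations)
  class(out) <- class(annotations)
  rownames(out) <- NULL
  out
}

# Build a full-rank-checked design matrix from term labels ("x", "a:b").
# Categorical variables are dummy-encoded against a first-level reference.
# Returns the matrix with an "assign" attribute mapping columns to terms.
build_design <- function(annotations, terms, intercept = TRUE) {
  df <- as.data.frame(annotations)
  for (v in names(df)) if (is.character(df[[v]]) || is.logical(df[[v]]))
    df[[v]] <- factor(df[[v]])
  rhs <- if (length(terms)) paste(vapply(terms, function(t)
    paste0("`", gsub(":", "`:`", t), "`"), ""), collapse = " + ") else "1"
  fml <- stats::as.formula(paste("~", if (intercept) rhs else paste(rhs, "- 1")))
  X <- stats::model.matrix(fml, data = df)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  X
}
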