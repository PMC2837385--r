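#' QC report
#'
#' Records, for one stage or for a whole cascade, the arrays and probes
#' excluded and why, plus replicate resolutions. Counts always reconcile:
#' `n_arrays_out = n_arrays_in - nrow(excluded_arrays)` and likewise for
#' probes.
#'
#' @param n_arrays_in,n_arrays_out,n_probes_in,n_probes_out counts.
#' @param excluded_arrays data.frame with columns `sample_id`, `reason`.
#' @param excluded_probes data.frame with columns `probe_id`, `reason`.
#' @param replicate_resolutions data.frame with columns `subject_id`,
#'   `kept`, `dropped` (comma-separated if several).
#' @return A `qc_report` list.
#' @export
qc_report <- function(n_arrays_in, n_arrays_out, n_probes_in, n_probes_out,
                      excluded_arrays = empty_excl("sample_id"),
                      excluded_probes = empty_excl("probe_id"),
                      replicate_resolutions = data.frame(
                        subject_id = character(), kept = character(),
                        dropped = character())) {
  stopifnot(n_arrays_out == n_arrays_in - nrow(excluded_arrays),
            n_probes_out == n_probes_in - nrow(excluded_probes))
  structure(list(n_arrays_in = n_arrays_in, n_arrays_out = n_arrays_out,
                 n_probes_in = n_probes_in, n_probes_out = n_probes_out,
                 excluded_arrays = excluded_arrays,
                 excluded_probes = excluded_probes,
                 replicate_resolutions = replicate_resolutions),
            class = "qc_report")
}

empty_excl <- function(id_col) {
  df <- data.frame(id = character(), reason = character(),
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  df
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: arrays %d -> %d, probes %d -> %d\n",
              x$n_arrays_in, x$n_arrays_out, x$n_probes_in, x$n_probes_out))
  if (nrow(x$excluded_arrays))
    cat("  excluded arrays:",
        paste(sprintf("%s (%s)", x$excluded_arrays$sample_id,
                      x$excluded_arrays$reason), collapse = ", "), "\n")
  if (nrow(x$excluded_probes))
    cat(sprintf("  excluded probes: %d\n", nrow(x$excluded_probes)))
  if (nrow(x$replicate_resolutions))
    cat(sprintf("  replicate resolutions: %d subjects\n",
                nrow(x$replicate_resolutions)))
  invisible(x)
}

combine_qc_reports <- function(reports) {
  first <- reports[[1]]; last <- reports[[length(reports)]]
  qc_report(first$n_arrays_in, last$n_arrays_out,
            first$n_probes_in, last$n_probes_out,
            excluded_arrays = do.call(rbind, lapply(reports, `[[`, "excluded_arrays")),
            excluded_probes = do.call(rbind, lapply(reports, `[[`, "excluded_probes")),
            replicate_resolutions = do.call(rbind, lapply(reports, `[[`,
                                                          "replicate_resolutions")))
}

#' Mask flagged cells as missing
#'
#' Cells whose quality flag exceeds 8191 (the manufacturer's unusable-spot
#' code boundary) are set to missing. The comparison is strict: a flag of
#' exactly 8191 is retained.
#'
#' @param expr an [expr_set()] with a flag matrix.
#' @param flag_cutoff flag threshold (default 8191).
#' @return The `expr_set` with masked values `NA`.
#' @export
mask_flagged <- function(expr, flag_cutoff = 8191) {
  if (is.null(expr$flags)) stop("expression set carries no flag matrix")
  v <- expr$values
  v[expr$flags > flag_cutoff] <- NA_real_
  expr_set(v, snr = expr$snr, flags = expr$flags, scale = expr$scale)
}

#' Resolve technical replicates
#'
#' For each subject hybridized on more than one array, keeps only the array
#' with the largest number of probes whose S/N exceeds 3 (strictly), i.e.
#' excludes the array(s) with the least detected probes. Ties are broken in
#' favour of the array appearing first in the input column order, and every
#' resolution is recorded.
#'
#' @param expr an [expr_set()] with an S/N matrix.
#' @param annotations an [annotation_table()] providing `subject_id`.
#' @param snr_cutoff detection threshold (default 3; strict `>`).
#' @return list `expr` (replicates removed), `report` (a [qc_report()]).
#' @export
resolve_replicates <- function(expr, annotations, snr_cutoff = 3) {
  if (is.null(expr$snr)) stop("expression set carries no S/N matrix")
  ann <- align_annotations(annotations, expr)
  counts <- colSums(expr$snr > snr_cutoff, na.rm = TRUE)
  keep <- rep(TRUE, ncol(expr$values))
  res <- list()
  for (subj in unique(ann$subject_id)) {
    idx <- which(ann$subject_id == subj)
    if (length(idx) < 2) next
    best <- idx[which.max(counts[idx])]  # which.max takes the first on ties
    drop <- setdiff(idx, best)
    keep[drop] <- FALSE
    res[[subj]] <- data.frame(subject_id = subj,
                              kept = sample_ids(expr)[best],
                              dropped = paste(sample_ids(expr)[drop],
                                              collapse = ","))
  }
  dropped_ids <- sample_ids(expr)[!keep]
  rep <- qc_report(ncol(expr$values), sum(keep),
                   nrow(expr$values), nrow(expr$values),
                   excluded_arrays = if (length(dropped_ids))
                     data.frame(sample_id = dropped_ids,
                                reason = "technical replicate with fewer detected probes")
                   else empty_excl("sample_id"),
                   replicate_resolutions = if (length(res)) do.call(rbind, res)
                   else data.frame(subject_id = character(), kept = character(),
                                   dropped = character()))
  list(expr = expr[, keep], report = rep)
}

#' Remove poorly detected arrays
#'
#' Arrays in which fewer than `min_fraction` of probes reach S/N >= 3
#' (inclusive) are removed. An array at exactly the threshold fraction is
#' kept: removal requires strictly less.
#'
#' @param expr an [expr_set()] with an S/N matrix.
#' @param snr_cutoff detection threshold (default 3, compared with `>=`).
#' @param min_fraction minimum detected fraction (default 0.40).
#' @return list `expr`, `report`.
#' @export
filter_arrays <- function(expr, snr_cutoff = 3, min_fraction = 0.40) {
  if (is.null(expr$snr)) stop("expression set carries no S/N matrix")
  frac <- colMeans(expr$snr >= snr_cutoff, na.rm = TRUE)
  keep <- frac >= min_fraction
  dropped <- sample_ids(expr)[!keep]
  rep <- qc_report(ncol(expr$values), sum(keep), nrow(expr$values), nrow(expr$values),
                   excluded_arrays = if (length(dropped))
                     data.frame(sample_id = dropped,
                                reason = sprintf("detected fraction below %.0f%%",
                                                 100 * min_fraction))
                   else empty_excl("sample_id"))
  list(expr = expr[, keep], report = rep)
}

#' Remove poorly detected probes
#'
#' Probes whose S/N exceeds 3 (strictly) in fewer than `min_fraction` of
#' the samples surviving earlier filters are dropped. A probe detected in
#' exactly half the samples is kept.
#'
#' @param expr an [expr_set()] with an S/N matrix.
#' @param snr_cutoff detection threshold (default 3, compared with `>`).
#' @param min_fraction minimum detected sample fraction (default 0.50).
#' @return list `expr`, `report`.
#' @export
filter_probes <- function(expr, snr_cutoff = 3, min_fraction = 0.50) {
  if (is.null(expr$snr)) stop("expression set carries no S/N matrix")
  frac <- rowMeans(expr$snr > snr_cutoff, na.rm = TRUE)
  keep <- frac >= min_fraction
  dropped <- probe_ids(expr)[!keep]
  rep <- qc_report(ncol(expr$values), ncol(expr$values), nrow(expr$values), sum(keep),
                   excluded_probes = if (length(dropped))
                     data.frame(probe_id = dropped,
                                reason = sprintf("detected in below %.0f%% of samples",
                                                 100 * min_fraction))
                   else empty_excl("probe_id"))
  list(expr = expr[keep, ], report = rep)
}

#' Log2 transformation and missing-aware quantile normalization
#'
#' Values still on the raw scale are log2-transformed first; each array's
#' observed values are then replaced by the mean of the order statistics
#' across arrays at the matching quantile rank (with missing cells, each
#' array's observed quantiles are interpolated onto the common grid, and
#' missingness is preserved). Delegates to [limma::normalizeQuantiles()].
#'
#' @param expr an [expr_set()].
#' @return The `expr_set`, log2 scale, quantile-normalized.
#' @export
quantile_normalize <- function(expr) {
  v <- expr$values
  if (expr$scale == "raw") {
    if (any(v <= 0, na.rm = TRUE)) stop("raw intensities must be positive")
    v <- log2(v)
  }
  if (any(colSums(!is.na(v)) == 0)) stop("array with all values missing")
  vn <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(vn) <- dimnames(v)
  expr_set(vn, snr = expr$snr, flags = expr$flags, scale = "log2")
}

#' k-nearest-neighbour imputation of missing values
#'
#' Each missing cell is filled with the inverse-distance-weighted mean of
#' the `k` nearest probes (probe neighbours, root-mean-square Euclidean
#' distance over co-observed samples) among probes observed at that sample.
#' Distance ties are broken by probe order. An exact duplicate (distance 0)
#' dominates: the imputed value is the mean of the zero-distance
#' neighbours. A probe with no co-observed neighbour values at a sample
#' falls back to its own observed mean; such cells are reported in the
#' `"fallback"` attribute.
#'
#' @param expr an [expr_set()], log2 scale.
#' @param k number of neighbours (default 10).
#' @return The `expr_set` with no missing values. Observed cells are never
#'   altered.
#' @export
knn_impute <- function(expr, k = 10, chunk = 512L) {
  stopifnot(expr$scale == "log2", k >= 1)
  v <- expr$values
  targets <- which(rowSums(is.na(v)) > 0)
  if (length(targets) == 0) return(expr)
  out <- v
  fallback <- character()
  obs <- !is.na(v)
  A <- v; A[!obs] <- 0
  M <- obs + 0
  A2 <- A * A
  tMA2 <- rbind(t(M), t(A2), t(A))  # stacked for a single crossprod per chunk
  for (start in seq(1, length(targets), by = chunk)) {
    idx <- targets[start:min(start + chunk - 1L, length(targets))]
    P <- cbind(A2[idx, , drop = FALSE], M[idx, , drop = FALSE],
               -2 * A[idx, , drop = FALSE]) %*% tMA2  # sum of sq diffs, co-observed
    co <- M[idx, , drop = FALSE] %*% t(M)
    d2 <- P / co  # mean squared difference; NaN where no co-observed sample
    d2[!is.finite(d2)] <- Inf
    d2[cbind(seq_along(idx), idx)] <- Inf  # never self
    d2[d2 < 0] <- 0  # numerical noise on exact duplicates
    for (i in seq_along(idx)) {
      g <- idx[i]
      ord <- order(d2[i, ], seq_len(nrow(v)))  # ties by probe order
      for (j in which(is.na(v[g, ]))) {
        cand <- ord[obs[ord, j] & is.finite(d2[i, ord])]
        if (length(cand) == 0) {
          out[g, j] <- mean(v[g, ], na.rm = TRUE)
          fallback <- c(fallback, sprintf("%s@%s", rownames(v)[g], colnames(v)[j]))
          next
        }
        nb <- cand[seq_len(min(k, length(cand)))]
        d <- sqrt(d2[i, nb])
        if (any(d == 0)) {
          out[g, j] <- mean(v[nb[d == 0], j])
        } else {
          w <- 1 / d
          out[g, j] <- sum(w * v[nb, j]) / sum(w)
        }
      }
    }
  }
  res <- expr_set(out, snr = expr$snr, flags = expr$flags, scale = "log2")
  attr(res, "fallback") <- fallback
  res
}

#' Full QC and preprocessing cascade
#'
#' Runs, in order: flag masking, technical replicate resolution, array
#' detection filter, probe detection filter, log2 transformation with
#' quantile normalization, and k-nearest-neighbour imputation. Stage counts
#' reconcile in the combined report.
#'
#' @param expr raw [expr_set()] with S/N and flag matrices.
#' @param annotations matching [annotation_table()].
#' @param flag_cutoff,snr_cutoff,array_min_fraction,probe_min_fraction,k
#'   stage thresholds, defaulting to the standard cascade (8191, 3, 0.40,
#'   0.50, 10).
#' @return list `expr` (normalized, imputed, log2), `annotations` (aligned
#'   to surviving arrays), `report` (combined [qc_report()]).
#' @export
qc_preprocess <- function(expr, annotations, flag_cutoff = 8191,
                          snr_cutoff = 3, array_min_fraction = 0.40,
                          probe_min_fraction = 0.50, k = 10) {
  e <- mask_flagged(expr, flag_cutoff)
  s1 <- resolve_replicates(e, annotations, snr_cutoff)
  s2 <- filter_arrays(s1$expr, snr_cutoff, array_min_fraction)
  s3 <- filter_probes(s2$expr, snr_cutoff, probe_min_fraction)
  e4 <- quantile_normalize(s3$expr)
  e5 <- knn_impute(e4, k)
  list(expr = e5,
       annotations = align_annotations(annotations, e5),
       report = combine_qc_reports(list(s1$report, s2$report, s3$report)))
}
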