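#' Curated gene set
#'
#' @param name set name.
#' @param members gene (or probe) identifiers.
#' @param source free-text provenance (publication, database).
#' @return A `gene_set` list.
#' @export
gene_set <- function(name, members, source = "") {
  stopifnot(is.character(name), length(name) == 1)
  structure(list(name = name, source = source,
                 member_ids = unique(as.character(members)),
                 mapped_probes = NULL, unmapped = NULL),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d members%s\n", x$name, length(x$member_ids),
              if (!is.null(x$mapped_probes))
                sprintf(", %d mapped probes", length(x$mapped_probes)) else ""))
  invisible(x)
}

#' Map gene-set members to measured probes
#'
#' Uses a two-column gene-to-probe mapping: genes represented by several
#' probes contribute all of them; members without any measured probe are
#' recorded in `unmapped`, never silently dropped.
#'
#' @param gs a [gene_set()].
#' @param map data.frame with columns `gene`, `probe` (or a path readable
#'   by [read_gene_map()]). `NULL` treats member ids as probe ids.
#' @param measured_probes character vector of probes on the platform.
#' @return The `gene_set` with `mapped_probes` and `unmapped` filled in.
#' @export
map_gene_set <- function(gs, map = NULL, measured_probes) {
  if (is.null(map)) {
    hits <- intersect(gs$member_ids, measured_probes)
    gs$mapped_probes <- hits
    gs$unmapped <- setdiff(gs$member_ids, measured_probes)
    return(gs)
  }
  stopifnot(all(c("gene", "probe") %in% names(map)))
  sub <- map[map$gene %in% gs$member_ids & map$probe %in% measured_probes, ,
             drop = FALSE]
  gs$mapped_probes <- unique(as.character(sub$probe))
  gs$unmapped <- setdiff(gs$member_ids, unique(as.character(sub$gene)))
  gs
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values in the input order (a thin wrapper over
#' [stats::p.adjust()], kept as the single FDR entry point of the
#' pipeline).
#'
#' @param pvals numeric vector of p-values.
#' @return Adjusted values, same order and length.
#' @export
adjust_fdr <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' Test one curated gene set against an outcome
#'
#' Set-level permutation p-value from the global test on the mapped
#' probes, plus core-member selection within the set (weighted z-score
#' rule) and per-core-probe directions.
#'
#' @param expr an [expr_set()] (log2, complete).
#' @param annotations an [annotation_table()].
#' @param outcome binary outcome variable name.
#' @param gs a mapped [gene_set()] (see [map_gene_set()]).
#' @param adjust adjustment term labels.
#' @param n_perm,seed permutation control.
#' @param w_tp,w_fp core-selection weights.
#' @return An `enrichment_row`: list `set`, `source`, `n_tested` (mapped
#'   probes), `n_members`, `p`, `set_z`, `core_up_group1`,
#'   `core_up_group0`, plus the underlying `scores` and `core` objects.
#' @export
test_gene_set <- function(expr, annotations, outcome, gs,
                          adjust = character(), n_perm = 1000, seed = NULL,
                          w_tp = 2, w_fp = 1) {
  if (is.null(gs$mapped_probes))
    gs <- map_gene_set(gs, NULL, rownames(expr_values(expr)))
  if (length(gs$mapped_probes) == 0)
    stop("gene set '", gs$name, "' maps to zero measured probes")
  sc <- global_test_scores(expr, annotations, outcome,
                           probe_set = gs$mapped_probes, adjust = adjust,
                           n_perm = n_perm, seed = seed)
  core <- select_core_weighted(sc, w_tp = w_tp, w_fp = w_fp)
  dir <- if (core$n_selected > 0)
    association_direction(expr, annotations, outcome, core$core_probes, adjust)
  else character()
  structure(list(set = gs$name, source = gs$source,
                 n_tested = length(gs$mapped_probes),
                 n_members = length(gs$member_ids),
                 p = sc$set_p, set_z = sc$set_z,
                 core_up_group1 = names(dir)[dir == "up-in-level-1"],
                 core_up_group0 = names(dir)[dir == "up-in-level-0"],
                 scores = sc, core = core),
            class = "enrichment_row")
}

#' Competitive comparative p-value for a gene set
#'
#' Fraction of random probe sets of the same size (drawn uniformly without
#' replacement from all measured probes) whose standardized global-test
#' statistic exceeds the query set's. Standardization by the permutation
#' moments makes the statistic comparable across sets of one size, and the
#' comparison is reported without an add-one correction so that very
#' extreme sets can report values such as 0.002 or exactly 0.
#'
#' @param expr an [expr_set()] (log2, complete).
#' @param annotations an [annotation_table()].
#' @param outcome binary outcome variable name.
#' @param gs a mapped [gene_set()], or a character vector of probe ids.
#' @param n_random number of random sets (default 1000).
#' @param seed integer seed (drives both the permutation null and the
#'   random draws).
#' @param adjust adjustment term labels.
#' @param n_perm permutations for the shared null.
#' @return The comparative p-value, with the observed and random set
#'   z-scores attached as attributes.
#' @export
comparative_pvalue <- function(expr, annotations, outcome, gs,
                               n_random = 1000, seed = NULL,
                               adjust = character(), n_perm = 1000) {
  Y <- expr_values(expr)
  probes <- if (inherits(gs, "gene_set")) {
    if (is.null(gs$mapped_probes)) gs <- map_gene_set(gs, NULL, rownames(Y))
    gs$mapped_probes
  } else as.character(gs)
  m <- length(probes)
  if (m == 0) stop("empty gene set")
  if (m > nrow(Y)) stop("set size exceeds the number of measured probes")
  eng <- gt_engine(expr, annotations, outcome, probe_set = NULL,
                   adjust = adjust, n_perm = n_perm, seed = seed)
  set_z <- function(idx) {
    qs <- colMeans(eng$Q_perm[idx, , drop = FALSE])
    s <- stats::sd(qs)
    if (s > 0) (mean(eng$Q_obs[idx]) - mean(qs)) / s else 0
  }
  z_obs <- set_z(match(probes, eng$probe_set))
  z_rand <- vapply(seq_len(n_random), function(b)
    set_z(sample.int(nrow(Y), m)), 0)
  p <- mean(z_rand > z_obs)
  attr(p, "z_obs") <- z_obs
  attr(p, "z_random") <- z_rand
  p
}

#' Enrichment analysis over a collection of curated gene sets
#'
#' Tests every set with the global test, adjusts the set p-values across
#' the batch by Benjamini-Hochberg, and (optionally) computes competitive
#' comparative p-values against random same-size sets.
#'
#' @param expr an [expr_set()] (log2, complete).
#' @param annotations an [annotation_table()].
#' @param outcome binary outcome variable name.
#' @param gene_sets list of [gene_set()]s.
#' @param map optional gene-to-probe mapping (see [map_gene_set()]).
#' @param adjust adjustment term labels.
#' @param n_perm,n_random,seed permutation / random-set control;
#'   `n_random = 0` skips comparative p-values.
#' @param w_tp,w_fp core-selection weights.
#' @return An `enrichment_table`: data.frame with columns `set`,
#'   `n_tested`, `p`, `fdr`, `comparative_p`, `n_core_up_group1`,
#'   `n_core_up_group0`, `core_up_group1`, `core_up_group0` (comma-joined),
#'   with the per-set `enrichment_row`s attached.
#' @export
enrichment_analysis <- function(expr, annotations, outcome, gene_sets,
                                map = NULL, adjust = character(),
                                n_perm = 1000, n_random = 1000,
                                seed = NULL, w_tp = 2, w_fp = 1) {
  measured <- rownames(expr_values(expr))
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2 * length(gene_sets))
  rows <- vector("list", length(gene_sets))
  for (i in seq_along(gene_sets)) {
    gs <- map_gene_set(gene_sets[[i]], map, measured)
    row <- test_gene_set(expr, annotations, outcome, gs, adjust = adjust,
                         n_perm = n_perm, seed = seeds[2 * i - 1],
                         w_tp = w_tp, w_fp = w_fp)
    row$comparative_p <- if (n_random > 0)
      as.numeric(comparative_pvalue(expr, annotations, outcome, gs,
                                    n_random = n_random, seed = seeds[2 * i],
                                    adjust = adjust, n_perm = n_perm))
    else NA_real_
    rows[[i]] <- row
  }
  tab <- data.frame(
    set = vapply(rows, `[[`, "", "set"),
    n_tested = vapply(rows, `[[`, 0L, "n_tested"),
    p = vapply(rows, `[[`, 0, "p"),
    fdr = adjust_fdr(vapply(rows, `[[`, 0, "p")),
    comparative_p = vapply(rows, function(r) r$comparative_p %||% NA_real_, 0),
    n_core_up_group1 = vapply(rows, function(r) length(r$core_up_group1), 0L),
    n_core_up_group0 = vapply(rows, function(r) length(r$core_up_group0), 0L),
    core_up_group1 = vapply(rows, function(r)
      paste(r$core_up_group1, collapse = ","), ""),
    core_up_group0 = vapply(rows, function(r)
      paste(r$core_up_group0, collapse = ","), ""),
    stringsAsFactors = FALSE)
  structure(tab, rows = rows, outcome = outcome, class = c("enrichment_table",
                                                           "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
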