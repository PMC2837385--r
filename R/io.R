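#' Read / write probe-by-sample matrices as tab-delimited text
#'
#' First column holds the probe id (header `probe_id`), remaining columns
#' one per sample. `write_matrix_tsv()` and `read_matrix_tsv()` round-trip
#' exactly (up to numeric formatting at full precision).
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @return `read_matrix_tsv()` returns the matrix; the writer returns the
#'   path invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id") stop("expected first column 'probe_id' in ", path)
  if (anyDuplicated(df$probe_id)) stop("duplicate probe ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  m
}

#' Read / write an annotation table with role declarations
#'
#' CSV with one row per array; variable roles are declared in a leading
#' comment line of the form
#' `# roles: lot=technical-random,freeze_days=technical-fixed,...`.
#'
#' @param annotations an [annotation_table()].
#' @param path file path.
#' @return `read_annotation_csv()` returns an [annotation_table()].
#' @export
write_annotation_csv <- function(annotations, path) {
  roles <- variable_roles(annotations)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# roles: ",
                    paste(sprintf("%s=%s", names(roles), roles),
                          collapse = ",")), con)
  utils::write.csv(as.data.frame(annotations), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# roles:", first))
    stop("annotation file lacks the '# roles:' declaration line")
  spec <- trimws(sub("^# roles:", "", first))
  pieces <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  roles <- vapply(pieces, `[`, "", 2)
  names(roles) <- vapply(pieces, `[`, "", 1)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (v in names(roles))
    if (!grepl(":", v, fixed = TRUE) && roles[[v]] == "technical-random")
      df[[v]] <- factor(df[[v]])
  annotation_table(df, roles)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description/source, then member ids, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @return list of [gene_set()]s.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 50))
    gene_set(f[1], members = f[-(1:2)], source = f[2])
  })
}

#' Read a two-column gene-to-probe mapping file
#'
#' Tab-delimited with header columns `gene` and `probe`.
#'
#' @param path file path.
#' @return data.frame with columns `gene`, `probe`.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "probe") %in% names(df)))
    stop("gene map needs 'gene' and 'probe' columns")
  df
}

#' Read an expression matrix from a GEO Series Matrix file
#'
#' Minimal read-only support for the Series Matrix dialect: the block
#' between `!series_matrix_table_begin` and `!series_matrix_table_end` is
#' parsed as a tab-delimited matrix with quoted sample accessions in the
#' header and probe ids in the first column (`ID_REF`).
#'
#' @param path Series Matrix file path.
#' @return numeric probe x sample matrix.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1 || length(end) != 1 || end <= beg + 1)
    stop("no series matrix table found in ", path)
  block <- lines[(beg + 1):(end - 1)]
  df <- utils::read.delim(text = block, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- gsub('^"|"$', "", names(df))
  ids <- gsub('^"|"$', "", as.character(df[[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Write a simulated cohort as the standard pipeline input files
#'
#' Emits `expression.tsv`, `snr.tsv`, `flags.tsv` (tab-delimited probe x
#' sample), `annotations.csv` (with role declarations) and `truth.txt`
#' (structured key-value text recording affected probes, variance
#' fractions and replicate pairs).
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(sim$expr$values, file.path(dir, "expression.tsv"))
  write_matrix_tsv(sim$expr$snr, file.path(dir, "snr.tsv"))
  write_matrix_tsv(sim$expr$flags, file.path(dir, "flags.tsv"))
  write_annotation_csv(sim$annotations, file.path(dir, "annotations.csv"))
  tr <- sim$truth
  con <- file(file.path(dir, "truth.txt"), "w")
  on.exit(close(con))
  writeLines(c(sprintf("variance_fraction_technical\t%.10g",
                       tr$variance_fraction_technical),
               sprintf("variance_fraction_biological\t%.10g",
                       tr$variance_fraction_biological)), con)
  for (v in names(tr$affected_probes))
    writeLines(sprintf("affected\t%s\t%s", v,
                       paste(tr$affected_probes[[v]], collapse = ",")), con)
  if (nrow(tr$replicate_pairs))
    writeLines(sprintf("replicate\t%s\t%s", tr$replicate_pairs$sample_1,
                       tr$replicate_pairs$sample_2), con)
  invisible(dir)
}

#' Pipeline configuration
#'
#' Collects the input paths, stage thresholds, permutation counts and the
#' master seed of an end-to-end run. The threshold defaults are the
#' standard cascade constants: flag cutoff 8191, S/N cutoff 3, array
#' detection fraction 0.40, probe detection fraction 0.50, k = 10
#' neighbours, screening alpha 0.001, core-selection weights 2 versus 1.
#'
#' @param expression,snr,flags,annotations paths to the input matrices and
#'   annotation CSV (ignored when `data` supplies in-memory objects).
#' @param gene_sets optional GMT path; `gene_map` optional gene-to-probe
#'   mapping path.
#' @param out_dir output directory; `NULL` disables persistence.
#' @param flag_cutoff,snr_cutoff,array_min_fraction,probe_min_fraction,k,alpha_screen,w_tp,w_fp
#'   stage thresholds.
#' @param n_perm_screen,n_perm_test,n_random permutation / random-set
#'   counts.
#' @param outcomes biological variables to run core selection for;
#'   `NULL` = all biological/exposure variables.
#' @param enrich_outcome variable used for gene-set enrichment (default:
#'   first outcome).
#' @param stages character vector of stages to run, a subset of
#'   `c("qc", "screen", "eigenr2", "select", "core", "unique", "enrich")`.
#' @param seed master seed; every stage derives its stream from it.
#' @param data optional list with in-memory `expr` ([expr_set()]),
#'   `annotations`, `gene_sets`, `gene_map`, bypassing the file readers.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression = NULL, snr = NULL, flags = NULL,
                            annotations = NULL, gene_sets = NULL,
                            gene_map = NULL, out_dir = NULL,
                            flag_cutoff = 8191, snr_cutoff = 3,
                            array_min_fraction = 0.40,
                            probe_min_fraction = 0.50, k = 10,
                            alpha_screen = 0.001, w_tp = 2, w_fp = 1,
                            n_perm_screen = 1000, n_perm_test = 1000,
                            n_random = 1000, outcomes = NULL,
                            enrich_outcome = NULL,
                            stages = c("qc", "screen", "eigenr2", "select",
                                       "core", "unique", "enrich"),
                            seed = 1L, data = NULL) {
  stopifnot(flag_cutoff > 0, snr_cutoff > 0, array_min_fraction > 0,
            probe_min_fraction > 0, k >= 1, alpha_screen > 0,
            w_tp > 0, w_fp > 0)
  structure(list(expression = expression, snr = snr, flags = flags,
                 annotations = annotations, gene_sets = gene_sets,
                 gene_map = gene_map, out_dir = out_dir,
                 flag_cutoff = flag_cutoff, snr_cutoff = snr_cutoff,
                 array_min_fraction = array_min_fraction,
                 probe_min_fraction = probe_min_fraction, k = k,
                 alpha_screen = alpha_screen, w_tp = w_tp, w_fp = w_fp,
                 n_perm_screen = n_perm_screen, n_perm_test = n_perm_test,
                 n_random = n_random, outcomes = outcomes,
                 enrich_outcome = enrich_outcome, stages = stages,
                 seed = as.integer(seed), data = data),
            class = "pipeline_config")
}

#' Read the pipeline inputs declared in a configuration
#'
#' Parses the expression / S/N / flag matrices (tab-delimited, probe rows),
#' the annotation CSV with role declarations and any GMT gene sets, and
#' cross-checks dimensions and sample coverage.
#'
#' @param config a [pipeline_config()].
#' @return list `expr` ([expr_set()]), `annotations`, `gene_sets` (possibly
#'   empty list), `gene_map` (or `NULL`).
#' @export
read_inputs <- function(config) {
  if (!is.null(config$data)) {
    d <- config$data
    return(list(expr = d$expr, annotations = d$annotations,
                gene_sets = d$gene_sets %||% list(),
                gene_map = d$gene_map))
  }
  vals <- read_matrix_tsv(config$expression)
  snr <- if (!is.null(config$snr)) read_matrix_tsv(config$snr)
  flags <- if (!is.null(config$flags)) read_matrix_tsv(config$flags)
  for (m in list(snr, flags)) if (!is.null(m) && !all(dim(m) == dim(vals)))
    stop("matrix dimension mismatch between inputs")
  ann <- read_annotation_csv(config$annotations)
  missing_ann <- setdiff(colnames(vals), ann$sample_id)
  if (length(missing_ann))
    stop("annotation missing sample(s): ",
         paste(utils::head(missing_ann, 5), collapse = ", "))
  extra <- setdiff(ann$sample_id, colnames(vals))
  if (length(extra))
    stop("annotation references sample(s) absent from the matrix: ",
         paste(utils::head(extra, 5), collapse = ", "))
  list(expr = expr_set(vals, snr = snr, flags = flags, scale = "raw"),
       annotations = ann,
       gene_sets = if (!is.null(config$gene_sets)) read_gmt(config$gene_sets)
                   else list(),
       gene_map = if (!is.null(config$gene_map)) read_gene_map(config$gene_map))
}

stage_seed <- function(config, offset) (config$seed * 1000L + offset) %% 2147483647L

#' Run the full analysis pipeline
#'
#' Executes the stages in the standard order — QC/preprocessing, technical
#' variable screen, eigenR2 variance decomposition, per-probe BIC model
#' selection, core-probe selection per biological variable, unique
#' biological association, curated gene-set enrichment — persisting each
#' stage's tables under `out_dir` when set. Deterministic given the
#' configuration and its seed.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return A `pipeline_result` list with elements `qc`, `screen`,
#'   `eigen_r2`, `association`, `core` (per-variable `core_selection`s),
#'   `unique`, `enrichment`, `config`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  inp <- read_inputs(config)
  res <- list(config = config)
  st <- config$stages
  expr <- inp$expr; ann <- inp$annotations

  if ("qc" %in% st) {
    say("stage qc")
    qc <- qc_preprocess(expr, ann, flag_cutoff = config$flag_cutoff,
                        snr_cutoff = config$snr_cutoff,
                        array_min_fraction = config$array_min_fraction,
                        probe_min_fraction = config$probe_min_fraction,
                        k = config$k)
    expr <- qc$expr; ann <- qc$annotations
    res$qc <- qc$report
  } else if (expr$scale == "raw") {
    expr <- quantile_normalize(expr)
    expr <- knn_impute(expr, config$k)
    ann <- align_annotations(ann, expr)
  }

  tech_random <- variables_with_role(ann, "technical-random")
  tech_fixed <- variables_with_role(ann, "technical-fixed")
  bio <- variables_with_role(ann, c("biological", "exposure"))
  inter <- variables_with_role(ann, "interaction")

  if ("screen" %in% st) {
    say("stage screen")
    res$screen <- screen_variables(expr, ann, c(tech_random, tech_fixed),
                                   alpha = config$alpha_screen,
                                   n_perm = config$n_perm_screen,
                                   seed = stage_seed(config, 2L))
  }

  if ("eigenr2" %in% st) {
    say("stage eigenr2")
    tech <- if (!is.null(res$screen) && length(res$screen$passed))
      names(res$screen$passed) else c(tech_random, tech_fixed)
    res$eigen_r2 <- list(
      technical = eigen_r2(expr, ann, tech),
      biological = eigen_r2(expr, ann, bio))
  }

  # without a screen stage no technical variable is admitted to the pool
  pool <- candidate_pool(ann, screen = res$screen %||%
    structure(list(passed = character()), class = "screen_result"))
  if ("select" %in% st) {
    say("stage select (%d probes)", nrow(expr$values))
    res$association <- build_association_matrix(expr, pool, ann,
                                                verbose = verbose)
  }

  outcomes <- config$outcomes %||% bio
  if ("core" %in% st && !is.null(res$association)) {
    say("stage core")
    res$core <- list()
    adjust <- intersect(pool$random_candidates, "lot")
    for (i in seq_along(outcomes)) {
      v <- outcomes[i]
      probes <- rownames(res$association$matrix)[res$association$matrix[, v] == 1L]
      if (length(probes) == 0) {
        res$core[[v]] <- structure(
          list(variable = v, threshold = Inf, fdr_at_threshold = NA_real_,
               core_probes = character(), utility = 0, n_selected = 0L,
               w_tp = config$w_tp, w_fp = config$w_fp, p_method = "normal"),
          class = "core_selection")
        next
      }
      sc <- global_test_scores(expr, ann, v, probe_set = probes,
                               adjust = adjust,
                               n_perm = config$n_perm_test,
                               seed = stage_seed(config, 10L + i))
      res$core[[v]] <- select_core_weighted(sc, config$w_tp, config$w_fp)
    }
  }

  if ("unique" %in% st && !is.null(res$association)) {
    say("stage unique")
    permitted <- intersect("lot", colnames(res$association$matrix))
    res$unique <- unique_biological(res$association, permitted = permitted)
  }

  if ("enrich" %in% st && length(inp$gene_sets)) {
    say("stage enrich")
    outcome <- config$enrich_outcome %||% outcomes[1]
    res$enrichment <- enrichment_analysis(
      expr, ann, outcome, inp$gene_sets, map = inp$gene_map,
      n_perm = config$n_perm_test, n_random = config$n_random,
      seed = stage_seed(config, 99L), w_tp = config$w_tp, w_fp = config$w_fp)
  }

  res$expr <- expr
  res$annotations <- ann
  class(res) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_report(res, config$out_dir)
  res
}

#' Write the pipeline report tables
#'
#' Emits tab-delimited, deterministically ordered tables: a per-variable
#' summary (probes selected, core probes, FDR at the chosen threshold), a
#' QC reconciliation table, the enrichment table (tested probes, p-value,
#' FDR adjusted, comparative p-value, core probes by direction), plus a
#' provenance record of the configuration and seed.
#'
#' @param res a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$qc)) {
    qc <- res$qc
    df <- data.frame(metric = c("arrays_in", "arrays_out", "probes_in",
                                "probes_out"),
                     value = c(qc$n_arrays_in, qc$n_arrays_out,
                               qc$n_probes_in, qc$n_probes_out))
    utils::write.table(df, file.path(dir, "qc_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(qc$excluded_arrays, file.path(dir, "qc_excluded_arrays.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$association)) {
    A <- res$association$matrix
    cores <- res$core %||% list()
    vars <- colnames(A)
    tab <- data.frame(
      variable = vars,
      n_probes = colSums(A),
      n_core = vapply(vars, function(v)
        if (!is.null(cores[[v]])) cores[[v]]$n_selected else NA_integer_, 0L),
      fdr_at_threshold = vapply(vars, function(v)
        if (!is.null(cores[[v]])) cores[[v]]$fdr_at_threshold else NA_real_, 0),
      stringsAsFactors = FALSE)
    utils::write.table(tab, file.path(dir, "variable_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_matrix_tsv(res$association$matrix + 0,
                     file.path(dir, "association_matrix.tsv"))
  }
  if (!is.null(res$eigen_r2)) {
    df <- data.frame(variable_set = names(res$eigen_r2),
                     eigen_r2 = vapply(res$eigen_r2, `[[`, 0, "eigen_r2"))
    utils::write.table(df, file.path(dir, "eigen_r2.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$screen))
    utils::write.table(res$screen$table, file.path(dir, "screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$enrichment))
    utils::write.table(as.data.frame(res$enrichment),
                       file.path(dir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$unique)) {
    df <- data.frame(variable = names(res$unique),
                     n_unique = vapply(res$unique, length, 0L),
                     probes = vapply(res$unique, paste, "", collapse = ","))
    utils::write.table(df, file.path(dir, "unique_biological.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  cfg <- res$config
  prov <- c(sprintf("seed\t%d", cfg$seed),
            sprintf("bloodvar_version\t%s",
                    as.character(utils::packageVersion("bloodvar"))),
            sprintf("r_version\t%s", R.version.string),
            sprintf("stages\t%s", paste(cfg$stages, collapse = ",")))
  writeLines(prov, file.path(dir, "provenance.txt"))
  invisible(dir)
}
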