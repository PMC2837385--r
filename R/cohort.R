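#' Configuration for the synthetic blood-expression cohort generator
#'
#' Describes a cohort of postmenopausal blood donors profiled on a
#' single-channel microarray, with the variance structure such studies
#' exhibit: crossed batch random effects (array lot, RNA extraction date),
#' a fixed RNA-degradation covariate (days between blood collection and
#' freezing, at most 3), binary biological/exposure covariates at realistic
#' prevalences whose effects touch only a fraction of probes, and Gaussian
#' residual noise. Defaults mirror a cohort of 289 subjects (304 arrays
#' once 15 technical replicate pairs are spiked in) measured on 16185
#' probes.
#'
#' @param n_samples number of subjects (one array each before replicates).
#' @param n_probes number of probes.
#' @param n_lots,n_extraction_dates number of array lots / extraction
#'   dates. Defaults scale with cohort size (about 30 arrays per lot and 24
#'   extractions per day, typical batch sizes for this kind of study).
#' @param sd_lot,sd_extraction SD (log2 units) of the per-probe random
#'   intercepts for array lot and extraction date.
#' @param beta_freeze SD (log2 units per day) of the per-probe degradation
#'   slopes on time-to-freezing (probes degrade in both directions and at
#'   different rates; slopes are drawn `N(0, beta_freeze^2)`).
#' @param covariate_prevalences named probabilities for the binary
#'   biological/exposure covariates (age class split, fasting, BMI class,
#'   smoking, hormone therapy `ht`, medication use `med`).
#' @param effect_fraction named fractions of probes carrying each
#'   covariate's effect (keys may include the `"ht:med"` interaction).
#' @param effect_size named mean log2 shifts for affected probes (random
#'   sign per probe).
#' @param sd_resid residual SD (log2 units).
#' @param n_replicate_pairs technical replicate pairs to spike in.
#' @param n_decoy_technical extra reported technical covariates with no
#'   expression effect (the generator exposes a configurable number of
#'   decoys rather than a fixed schema).
#' @param frac_undetected target fraction of cells falling below the S/N
#'   detection threshold per array (drives the per-array noise constant).
#' @param flag_fail_fraction fraction of cells receiving a quality flag
#'   above 8191 (masked as missing downstream).
#' @param seed integer seed; all generator randomness flows from it.
#'
#' @return A `cohort_config` list, validated.
#' @seealso [calibrate_variance_fractions()], [simulate_cohort()]
#' @export
cohort_config <- function(n_samples = 289L,
                          n_probes = 16185L,
                          n_lots = NULL,
                          n_extraction_dates = NULL,
                          sd_lot = 0.37,
                          sd_extraction = 0.26,
                          beta_freeze = 0.25,
                          covariate_prevalences = c(age_class = 0.5,
                                                    fasting = 28 / 286,
                                                    bmi_class = 0.478,
                                                    smoking = 0.25,
                                                    ht = 0.30,
                                                    med = 0.582),
                          effect_fraction = c(age_class = 0.0025,
                                              fasting = 0.841,
                                              bmi_class = 0.191,
                                              smoking = 0.187,
                                              ht = 0.355,
                                              med = 0.534,
                                              "ht:med" = 0.112),
                          effect_size = NULL,
                          sd_resid = 0.5,
                          n_replicate_pairs = 15L,
                          n_decoy_technical = 5L,
                          frac_undetected = 0.5,
                          flag_fail_fraction = 0.01,
                          seed = NULL) {
  if (is.null(n_lots)) n_lots <- max(2L, round(n_samples / 30))
  if (is.null(n_extraction_dates))
    n_extraction_dates <- max(2L, round(n_samples / 24))
  if (is.null(effect_size)) {
    effect_size <- rep(0.35, length(effect_fraction))
    names(effect_size) <- names(effect_fraction)
  }
  cfg <- list(n_samples = as.integer(n_samples),
              n_probes = as.integer(n_probes),
              n_lots = as.integer(n_lots),
              n_extraction_dates = as.integer(n_extraction_dates),
              sd_lot = sd_lot, sd_extraction = sd_extraction,
              beta_freeze = beta_freeze,
              covariate_prevalences = covariate_prevalences,
              effect_fraction = effect_fraction,
              effect_size = effect_size,
              sd_resid = sd_resid,
              n_replicate_pairs = as.integer(n_replicate_pairs),
              n_decoy_technical = as.integer(n_decoy_technical),
              frac_undetected = frac_undetected,
              flag_fail_fraction = flag_fail_fraction,
              seed = seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 1, cfg$n_probes >= 1,
            cfg$n_lots >= 1, cfg$n_extraction_dates >= 1)
  if (any(c(cfg$sd_lot, cfg$sd_extraction, cfg$sd_resid) < 0))
    stop("SDs must be non-negative")
  if (any(cfg$covariate_prevalences < 0 | cfg$covariate_prevalences > 1))
    stop("prevalences must lie in [0,1]")
  if (any(cfg$effect_fraction < 0 | cfg$effect_fraction > 1))
    stop("effect fractions must lie in [0,1]")
  if (any(cfg$effect_size < 0)) stop("effect sizes must be non-negative")
  extra <- setdiff(names(cfg$effect_fraction),
                   c(names(cfg$covariate_prevalences),
                     interaction_labels(names(cfg$covariate_prevalences))))
  if (length(extra))
    stop("effect_fraction names unknown: ", paste(extra, collapse = ", "))
  invisible(cfg)
}

interaction_labels <- function(vars) {
  if (length(vars) < 2) return(character())
  cmb <- utils::combn(vars, 2)
  c(paste(cmb[1, ], cmb[2, ], sep = ":"), paste(cmb[2, ], cmb[1, ], sep = ":"))
}

# Designed (population) per-probe variance contributions implied by a
# config. With L realized batch levels the across-sample variance of a
# balanced random intercept has expectation sigma^2 (L-1)/L (the L draws
# are centered at their own mean), so the finite-level factors enter here
# and the recorded truth matches the design in expectation.
designed_variances <- function(cfg) {
  v_days <- 9 / 12  # variance of U(0, 3) days to freezing
  L <- cfg$n_lots; D <- cfg$n_extraction_dates
  v_tech <- cfg$sd_lot^2 * (L - 1) / L +
    cfg$sd_extraction^2 * (D - 1) / D +
    cfg$beta_freeze^2 * v_days
  p <- cfg$covariate_prevalences
  var_x <- function(v) {
    if (grepl(":", v, fixed = TRUE)) {
      pp <- strsplit(v, ":", fixed = TRUE)[[1]]
      q <- p[pp[1]] * p[pp[2]]
    } else q <- p[v]
    unname(q * (1 - q))
  }
  v_bio <- sum(vapply(names(cfg$effect_fraction), function(v)
    cfg$effect_fraction[[v]] * cfg$effect_size[[v]]^2 * var_x(v), 0))
  list(technical = v_tech, biological = v_bio, residual = cfg$sd_resid^2)
}

#' Calibrate a cohort configuration to target variance fractions
#'
#' Rescales the technical SDs (`sd_lot`, `sd_extraction`, `beta_freeze`)
#' and the covariate effect sizes by common factors so that the designed
#' fractions of per-probe variance attributable to technical and to
#' biological/exposure sources equal the requested targets, holding
#' `sd_resid` fixed. The relative mix within each source is preserved.
#'
#' @param config a [cohort_config()].
#' @param technical,biological target variance fractions (must sum to
#'   less than 1).
#' @return The rescaled config, with `designed_fractions` recorded.
#' @export
calibrate_variance_fractions <- function(config, technical, biological) {
  stopifnot(technical >= 0, biological >= 0, technical + biological < 1)
  v <- designed_variances(config)
  resid_frac <- 1 - technical - biological
  a <- if (v$technical > 0) sqrt((technical / resid_frac) * v$residual / v$technical) else 0
  b <- if (v$biological > 0) sqrt((biological / resid_frac) * v$residual / v$biological) else 0
  config$sd_lot <- config$sd_lot * a
  config$sd_extraction <- config$sd_extraction * a
  config$beta_freeze <- config$beta_freeze * a
  config$effect_size <- config$effect_size * b
  config$designed_fractions <- c(technical = technical, biological = biological)
  config
}

#' Generate the per-sample annotation table for a synthetic cohort
#'
#' Assigns each subject an array lot and an RNA extraction date (balanced
#' random assignment, crossed factors), a time-to-freezing in days (uniform
#' on 0–3; samples are frozen within 3 days), the configured number of
#' decoy technical covariates, and binary biological/exposure covariates
#' drawn at the configured prevalences.
#'
#' @param config a [cohort_config()].
#' @return An [annotation_table()] with one row per sample and all roles
#'   tagged.
#' @export
generate_annotations <- function(config) {
  validate_cohort_config(config)
  n <- config$n_samples
  if (config$n_lots > n) stop("n_lots exceeds n_samples")
  if (config$n_extraction_dates > n) stop("n_extraction_dates exceeds n_samples")
  if (!is.null(config$seed)) set.seed(config$seed)
  df <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                   subject_id = sprintf("subj%04d", seq_len(n)),
                   stringsAsFactors = FALSE)
  df$lot <- factor(sprintf("lot%02d", sample(rep_len(seq_len(config$n_lots), n))))
  df$extraction_date <- factor(sprintf("xd%02d",
    sample(rep_len(seq_len(config$n_extraction_dates), n))))
  df$freeze_days <- stats::runif(n, 0, 3)
  roles <- c(lot = "technical-random", extraction_date = "technical-random",
             freeze_days = "technical-fixed")
  if (config$n_decoy_technical > 0) {
    for (k in seq_len(config$n_decoy_technical)) {
      nm <- sprintf("tech_decoy%d", k)
      df[[nm]] <- stats::rnorm(n)
      roles[nm] <- "technical-fixed"
    }
  }
  prev <- config$covariate_prevalences
  bio <- c("age_class", "fasting", "bmi_class")
  for (v in names(prev)) {
    df[[v]] <- stats::rbinom(n, 1L, prev[[v]])
    roles[v] <- if (v %in% bio) "biological" else "exposure"
  }
  if ("ht:med" %in% names(config$effect_fraction)) roles["ht:med"] <- "interaction"
  annotation_table(df, roles)
}

#' Generate a synthetic expression matrix with recorded ground truth
#'
#' Per-probe model on the log2 scale:
#' baseline + lot intercept + extraction-date intercept +
#' slope x days-to-freezing + covariate shifts (on affected probes only) +
#' Gaussian residual. Baselines are drawn from a long-tailed distribution
#' (6 + Exp(rate 1/2)) so that quantile normalization is non-trivial.
#' Random intercepts are probe-specific and crossed. Returned values are
#' raw-scale intensities (`2^log2`).
#'
#' @param annotations output of [generate_annotations()].
#' @param config the same [cohort_config()].
#' @return list with elements `expr` (an [expr_set()], raw scale, no S/N or
#'   flags yet) and `truth` (a `cohort_truth`: per-variable affected probe
#'   sets, realized technical/biological variance fractions computed from
#'   the simulated components, empty replicate list).
#' @export
generate_expression <- function(annotations, config) {
  validate_cohort_config(config)
  G <- config$n_probes
  n <- nrow(annotations)
  pid <- sprintf("p%05d", seq_len(G))
  baseline <- 6 + stats::rexp(G, rate = 1 / 2)

  lot_idx <- as.integer(annotations$lot)
  xd_idx <- as.integer(annotations$extraction_date)
  lot_eff <- matrix(stats::rnorm(G * nlevels(annotations$lot), 0, config$sd_lot),
                    nrow = G)
  xd_eff <- matrix(stats::rnorm(G * nlevels(annotations$extraction_date), 0,
                                config$sd_extraction), nrow = G)
  slope <- stats::rnorm(G, 0, config$beta_freeze)
  tech <- lot_eff[, lot_idx, drop = FALSE] + xd_eff[, xd_idx, drop = FALSE] +
    outer(slope, annotations$freeze_days)

  bio <- matrix(0, G, n)
  affected <- list()
  for (v in names(config$effect_fraction)) {
    m <- round(config$effect_fraction[[v]] * G)
    idx <- if (m > 0) sort(sample.int(G, m)) else integer()
    affected[[v]] <- pid[idx]
    if (m == 0) next
    x <- if (grepl(":", v, fixed = TRUE)) {
      pp <- strsplit(v, ":", fixed = TRUE)[[1]]
      annotations[[pp[1]]] * annotations[[pp[2]]]
    } else annotations[[v]]
    beta <- sample(c(-1, 1), m, replace = TRUE) * config$effect_size[[v]]
    bio[idx, ] <- bio[idx, ] + outer(beta, as.numeric(x))
  }

  resid <- matrix(stats::rnorm(G * n, 0, config$sd_resid), G, n)
  log2_mat <- baseline + tech + bio + resid

  row_var <- function(m) {
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (ncol(m) - 1)
  }
  vt <- sum(row_var(tech)); vb <- sum(row_var(bio)); ve <- sum(row_var(resid))
  tot <- vt + vb + ve
  truth <- cohort_truth(affected_probes = affected,
                        variance_fraction_technical = vt / tot,
                        variance_fraction_biological = vb / tot,
                        replicate_pairs = data.frame(sample_1 = character(),
                                                     sample_2 = character()))
  expr <- expr_set(2^log2_mat, probe_ids = pid,
                   sample_ids = annotations$sample_id, scale = "raw")
  list(expr = expr, truth = truth)
}

#' Ground-truth record for a synthetic cohort
#'
#' @param affected_probes named list mapping each covariate to the probe
#'   ids carrying its effect.
#' @param variance_fraction_technical,variance_fraction_biological realized
#'   fractions of total per-probe variance, computed from the simulated
#'   components.
#' @param replicate_pairs data.frame of spiked technical replicate pairs.
#' @return A `cohort_truth` list.
#' @export
cohort_truth <- function(affected_probes, variance_fraction_technical,
                         variance_fraction_biological, replicate_pairs) {
  stopifnot(variance_fraction_technical >= 0, variance_fraction_technical <= 1,
            variance_fraction_biological >= 0, variance_fraction_biological <= 1)
  if (variance_fraction_technical + variance_fraction_biological > 1)
    stop("variance fractions jointly exceed 1")
  structure(list(affected_probes = affected_probes,
                 variance_fraction_technical = variance_fraction_technical,
                 variance_fraction_biological = variance_fraction_biological,
                 replicate_pairs = replicate_pairs),
            class = "cohort_truth")
}

#' Simulate the detection layer: signal-to-noise ratios and quality flags
#'
#' S/N is intensity divided by a per-array noise constant, with
#' multiplicative log-normal jitter (truncated at 2.5 SD). The noise
#' constant is set so that about `frac_undetected` of the array's cells
#' fall below S/N 3 (with `frac_undetected = 0` every cell is strictly
#' above 3). A random `flag_fail_fraction` of cells receives a flag above
#' 8191 (and S/N is irrelevant for such cells downstream: they are masked).
#' All other flags are 0.
#'
#' @param expr an [expr_set()] with raw-scale values.
#' @param config a [cohort_config()].
#' @return The `expr_set` with `snr` and `flags` filled in.
#' @export
simulate_detection <- function(expr, config) {
  stopifnot(expr$scale == "raw")
  v <- expr$values
  G <- nrow(v); n <- ncol(v)
  jit <- function(k) {
    u <- stats::runif(k, stats::pnorm(-2.5), stats::pnorm(2.5))
    exp(0.1 * stats::qnorm(u))
  }
  snr <- matrix(0, G, n)
  for (j in seq_len(n)) {
    cj <- if (config$frac_undetected > 0)
      stats::quantile(v[, j], config$frac_undetected, names = FALSE) / 3
    else min(v[, j]) / (3 * exp(0.26))  # keeps every jittered cell above 3
    snr[, j] <- (v[, j] / cj) * jit(G)
  }
  flags <- matrix(0L, G, n)
  if (config$flag_fail_fraction > 0) {
    fail <- which(stats::runif(G * n) < config$flag_fail_fraction)
    flags[fail] <- 8192L + sample.int(1000L, length(fail), replace = TRUE)
  }
  expr_set(v, snr = snr, flags = flags, scale = "raw")
}

#' Spike technical replicate arrays into a cohort
#'
#' Duplicates `n_pairs` randomly chosen subjects' arrays with fresh
#' technical noise (log-scale hybridization noise of SD `noise_sd`, fresh
#' S/N jitter, fresh flag failures), appends them as new arrays sharing the
#' subject identity, and records the pairs in the ground truth.
#'
#' @param expr an [expr_set()] (raw scale, with S/N and flags).
#' @param annotations matching [annotation_table()].
#' @param n_pairs number of replicate pairs.
#' @param seed optional integer seed.
#' @param noise_sd log2-scale SD of the replicate hybridization noise.
#' @param flag_fail_fraction flag failure rate for the new arrays.
#' @return list `expr`, `annotations`, `replicate_pairs` (data.frame).
#' @export
spike_replicates <- function(expr, annotations, n_pairs, seed = NULL,
                             noise_sd = 0.2, flag_fail_fraction = 0.01) {
  n <- ncol(expr$values)
  if (n_pairs > n) stop("n_pairs exceeds number of samples")
  if (!is.null(seed)) set.seed(seed)
  pairs <- data.frame(sample_1 = character(), sample_2 = character())
  if (n_pairs == 0) return(list(expr = expr, annotations = annotations,
                                replicate_pairs = pairs))
  G <- nrow(expr$values)
  pick <- sort(sample.int(n, n_pairs))
  new_vals <- expr$values[, pick, drop = FALSE] *
    2^matrix(stats::rnorm(G * n_pairs, 0, noise_sd), G)
  new_snr <- expr$snr[, pick, drop = FALSE] *
    exp(matrix(stats::rnorm(G * n_pairs, 0, 0.1), G))
  new_flags <- matrix(0L, G, n_pairs)
  fail <- which(stats::runif(G * n_pairs) < flag_fail_fraction)
  new_flags[fail] <- 8192L + sample.int(1000L, length(fail), replace = TRUE)
  new_ids <- paste0(colnames(expr$values)[pick], "_r2")
  vals <- cbind(expr$values, new_vals)
  snr <- cbind(expr$snr, new_snr)
  flags <- cbind(expr$flags, new_flags)
  colnames(vals) <- colnames(snr) <- colnames(flags) <-
    c(colnames(expr$values), new_ids)
  new_ann <- as.data.frame(annotations)[pick, , drop = FALSE]
  new_ann$sample_id <- new_ids
  out_ann <- rbind(as.data.frame(annotations), new_ann)
  out_ann <- annotation_table(out_ann, variable_roles(annotations))
  pairs <- data.frame(sample_1 = colnames(expr$values)[pick],
                      sample_2 = new_ids, stringsAsFactors = FALSE)
  list(expr = expr_set(vals, snr = snr, flags = flags, scale = "raw"),
       annotations = out_ann, replicate_pairs = pairs)
}

#' Simulate a complete synthetic cohort
#'
#' Runs annotation generation, expression generation, the detection layer
#' and replicate spiking in sequence, all driven by `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `expr` (raw-scale [expr_set()] with S/N and flags),
#'   `annotations`, `truth` (a `cohort_truth` including replicate pairs)
#'   and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  ann <- generate_annotations(config)
  gen <- generate_expression(ann, config)
  expr <- simulate_detection(gen$expr, config)
  rep <- spike_replicates(expr, ann, config$n_replicate_pairs,
                          flag_fail_fraction = config$flag_fail_fraction)
  truth <- gen$truth
  truth$replicate_pairs <- rep$replicate_pairs
  list(expr = rep$expr, annotations = rep$annotations,
       truth = truth, config = config)
}
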