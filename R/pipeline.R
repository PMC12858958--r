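#' Configuration for an end-to-end evaluation run
#'
#' Validates and bundles everything [run_pipeline()] needs. Exactly one
#' input mode must be active: synthetic mode (a [simulation_config()]
#' plus a [rate_table()]) or real-input mode (paths to a cohort table
#' and rate table on disk; scores must already be present in the cohort
#' table). Defaults mirror the analysis conventions: 5 PGS quantiles,
#' a 1.2% absolute-risk threshold referenced to age 50, top fractions
#' 10/25/50%, a 10-incident-case minimum per reported stratum and 2000
#' bootstrap replicates for AUC intervals.
#'
#' @param sim Optional [simulation_config()] (synthetic mode).
#' @param rates A [rate_table()] (synthetic mode) — or `NULL` when
#'   `rate_table_path` is given.
#' @param cohort_path,rate_table_path File paths (real-input mode).
#' @param n_quantiles Quantile count for relative risks (default 5).
#' @param risk_threshold Absolute-risk threshold (default 0.012).
#' @param reference_age Reference screening age in years (default 50).
#' @param top_fractions Fractions for case-capture reporting.
#' @param min_stratum_cases Minimum incident cases per stratum.
#' @param B_auc Bootstrap replicates for AUC CIs.
#' @param seed Global integer seed.
#' @param output_dir Directory for written tables and the manifest, or
#'   `NULL` to skip writing.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(sim = NULL, rates = NULL, cohort_path = NULL,
                            rate_table_path = NULL, n_quantiles = 5L,
                            risk_threshold = 0.012, reference_age = 50,
                            top_fractions = c(0.10, 0.25, 0.50),
                            min_stratum_cases = 10L, B_auc = 2000L,
                            seed = 1L, output_dir = NULL) {
  synthetic <- !is.null(sim)
  real <- !is.null(cohort_path)
  if (synthetic == real)
    stop("exactly one of synthetic mode (sim=) or real-input mode ",
         "(cohort_path=) must be active", call. = FALSE)
  if (synthetic) stopifnot(inherits(sim, "simulation_config"),
                           inherits(rates, "rate_table"))
  if (risk_threshold <= 0 || risk_threshold >= 1)
    stop("risk_threshold must lie in (0, 1)", call. = FALSE)
  if (any(top_fractions <= 0 | top_fractions > 1))
    stop("top_fractions must lie in (0, 1]", call. = FALSE)
  if (min_stratum_cases < 1)
    stop("min_stratum_cases must be >= 1", call. = FALSE)
  structure(list(mode = if (synthetic) "synthetic" else "real",
                 sim = sim, rates = rates, cohort_path = cohort_path,
                 rate_table_path = rate_table_path,
                 n_quantiles = as.integer(n_quantiles),
                 risk_threshold = risk_threshold,
                 reference_age = reference_age,
                 top_fractions = top_fractions,
                 min_stratum_cases = as.integer(min_stratum_cases),
                 B_auc = as.integer(B_auc), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "analysis_config")
}

#' Run the full PGS risk-evaluation pipeline
#'
#' Orchestrates the analysis end-to-end: obtain a cohort (generated
#' under the liability model in synthetic mode, or read from disk),
#' standardize PGS within subgroups, map each subgroup's observed AUC
#' and case proportion to a liability model, derive estimated and
#' observed quantile relative risks, build age- and age-PGS-specific
#' absolute risks from the rate table, and evaluate discrimination
#' (AUC, DeLong comparisons of Z-score vs age-only vs age-PGS risk),
#' calibration (E/O), case capture and the threshold-crossing screening
#' ages. All randomness derives from the configured seed, so a repeated
#' run is identical; when `output_dir` is set, tables, a JSON report and
#' a manifest (seed, config hash, file hashes) are written.
#'
#' @param config An [analysis_config()].
#' @return A list of class `"pipeline_result"` with elements `cohort`,
#'   `models` (per-subgroup liability models), `quantile_rr` (estimated
#'   and observed, per subgroup), `surface`, `crossing`, `evaluation`
#'   (an `"evaluation_report"`), `capture`, `threshold`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  log_stage <- function(stage, ...)
    message(sprintf("[pgsrisk] %-18s %s", stage, sprintf(...)))
  if (config$mode == "synthetic") {
    rates <- config$rates
    cohort <- simulate_liability_cohort(config$sim)
    log_stage("simulate", "n=%d cases=%d", nrow(cohort),
              sum(cohort$incident_case_5y))
  } else {
    cohort <- read_cohort_table(config$cohort_path)
    rates <- read_rate_table(config$rate_table_path)
    if (!"raw_score" %in% names(cohort))
      stop("real-input mode expects a raw_score column in the cohort table",
           call. = FALSE)
    log_stage("load", "n=%d from %s", nrow(cohort), config$cohort_path)
  }

  # within-subgroup standardization of the raw PGS
  cohort <- standardize_within_group(cohort, cohort$subgroup)
  log_stage("standardize", "%d subgroup(s)",
            length(unique(cohort$subgroup)))

  # per-subgroup liability models and quantile relative risks
  subgroups <- sort(unique(cohort$subgroup))
  models <- list(); qrr <- list()
  for (g in subgroups) {
    sub <- cohort[cohort$subgroup == g, ]
    case <- sub$incident_case_5y
    a <- max(auc(sub$z_score, case), 0.5)
    K <- sum(sub$design_weight * case) / sum(sub$design_weight)
    m <- liability_model(K = K, auc = a)
    est <- quantile_relative_risks(m, config$n_quantiles)
    obs <- observed_quantile_rr(sub$z_score, case,
                                n_quantiles = config$n_quantiles)
    tab <- merge(est, obs, by = "quantile_index",
                 suffixes = c("_theoretical", "_empirical"))
    tab$subgroup <- g
    models[[g]] <- m
    qrr[[g]] <- tab
    log_stage("liability", "%s: AUC=%.3f K=%.4f rho=%.3f", g, a, K, m$rho)
  }
  quantile_rr <- do.call(rbind, qrr)

  # absolute risks: age-only and age-PGS per individual
  cohort$age_risk <- age_specific_risk(rates, cohort$age_band)
  rr_ind <- numeric(nrow(cohort))
  for (g in subgroups) {
    i <- cohort$subgroup == g
    rr_ind[i] <- individual_relative_risk(cohort$z_score[i], models[[g]])
  }
  cohort$predicted_risk <- age_pgs_risk(cohort$age_risk, rr_ind)
  log_stage("absolute_risk", "mean age risk %.4f, mean age-PGS risk %.4f",
            mean(cohort$age_risk), mean(cohort$predicted_risk))

  # risk surface and screening-age shifts (first subgroup's RRs)
  ages <- rates$age_low
  surface <- risk_surface(rates, data.frame(
    stratum = sprintf("q%d", qrr[[1]]$quantile_index),
    rr = qrr[[1]]$estimated_rr), ages)
  crossing <- threshold_crossing_age(surface, config$risk_threshold,
                                     config$reference_age)

  # discrimination + calibration by subgroup
  evaluation <- stratified_evaluate(
    cohort, strata = "subgroup",
    score_cols = c("z_score", "age_risk", "predicted_risk"),
    risk_cols = c("age_risk", "predicted_risk"),
    min_cases = config$min_stratum_cases, B = config$B_auc,
    seed = substream_seed(config$seed, "evaluate"))
  log_stage("evaluate", "%d strata evaluated, %d skipped",
            nrow(evaluation$strata), nrow(evaluation$skipped))

  capture <- case_capture(cohort$z_score, cohort$incident_case_5y,
                          config$top_fractions)
  threshold <- proportion_above_threshold(cohort, config$risk_threshold)

  bundle <- list(cohort = cohort, models = models,
                 quantile_rr = quantile_rr, surface = surface,
                 crossing = crossing, evaluation = evaluation,
                 capture = capture, threshold = threshold)
  bundle$manifest <- list(
    package = "pgsrisk",
    version = as.character(utils::packageVersion("pgsrisk")),
    seed = config$seed,
    mode = config$mode,
    config_hash = config_hash(config),
    n_individuals = nrow(cohort),
    n_cases = sum(cohort$incident_case_5y))
  class(bundle) <- "pipeline_result"
  if (!is.null(config$output_dir))
    write_report(bundle, config$output_dir)
  bundle
}

#' Stable hash of an analysis configuration
#'
#' MD5 of the deparsed configuration object, recorded in the manifest so
#' that "what ran" is always recoverable and two runs of the same
#' configuration are verifiably identical.
#'
#' @param config An [analysis_config()] (or any R object).
#' @return A 32-character hex string.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$output_dir <- NULL  # run location, not an analysis parameter
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x), tmp)
  unname(tools::md5sum(tmp))
}

#' Suppress small counts in exported tables
#'
#' Renders counts of five or fewer as the suppression marker
#' `"≤5"` (and larger counts as plain integers), the
#' confidentiality convention for small cells in published cohort
#' tables.
#'
#' @param x Integer vector of counts.
#' @param limit Suppression limit (default 5).
#' @return Character vector.
#' @examples
#' suppress_small_counts(c(3, 5, 6, 120))
#' @export
suppress_small_counts <- function(x, limit = 5L) {
  ifelse(!is.na(x) & x <= limit, "≤5", as.character(x))
}

#' Write a pipeline result bundle to disk
#'
#' Exports the evaluation tables as tab-separated text and the whole
#' report as JSON, applying the small-cell suppression rule to count
#' columns in the exported tables, and writes a manifest with MD5
#' hashes of every written file. Two runs of the same configuration
#' produce byte-identical files.
#'
#' @param bundle A `"pipeline_result"` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @param format Subset of `c("json", "tsv")`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir, format = c("json", "tsv")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  suppress_cols <- function(d) {
    for (col in intersect(c("n_cases", "n_controls", "cases_in_bin",
                            "n_in_bin", "observed"), names(d)))
      d[[col]] <- suppress_small_counts(round(d[[col]]))
    d
  }
  if ("tsv" %in% format) {
    tabs <- list(auc = bundle$evaluation$auc,
                 delong = bundle$evaluation$delong,
                 calibration = bundle$evaluation$calibration,
                 skipped = bundle$evaluation$skipped,
                 quantile_rr = bundle$quantile_rr,
                 risk_surface = as.data.frame(bundle$surface),
                 threshold_crossing = bundle$crossing,
                 case_capture = bundle$capture)
    for (nm in names(tabs)) {
      if (is.null(tabs[[nm]]) || nrow(tabs[[nm]]) == 0) next
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(suppress_cols(tabs[[nm]]), p, sep = "\t",
                         quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
      paths <- c(paths, p)
    }
  }
  if ("json" %in% format) {
    rep <- list(
      manifest = bundle$manifest,
      models = lapply(bundle$models, unclass),
      quantile_rr = bundle$quantile_rr,
      evaluation = lapply(unclass(bundle$evaluation), as.data.frame),
      crossing = bundle$crossing,
      capture = bundle$capture,
      threshold = bundle$threshold)
    p <- file.path(dir, "report.json")
    jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    paths <- c(paths, p)
  }
  manifest <- bundle$manifest
  manifest$files <- lapply(stats::setNames(paths, basename(paths)),
                           function(p) unname(tools::md5sum(p)))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
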