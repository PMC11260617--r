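#' @title Pipeline orchestration
#' @description One configuration object drives the full analysis:
#'   ingest (or simulate) -> deduplicate -> primary-suspect selection ->
#'   SOC restriction -> signal screen -> severity comparison ->
#'   time-to-onset/Weibull tables, with every intermediate persisted as
#'   delimited text plus a JSON run manifest.  Identical configuration
#'   and inputs give byte-identical outputs.
#' @name pipeline
NULL

#' Build and validate a pipeline configuration
#'
#' @param input_dir quarter directory to ingest, or `NULL` to simulate.
#' @param scenario a `faers_scenario` used when `input_dir` is `NULL`.
#' @param target_drugs canonical drug ids to analyze.
#' @param synonyms drug synonym table (defaults to the generator-matched
#'   table when simulating, else the shipped GLP-1 table).
#' @param hierarchy a `term_hierarchy` (default: shipped mock
#'   vocabulary).
#' @param soc SOC code the analysis is restricted to (default: the mock
#'   metabolism-and-nutrition class).
#' @param levels hierarchy levels to screen (subset of `"PT"`, `"HLT"`).
#' @param min_count minimum report count per screened term.
#' @param background reference set for the disproportionality screen:
#'   `"all"` uses every ingested report (only in-SOC reactions count
#'   towards terms), `"in_soc"` restricts the reference set to reports
#'   with at least one in-SOC reaction.
#' @param zero_correction Haldane-Anscombe correction for ROR/PRR.
#' @param ic025_multiplier sd multiplier for IC025.
#' @param weibull_location fixed Weibull threshold (0 = two-parameter
#'   fit).
#' @param pt_hlt_only PT codes excluded from PT-level screening and
#'   analyzed only at the HLT level.
#' @param out_dir output directory (created on run).
#' @param seed seed recorded in the manifest and used when simulating.
#' @return object of class `faers_config`.
#' @export
faers_config <- function(input_dir = NULL, scenario = NULL,
                         target_drugs,
                         synonyms = NULL,
                         hierarchy = load_term_hierarchy(),
                         soc = "10027433",
                         levels = c("PT", "HLT"),
                         min_count = 3L,
                         background = c("all", "in_soc"),
                         zero_correction = FALSE,
                         ic025_multiplier = 1.96,
                         weibull_location = 0,
                         pt_hlt_only = character(),
                         out_dir = tempfile("pvfaers_run_"),
                         seed = 1L) {
  if (is.null(input_dir) && is.null(scenario)) {
    stop("configuration needs either 'input_dir' or 'scenario'")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop(sprintf("configuration field 'input_dir': '%s' does not exist",
                 input_dir))
  }
  if (is.null(synonyms)) {
    synonyms <- if (is.null(input_dir)) synth_drug_synonyms()
      else load_drug_synonyms(system.file("extdata", "glp1_synonyms.tsv",
                                          package = "pvfaers"))
  }
  configured <- unique(synonyms$canonical_drug)
  unknown <- setdiff(target_drugs, configured)
  if (length(unknown) > 0L) {
    stop(sprintf(
      "configuration field 'target_drugs': unknown drug id(s) %s; configured drugs: %s",
      paste(unknown, collapse = ", "), paste(sort(configured), collapse = ", ")))
  }
  levels <- match.arg(levels, c("PT", "HLT"), several.ok = TRUE)
  background <- match.arg(background)
  structure(list(input_dir = input_dir, scenario = scenario,
                 target_drugs = target_drugs, synonyms = synonyms,
                 hierarchy = hierarchy, soc = soc, levels = levels,
                 min_count = as.integer(min_count),
                 background = background,
                 zero_correction = zero_correction,
                 ic025_multiplier = ic025_multiplier,
                 weibull_location = weibull_location,
                 pt_hlt_only = pt_hlt_only,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "faers_config")
}

config_fingerprint <- function(config) {
  flat <- list(
    input_dir = config$input_dir,
    scenario_seed = if (!is.null(config$scenario)) config$scenario$seed,
    n_cases = if (!is.null(config$scenario)) config$scenario$n_cases,
    target_drugs = config$target_drugs, soc = config$soc,
    levels = config$levels, min_count = config$min_count,
    background = config$background,
    zero_correction = config$zero_correction,
    ic025_multiplier = config$ic025_multiplier,
    weibull_location = config$weibull_location,
    pt_hlt_only = config$pt_hlt_only, seed = config$seed,
    vocabulary = config$hierarchy$version)
  json <- jsonlite::toJSON(flat, auto_unbox = TRUE, null = "null")
  list(json = json,
       md5 = unname(tools::md5sum(local({
         f <- tempfile(); writeLines(as.character(json), f); f
       }))))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Run the full pipeline
#'
#' Stages in order: ingest (or simulate), link, deduplicate, SOC filter,
#' then per target drug: primary-suspect selection, descriptive summary,
#' signal screen per level, severity comparison, TTO summary and Weibull
#' fit.  Each table is written under `config$out_dir`; a
#' `run_manifest.json` records the configuration, record counts at every
#' stage and the package version.
#'
#' @param config a `faers_config`.
#' @return list (class `faers_run`) with elements `summaries`,
#'   `signals`, `severity`, `tto`, `weibull`, `counts`, `out_dir`,
#'   invisibly also written to disk.
#' @export
run_faers_pipeline <- function(config) {
  stopifnot(inherits(config, "faers_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage_counts <- list()

  if (is.null(config$input_dir)) {
    synth <- generate_faers(config$scenario,
                            dir = file.path(out_dir, "quarter"))
    quarter <- read_faers_quarter(file.path(out_dir, "quarter"))
  } else {
    quarter <- read_faers_quarter(config$input_dir)
  }
  stage_counts$ingested_demo_rows <- unname(quarter$counts[["DEMO"]])
  stage_counts$quarantined_lines <- nrow(quarter$quarantined)

  reports <- link_faers_tables(quarter)
  stage_counts$linked_reports <- n_reports(reports)

  reports <- dedup_faers(reports)
  stage_counts$deduplicated_cases <- n_reports(reports)

  reports <- annotate_soc(reports, config$hierarchy, config$soc)
  soc_reports <- filter_to_soc(reports, config$hierarchy, config$soc)
  stage_counts$in_soc_reports <- n_reports(soc_reports)
  screen_set <- if (config$background == "all") reports else soc_reports

  summaries <- list(); signals <- list(); severity <- list()
  tto <- list(); weibull <- list()

  for (drug in config$target_drugs) {
    cohort <- select_primary_suspect(soc_reports, config$synonyms, drug)
    stage_counts[[paste0("cohort_", drug)]] <- n_reports(cohort)

    cs <- summarize_cohort(cohort, drug = drug)
    summaries[[drug]] <- cs
    write_tsv(cohort_summary_table(cs),
              file.path(out_dir, sprintf("table1_%s.tsv", drug)))

    for (level in config$levels) {
      sig <- screen_signals(
        screen_set, config$synonyms, drug, level = level,
        hierarchy = config$hierarchy, min_count = config$min_count,
        zero_correction = config$zero_correction,
        ic025_multiplier = config$ic025_multiplier,
        in_soc_only = TRUE,
        exclude_terms = if (level == "PT") config$pt_hlt_only else character())
      signals[[paste(drug, level, sep = "_")]] <- sig
      write_tsv(as.data.frame(sig),
                file.path(out_dir, sprintf("signals_%s_%s.tsv", drug, level)))
    }

    sev <- compare_severity(cohort, drug = drug)
    severity[[drug]] <- sev
    write_tsv(sev, file.path(out_dir, sprintf("severity_%s.tsv", drug)))

    ts <- compute_tto(cohort, config$synonyms, drug)
    tto[[drug]] <- ts
    tto_row <- data.frame(
      drug = drug, n = length(ts$values),
      median = if (length(ts$values)) median_iqr(ts$values)[["median"]] else NA,
      q1 = if (length(ts$values)) median_iqr(ts$values)[["q1"]] else NA,
      q3 = if (length(ts$values)) median_iqr(ts$values)[["q3"]] else NA,
      min = if (length(ts$values)) min(ts$values) else NA,
      max = if (length(ts$values)) max(ts$values) else NA,
      excluded_missing_event = ts$n_excluded[["missing_event"]],
      excluded_missing_start = ts$n_excluded[["missing_start"]],
      excluded_event_before_start = ts$n_excluded[["event_before_start"]],
      excluded_partial_date = ts$n_excluded[["partial_date"]],
      stringsAsFactors = FALSE)
    write_tsv(tto_row, file.path(out_dir, sprintf("tto_%s.tsv", drug)))
    write_tsv(tto_cumulative(ts),
              file.path(out_dir, sprintf("tto_cdf_%s.tsv", drug)))

    wb <- tryCatch(
      weibull_fit(ts, location = config$weibull_location),
      error = function(e) NULL)
    weibull[[drug]] <- wb
    wrow <- if (is.null(wb)) {
      data.frame(drug = drug, n = length(ts$values), shape = NA, shape_low = NA,
                 shape_high = NA, scale = NA, scale_low = NA, scale_high = NA,
                 failure_type = "insufficient data", stringsAsFactors = FALSE)
    } else {
      data.frame(drug = drug, n = wb$n, shape = wb$shape,
                 shape_low = wb$shape_ci[1], shape_high = wb$shape_ci[2],
                 scale = wb$scale, scale_low = wb$scale_ci[1],
                 scale_high = wb$scale_ci[2], failure_type = wb$failure_type,
                 stringsAsFactors = FALSE)
    }
    write_tsv(wrow, file.path(out_dir, sprintf("weibull_%s.tsv", drug)))
  }

  fp <- config_fingerprint(config)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pvfaers")),
    config = jsonlite::fromJSON(fp$json),
    config_md5 = fp$md5,
    stage_counts = stage_counts,
    assumptions = list(
      tto_between_group_test = "mann_whitney (two-sample, bonferroni when pairwise)",
      mann_whitney_variance = "tie-corrected, no continuity correction",
      expected_count_rule = "pearson chi2 when all expected >= 5, else fisher",
      gps_expected_counts = "crude (unstratified)",
      background = config$background))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(structure(
    list(summaries = summaries, signals = signals, severity = severity,
         tto = tto, weibull = weibull, counts = stage_counts,
         out_dir = out_dir),
    class = "faers_run"))
}

#' @export
print.faers_run <- function(x, ...) {
  cat("<faers_run>\n  stage counts:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("    %-24s %d\n", nm, x$counts[[nm]]))
  }
  cat(sprintf("  outputs in %s\n", x$out_dir))
  invisible(x)
}
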