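# End-to-end orchestration: one configuration in, a bundle of result
# tables out, with every filtering step logged so the denominators behind
# each disproportionality estimate stay auditable.

#' Pipeline configuration
#'
#' Either `input_dir` (a directory of FAERS quarterly files) or
#' `simulate` (a [sim_config()]; files are generated under
#' `out_dir/sim/`) must be given.
#'
#' @param out_dir Output directory for result tables and the manifest.
#' @param input_dir Directory of FAERS quarterly files, or `NULL`.
#' @param simulate A `sim_config` to generate input from, or `NULL`.
#' @param dictionary Drug dictionary tibble (default the shipped one).
#' @param hierarchy `meddra_hierarchy` (default the shipped synthetic
#'   one).
#' @param ae_groups Group selector tibble (default the shipped eight
#'   neuropsychiatric groups).
#' @param target_socs SOCs whose primary PTs define the neuropsychiatric
#'   PT universe.
#' @param strata Indication strata to analyze.
#' @param comparators Comparator constructions for the per-drug group
#'   analysis.
#' @param tto_bins Day boundaries for onset-time bins.
#' @param age_breaks Age-group boundaries (years).
#' @param dm_keywords,weight_keywords Indication keyword lists.
#' @param n_min Signal count threshold.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            input_dir = NULL, simulate = NULL,
                            dictionary = default_drug_dictionary(),
                            hierarchy = synthetic_hierarchy(),
                            ae_groups = default_ae_groups(),
                            target_socs = c("Psychiatric disorders",
                                            "Nervous system disorders"),
                            strata = c("all", "DM", "weight-loss"),
                            comparators = c("database", "antidiabetic",
                                            "anti-obesity"),
                            tto_bins = TTO_DEFAULT_BINS,
                            age_breaks = DEFAULT_AGE_BREAKS,
                            dm_keywords = "DIABETES",
                            weight_keywords = c("OBESITY", "WEIGHT",
                                                "OVERWEIGHT"),
                            n_min = 3) {
  if (is.null(input_dir) && is.null(simulate)) {
    abort("pipeline_config: give input_dir or a simulate block")
  }
  problems <- character(0)
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    problems <- c(problems, paste0("input_dir does not exist: ", input_dir))
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    problems <- c(problems, "simulate must be a sim_config object")
  }
  if (length(strata) < 1) problems <- c(problems, "at least one stratum")
  if (length(problems) > 0) {
    abort(paste0("invalid pipeline configuration:\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }
  structure(list(out_dir = out_dir, input_dir = input_dir,
                 simulate = simulate, dictionary = dictionary,
                 hierarchy = hierarchy, ae_groups = ae_groups,
                 target_socs = target_socs, strata = strata,
                 comparators = comparators, tto_bins = tto_bins,
                 age_breaks = age_breaks, dm_keywords = dm_keywords,
                 weight_keywords = weight_keywords, n_min = n_min),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Ingests (or simulates) the quarterly files, deduplicates, applies the
#' primary-suspect GLP-1RA filter, and writes: the load and dedup logs,
#' the attrition log (raw reports -> deduplicated cases -> target
#' exposures -> event cohort), cohort characteristics, the annual report
#' series, the PT-level scan per indication stratum, the per-drug
#' adverse-event-group signal tables per comparator and stratum, the
#' onset-time summaries and cumulative curves, and a manifest recording
#' the configuration hash and row counts of every output.
#'
#' All outputs are plain CSV (plus a JSON manifest) and regenerate
#' byte-identically from the same configuration.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of the in-memory result tables plus the
#'   manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  say <- function(...) if (!quiet) inform(paste0(...))

  input_dir <- config$input_dir
  if (is.null(input_dir)) {
    input_dir <- file.path(out, "sim")
    say("simulating ", config$simulate$n_cases, " cases -> ", input_dir)
    simulate_faers(config$simulate, input_dir)
  }

  ft <- read_faers(input_dir)
  raw <- join_cases(ft)
  say("ingested ", nrow(raw$demo), " reports (",
      sum(ft$log$rejected), " rows rejected, ",
      sum(raw$orphans$n), " orphan child rows)")
  fc <- deduplicate(raw)
  say("deduplicated to ", nrow(fc$cases), " cases")

  exposures <- case_exposures(fc, config$dictionary, roles = "PS")
  glp1_ids <- exposed_ids(exposures, class = "GLP-1RA")
  neuro_pts <- unique(unlist(lapply(config$target_socs, function(s) {
    pts_for_primary_soc(config$hierarchy, s)
  })))
  neuro_ids <- cases_with_pts(fc, neuro_pts)
  cohort_ids <- intersect(glp1_ids, neuro_ids)
  say(length(glp1_ids), " primary-suspect GLP-1RA cases; ",
      length(cohort_ids), " with neuropsychiatric events")

  attrition <- tibble(
    step = c("raw reports", "deduplicated cases",
             "primary-suspect GLP-1RA cases",
             "GLP-1RA neuropsychiatric cohort"),
    n = c(nrow(raw$demo), nrow(fc$cases), length(glp1_ids),
          length(cohort_ids)))

  group_pts <- resolve_ae_groups(config$ae_groups, config$hierarchy)

  characteristics <- bind_rows(lapply(
    c("sex", "age_group", "reporter", "year", "indication", "outcome"),
    function(d) tabulate_characteristics(
      fc, d, cohort_ids, config$age_breaks,
      config$dm_keywords, config$weight_keywords)))

  annual <- annual_series(fc, neuro_pts, glp1_ids)

  glp1_generics <- config$dictionary |>
    filter(.data$class == "GLP-1RA") |>
    distinct(.data$generic)
  per_drug_targets <- tibble(drug = tolower(glp1_generics$generic),
                             class = NA_character_,
                             generic = glp1_generics$generic)
  class_target <- tibble(drug = "GLP-1RA (class)", class = "GLP-1RA",
                         generic = NA_character_)

  scans <- bind_rows(lapply(setdiff(config$strata, "all"), function(st) {
    universe <- stratum_ids(fc, st, dm_keywords = config$dm_keywords,
                            weight_keywords = config$weight_keywords)
    t_ids <- intersect(universe, glp1_ids)
    c_ids <- comparator_ids(exposures, universe, "database")
    scan_pts(fc, exposures, neuro_pts, t_ids, c_ids, config$n_min) |>
      mutate(stratum = st, .before = 1)
  }))

  signals <- bind_rows(lapply(config$strata, function(st) {
    bind_rows(lapply(config$comparators, function(cmp) {
      signal_table(fc, exposures, group_pts,
                   bind_rows(class_target, per_drug_targets),
                   comparator = cmp, stratum = st, n_min = config$n_min,
                   dm_keywords = config$dm_keywords,
                   weight_keywords = config$weight_keywords)
    }))
  }))

  tto <- compute_tto(fc, exposures |> filter(.data$class == "GLP-1RA"))
  tto <- tto |> filter(.data$caseid %in% cohort_ids)
  tto_by_drug <- tto_summary_table(tto, "generic", config$tto_bins)
  inc <- tto |> filter(.data$included)
  tto_overall <- summarize_tto(inc$onset_days, config$tto_bins)
  tto_curve <- tto_overall$cumulative
  tto_exclusions <- tto |>
    count(reason = ifelse(.data$included, "included",
                          .data$exclusion_reason), name = "n")

  results <- list(load_log = ft$log, dedup_log = fc$dedup_log,
                  attrition = attrition,
                  characteristics = characteristics,
                  annual_series = annual, pt_scan = scans,
                  ae_group_signals = signals,
                  tto_by_drug = tto_by_drug,
                  tto_bins = tto_overall$bins,
                  tto_curve = tto_curve,
                  tto_exclusions = tto_exclusions)
  for (nm in names(results)) {
    readr::write_csv(results[[nm]], file.path(out, paste0(nm, ".csv")))
  }
  manifest <- list(
    config_hash = hash(config[setdiff(names(config), "out_dir")]),
    n_raw_reports = nrow(raw$demo),
    n_cases = nrow(fc$cases),
    n_cohort = length(cohort_ids),
    tto_median_days = tto_overall$median_days,
    outputs = lapply(results, nrow))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("wrote ", length(results), " tables + manifest to ", out)
  invisible(c(results, list(manifest = manifest, cases = fc,
                            exposures = exposures,
                            cohort_ids = cohort_ids)))
}
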