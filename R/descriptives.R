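# Descriptive tabulation of a case cohort.

OUTCOME_SEVERITY <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
DEFAULT_AGE_BREAKS <- c(18, 65, 85)

#' Tabulate cohort characteristics
#'
#' Counts and percentages of a deduplicated, exposure-filtered cohort
#' along one dimension.  Unknown or absent values fall into a
#' `"missing"` level, and percentages use the all-cases denominator, so
#' each dimension's counts sum to the cohort total.
#'
#' Dimensions: `sex`; `age_group` with boundaries `<18`, `[18,65)`,
#' `[65,85]`, `>85` by default; `reporter` (healthcare professional vs
#' consumer/non-HCP from the FAERS occupation code); `year` (FDA receipt
#' year — always present, unlike the event date); `indication` (DM /
#' weight-loss / other from the indication keyword match); `outcome`
#' (worst outcome per case, ranked DE > LT > HO > DS > CA > RI > OT).
#'
#' @param fc A `faers_cases` object.
#' @param dimension One of `"sex"`, `"age_group"`, `"reporter"`,
#'   `"year"`, `"indication"`, `"outcome"`.
#' @param cohort_ids Caseids of the cohort; defaults to all cases.
#' @param age_breaks Inner age boundaries (years).
#' @param dm_keywords,weight_keywords Indication keyword lists.
#' @return A tibble `dimension`, `level`, `n`, `percent`.
#' @export
tabulate_characteristics <- function(fc, dimension,
                                     cohort_ids = NULL,
                                     age_breaks = DEFAULT_AGE_BREAKS,
                                     dm_keywords = "DIABETES",
                                     weight_keywords = c("OBESITY", "WEIGHT",
                                                         "OVERWEIGHT")) {
  dims <- c("sex", "age_group", "reporter", "year", "indication", "outcome")
  if (!dimension %in% dims) {
    abort(paste0("unknown dimension '", dimension, "'; use one of ",
                 paste(dims, collapse = ", ")))
  }
  cohort_ids <- cohort_ids %||% unique(fc$cases$caseid)
  cases <- fc$cases[fc$cases$caseid %in% cohort_ids, , drop = FALSE]
  lvl <- switch(dimension,
    sex = {
      s <- toupper(trimws(cases$sex))
      ifelse(s %in% c("F", "M"), s, "missing")
    },
    age_group = {
      b <- sort(age_breaks)
      stopifnot(length(b) == 3)
      age <- cases$age_years
      dplyr::case_when(
        is.na(age) ~ "missing",
        age < b[1] ~ paste0("<", b[1]),
        age < b[2] ~ paste0("[", b[1], ",", b[2], ")"),
        age <= b[3] ~ paste0("[", b[2], ",", b[3], "]"),
        TRUE ~ paste0(">", b[3]))
    },
    reporter = {
      occ <- toupper(trimws(cases$occp_cod))
      dplyr::case_when(
        occ %in% c("MD", "PH", "OT", "HP", "RN") ~ "healthcare professional",
        occ %in% c("CN", "LW") ~ "consumer/non-HCP",
        TRUE ~ "missing")
    },
    year = {
      y <- format(cases$fda_date, "%Y")
      ifelse(is.na(y), "missing", y)
    },
    indication = {
      dm <- cases$caseid %in% stratum_ids(fc, "DM",
                                          dm_keywords = dm_keywords,
                                          weight_keywords = weight_keywords)
      wt <- cases$caseid %in% stratum_ids(fc, "weight-loss",
                                          dm_keywords = dm_keywords,
                                          weight_keywords = weight_keywords)
      has_any <- cases$primaryid %in% fc$indi$primaryid
      dplyr::case_when(dm & wt ~ "DM + weight-loss",
                       dm ~ "DM",
                       wt ~ "weight-loss",
                       has_any ~ "other",
                       TRUE ~ "missing")
    },
    outcome = {
      oc <- fc$outc |>
        mutate(code = toupper(trimws(.data$outc_cod))) |>
        filter(.data$code %in% OUTCOME_SEVERITY) |>
        mutate(rank = match(.data$code, OUTCOME_SEVERITY)) |>
        group_by(.data$primaryid) |>
        summarise(worst = OUTCOME_SEVERITY[min(.data$rank)],
                  .groups = "drop")
      w <- oc$worst[match(cases$primaryid, oc$primaryid)]
      ifelse(is.na(w), "missing", w)
    })
  tab <- tibble(level = lvl) |>
    count(.data$level, name = "n") |>
    mutate(percent = 100 * .data$n / length(lvl))
  bind_cols(tibble(dimension = dimension), tab)
}

#' Annual report series: events of interest versus others
#'
#' One row per calendar year (from the FDA receipt date) over the cohort's
#' observed range, with the count of cohort cases reporting at least one
#' PT of `neuro_pts`, the count without, and the proportion.  Years with
#' no reports get zero rows; cases with no receipt year are dropped from
#' the series.
#'
#' @param fc A `faers_cases` object.
#' @param neuro_pts PT set defining the event of interest.
#' @param cohort_ids Caseids of the cohort; defaults to all cases.
#' @return A tibble `year`, `n_event`, `n_other`, `proportion`.
#' @export
annual_series <- function(fc, neuro_pts, cohort_ids = NULL) {
  cohort_ids <- cohort_ids %||% unique(fc$cases$caseid)
  cases <- fc$cases[fc$cases$caseid %in% cohort_ids, , drop = FALSE]
  year <- as.integer(format(cases$fda_date, "%Y"))
  keep <- !is.na(year)
  cases <- cases[keep, , drop = FALSE]
  year <- year[keep]
  if (nrow(cases) == 0) {
    return(tibble(year = integer(0), n_event = integer(0),
                  n_other = integer(0), proportion = double(0)))
  }
  ev_ids <- cases_with_pts(fc, neuro_pts)
  is_ev <- cases$caseid %in% ev_ids
  tibble(year = year, is_ev = is_ev) |>
    group_by(.data$year) |>
    summarise(n_event = sum(.data$is_ev),
              n_other = sum(!.data$is_ev), .groups = "drop") |>
    tidyr::complete(year = tidyr::full_seq(.data$year, 1),
                    fill = list(n_event = 0L, n_other = 0L)) |>
    mutate(total = .data$n_event + .data$n_other,
           proportion = ifelse(.data$total == 0, 0,
                               .data$n_event / .data$total)) |>
    select(-"total")
}
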