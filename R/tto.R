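# Time-to-onset analysis.
#
# TTO is the interval, in whole days, between initiation of the suspect
# drug (the earliest fully-dated therapy start for that drug) and the
# event date of the report.  Only strictly positive, fully dated
# intervals are analyzable: records with missing or partial dates, with
# the start after the event, or with a zero interval are excluded, each
# with an explicit reason, so the exclusion accounting is auditable.

TTO_DEFAULT_BINS <- c(30, 60, 90, 180, 360)

#' Compute per-case time to onset
#'
#' For each exposure assignment the therapy rows of the same report and
#' drug sequence(s) are located, the earliest day-precision start date is
#' taken as initiation, and the onset is `event_date - start_date` in
#' days.  Exclusion reasons, in order of precedence: `"missing date"`
#' (no event date or no therapy start at all), `"partial date"` (dates
#' present only at year/month precision — never imputed),
#' `"start-after-event"` (negative interval), `"non-positive"` (zero
#' interval).
#'
#' @param fc A `faers_cases` object.
#' @param exposures Exposure table from [case_exposures()]; one TTO
#'   record is produced per distinct (caseid, generic).
#' @return A tibble `caseid`, `generic`, `onset_days`, `included`,
#'   `exclusion_reason`.
#' @export
compute_tto <- function(fc, exposures) {
  exp_drug <- exposures |> distinct(.data$caseid, .data$primaryid,
                                    .data$drug_seq, .data$generic)
  ther <- fc$ther
  ther_dates <- parse_partial_date(ther$start_dt)
  ther <- ther |>
    mutate(start_date = ther_dates$date,
           start_precision = ther_dates$precision)
  joined <- exp_drug |>
    left_join(ther |> select("primaryid", drug_seq = "dsg_drug_seq",
                             "start_date", "start_precision"),
              by = c("primaryid", "drug_seq"))
  starts <- joined |>
    group_by(.data$caseid, .data$generic) |>
    summarise(start_date = if (any(.data$start_precision %in% "day")) {
                min(.data$start_date[.data$start_precision %in% "day"])
              } else as.Date(NA),
              start_partial = any(.data$start_precision %in%
                                    c("year", "month")),
              start_any = any(!is.na(.data$start_precision) &
                                .data$start_precision != "missing"),
              .groups = "drop")
  demo <- fc$cases |> select("caseid", "event_date", "event_precision")
  rec <- starts |>
    left_join(demo, by = "caseid") |>
    mutate(onset_days = as.integer(.data$event_date - .data$start_date))
  event_partial <- rec$event_precision %in% c("year", "month")
  event_missing <- !(rec$event_precision %in% c("day", "year", "month"))
  start_missing <- !rec$start_any
  reason <- dplyr::case_when(
    event_missing | start_missing ~ "missing date",
    event_partial | (is.na(rec$start_date) & rec$start_partial) ~
      "partial date",
    rec$onset_days < 0 ~ "start-after-event",
    rec$onset_days == 0 ~ "non-positive",
    TRUE ~ NA_character_)
  tibble(caseid = rec$caseid, generic = rec$generic,
         onset_days = ifelse(is.na(reason), rec$onset_days, NA_integer_),
         included = is.na(reason), exclusion_reason = reason)
}

#' Summarize time-to-onset records
#'
#' Median and quartiles use linear interpolation between order statistics
#' (quantile type 7).  Bins are left-open/right-closed day intervals; the
#' cumulative curve gives the fraction of records with onset at or below
#' each observed day.
#'
#' @param onset_days Integer vector of included onset days (positive).
#' @param bins Upper bin boundaries in days; a final open-ended bin is
#'   added above the largest boundary.
#' @return A list of class `tto_summary`: `n`, `median_days`,
#'   `iqr_lower_days`, `iqr_upper_days`, `bins` (tibble `bin`, `n`,
#'   `percent`), `cumulative` (tibble `day`, `fraction`).  Empty input
#'   yields the `n = 0` sentinel with `NA` summaries.
#' @export
summarize_tto <- function(onset_days, bins = TTO_DEFAULT_BINS) {
  onset_days <- onset_days[!is.na(onset_days)]
  if (length(onset_days) == 0) {
    return(structure(list(n = 0L, median_days = NA_real_,
                          iqr_lower_days = NA_real_,
                          iqr_upper_days = NA_real_,
                          bins = tibble(bin = character(0), n = integer(0),
                                        percent = double(0)),
                          cumulative = tibble(day = integer(0),
                                              fraction = double(0))),
                     class = "tto_summary"))
  }
  stopifnot(all(onset_days > 0))
  q <- unname(quantile(onset_days, c(0.25, 0.5, 0.75), type = 7))
  breaks <- c(0, sort(bins), Inf)
  labels <- c(paste0("(", head(breaks, -2), ",", breaks[-c(1, length(breaks))],
                     "]"),
              paste0(">", breaks[length(breaks) - 1]))
  cut_idx <- cut(onset_days, breaks = breaks, labels = labels, right = TRUE)
  bin_tab <- tibble(bin = labels,
                    n = as.integer(table(cut_idx)[labels]))
  bin_tab$percent <- 100 * bin_tab$n / length(onset_days)
  days <- sort(unique(onset_days))
  cum <- tibble(day = days,
                fraction = vapply(days, function(d) mean(onset_days <= d),
                                  numeric(1)))
  structure(list(n = length(onset_days), median_days = q[[2]],
                 iqr_lower_days = q[[1]], iqr_upper_days = q[[3]],
                 bins = bin_tab, cumulative = cum),
            class = "tto_summary")
}

#' @export
print.tto_summary <- function(x, ...) {
  cat("<tto_summary> n = ", x$n, ", median ", x$median_days,
      " days (IQR ", x$iqr_lower_days, "-", x$iqr_upper_days, ")\n",
      sep = "")
  invisible(x)
}

#' Per-group and per-drug TTO summary table
#'
#' @param tto TTO record tibble from [compute_tto()], optionally with an
#'   `ae_group` column when summarizing per adverse-event group.
#' @param by Grouping column, `"generic"` or `"ae_group"`.
#' @param bins Bin boundaries, see [summarize_tto()].
#' @return A tibble with one row per group: `n`, `median_days`,
#'   `iqr_lower_days`, `iqr_upper_days`.
#' @export
tto_summary_table <- function(tto, by = "generic", bins = TTO_DEFAULT_BINS) {
  out <- tto |>
    filter(.data$included) |>
    group_by(group = .data[[by]]) |>
    reframe({
      s <- summarize_tto(.data$onset_days, bins)
      tibble(n = s$n, median_days = s$median_days,
             iqr_lower_days = s$iqr_lower_days,
             iqr_upper_days = s$iqr_upper_days)
    })
  names(out)[names(out) == "group"] <- by
  out
}
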