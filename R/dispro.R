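# Reporting odds ratio disproportionality.
#
# For a target drug set, a comparator set and an adverse-event PT set, the
# 2x2 contingency table is
#
#     a  target cases reporting the event     b  target cases without it
#     c  comparator cases reporting the event d  comparator cases without it
#
# and ROR = (a/b) / (c/d) with the Wald 95% CI
# exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)).  No continuity
# correction is applied: a table with any zero cell is reported as not
# estimable.  A drug-event pair is a signal when at least 3 target cases
# report the event and the CI lower bound strictly exceeds 1.

ROR_Z <- 1.96  # two-sided 95%; fixed so results stay comparable

#' Compute reporting odds ratios with Wald 95% confidence intervals
#'
#' Vectorized over tables.  Cells must be non-negative; a table with any
#' zero cell is flagged not estimable (`estimable = FALSE`, `ror` and CI
#' `NA`) rather than silently corrected.
#'
#' @param a,b,c_,d Cell counts (target/event, target/other,
#'   comparator/event, comparator/other).
#' @return A tibble with `a`, `b`, `c`, `d`, `n` (= a), `ror`,
#'   `ci_lower`, `ci_upper`, `estimable`.
#' @export
compute_ror <- function(a, b, c_, d) {
  stopifnot(all(a >= 0, na.rm = TRUE), all(b >= 0, na.rm = TRUE),
            all(c_ >= 0, na.rm = TRUE), all(d >= 0, na.rm = TRUE))
  est <- a > 0 & b > 0 & c_ > 0 & d > 0
  ror <- ci_l <- ci_u <- rep(NA_real_, length(a))
  log_ror <- log((a[est] / b[est]) / (c_[est] / d[est]))
  se <- sqrt(1 / a[est] + 1 / b[est] + 1 / c_[est] + 1 / d[est])
  ror[est] <- exp(log_ror)
  ci_l[est] <- exp(log_ror - ROR_Z * se)
  ci_u[est] <- exp(log_ror + ROR_Z * se)
  tibble(a = a, b = b, c = c_, d = d, n = a,
         ror = ror, ci_lower = ci_l, ci_upper = ci_u, estimable = est)
}

#' Apply the signal criteria
#'
#' A pair is flagged as a signal when the event count `n` is at least
#' `n_min` (default 3) and the 95% CI lower bound strictly exceeds 1.
#' Non-estimable results are never signals.
#'
#' @param res Result tibble from [compute_ror()].
#' @param n_min Minimum number of target cases with the event.
#' @return `res` with an `is_signal` logical column added.
#' @export
flag_signal <- function(res, n_min = 3) {
  res$is_signal <- res$estimable & res$n >= n_min & res$ci_lower > 1
  res
}

#' Build one 2x2 contingency table from case-id sets
#'
#' Counting is case-level: a case with several matching reaction PTs
#' counts once.  A case appearing in both the target and comparator sets
#' is assigned to the target only (and the overlap is reported).
#'
#' @param target_ids,comparator_ids Case ids of the two exposure arms.
#' @param ae_ids Case ids reporting at least one PT of the event set.
#' @return A one-row tibble `a`, `b`, `c`, `d`, `overlap`.
#' @export
build_contingency <- function(target_ids, comparator_ids, ae_ids) {
  target_ids <- unique(target_ids)
  comparator_ids <- unique(comparator_ids)
  overlap <- intersect(comparator_ids, target_ids)
  comparator_ids <- setdiff(comparator_ids, target_ids)
  ae <- unique(ae_ids)
  a <- sum(target_ids %in% ae)
  c_ <- sum(comparator_ids %in% ae)
  tibble(a = a, b = length(target_ids) - a,
         c = c_, d = length(comparator_ids) - c_,
         overlap = length(overlap))
}

#' Case ids reporting at least one PT of a set
#'
#' @param fc A `faers_cases` object.
#' @param pts Character vector of preferred terms.
#' @return Character vector of caseids.
#' @export
cases_with_pts <- function(fc, pts) {
  hit <- fc$reac[toupper(trimws(fc$reac$pt)) %in% toupper(trimws(pts)), ,
                 drop = FALSE]
  unique(fc$cases$caseid[fc$cases$primaryid %in% hit$primaryid])
}

#' Case ids of an indication stratum
#'
#' A case belongs to the diabetes stratum when any of its indication PTs
#' matches a diabetes keyword, and to the weight-loss stratum when any
#' matches a weight keyword; a case matching both belongs to both strata
#' (strata are analyzed separately, not exclusively).
#'
#' @param fc A `faers_cases` object.
#' @param stratum `"all"`, `"DM"` or `"weight-loss"`.
#' @param dm_keywords,weight_keywords Keyword sets matched as
#'   case-insensitive substrings of the indication PT.
#' @return Character vector of caseids.
#' @export
stratum_ids <- function(fc, stratum = c("all", "DM", "weight-loss"),
                        dm_keywords = "DIABETES",
                        weight_keywords = c("OBESITY", "WEIGHT",
                                            "OVERWEIGHT")) {
  stratum <- match.arg(stratum)
  if (stratum == "all") return(unique(fc$cases$caseid))
  kw <- if (stratum == "DM") dm_keywords else weight_keywords
  pat <- paste(toupper(kw), collapse = "|")
  hit <- fc$indi[stringr::str_detect(toupper(fc$indi$indi_pt), pat), ,
                 drop = FALSE]
  unique(fc$cases$caseid[fc$cases$primaryid %in% hit$primaryid])
}

#' Case ids exposed to a target drug class or generic
#'
#' @param exposures Exposure table from [case_exposures()].
#' @param class,generic Select by dictionary class and/or generic name.
#' @return Character vector of caseids.
#' @export
exposed_ids <- function(exposures, class = NULL, generic = NULL) {
  e <- exposures
  if (!is.null(class)) e <- e[e$class %in% class, , drop = FALSE]
  if (!is.null(generic)) {
    e <- e[e$generic %in% toupper(generic), , drop = FALSE]
  }
  unique(e$caseid)
}

#' Comparator case ids
#'
#' Three comparator constructions are supported: the whole database minus
#' the target-class exposures; cases exposed (primary suspect) to
#' non-GLP-1RA antidiabetic classes; and cases exposed to non-GLP-1RA
#' anti-obesity drugs.  Cases exposed to any excluded class (by default
#' the GLP-1RA class) are removed from the dictionary-based comparators.
#'
#' @param exposures Exposure table from [case_exposures()].
#' @param universe Caseids of the stratum under analysis.
#' @param comparator `"database"`, `"antidiabetic"` or `"anti-obesity"`.
#' @param exclude_classes Classes whose exposed cases never enter a
#'   dictionary-based comparator.
#' @return Character vector of caseids.
#' @export
comparator_ids <- function(exposures, universe,
                           comparator = c("database", "antidiabetic",
                                          "anti-obesity"),
                           exclude_classes = "GLP-1RA") {
  comparator <- match.arg(comparator)
  excluded <- exposed_ids(exposures, class = exclude_classes)
  pool <- switch(comparator,
    database = universe,
    antidiabetic = intersect(universe,
                             exposed_ids(exposures,
                                         class = antidiabetic_classes())),
    `anti-obesity` = intersect(universe,
                               exposed_ids(exposures,
                                           class = antiobesity_classes())))
  setdiff(pool, excluded)
}

#' Disproportionality table for drug targets x adverse-event groups
#'
#' Builds the forest-plot-ready signal table: one row per (target, AE
#' group), with cells, ROR, 95% CI and signal flag, within one indication
#' stratum and against one comparator construction.
#'
#' @param fc A `faers_cases` object.
#' @param exposures Exposure table from [case_exposures()].
#' @param group_pts Named list of PT sets from [resolve_ae_groups()].
#' @param targets Tibble with columns `drug` (label) and either `class`
#'   or `generic` (NA where not used), one row per target.
#' @param comparator Comparator construction, see [comparator_ids()].
#' @param stratum Indication stratum, see [stratum_ids()].
#' @param n_min Signal count threshold.
#' @param ... Passed to [stratum_ids()] (keyword lists).
#' @return A tibble `stratum`, `comparator`, `drug`, `ae_group`, `a`,
#'   `b`, `c`, `d`, `ror`, `ci_lower`, `ci_upper`, `n`, `is_signal`.
#' @export
signal_table <- function(fc, exposures, group_pts, targets,
                         comparator = "database", stratum = "all",
                         n_min = 3, ...) {
  universe <- stratum_ids(fc, stratum, ...)
  rows <- purrr::pmap(targets, function(drug, class = NA, generic = NA, ...) {
    t_ids <- intersect(universe,
                       exposed_ids(exposures,
                                   class = if (!is.na(class)) class,
                                   generic = if (!is.na(generic)) generic))
    c_ids <- comparator_ids(exposures, universe, comparator)
    purrr::imap(group_pts, function(pts, gname) {
      ae <- cases_with_pts(fc, pts)
      ct <- build_contingency(t_ids, c_ids, ae)
      tibble(drug = drug, ae_group = gname, ct)
    }) |> bind_rows()
  }) |> bind_rows()
  res <- compute_ror(rows$a, rows$b, rows$c, rows$d) |> flag_signal(n_min)
  bind_cols(tibble(stratum = stratum, comparator = comparator,
                   drug = rows$drug, ae_group = rows$ae_group),
            res)
}

#' PT-level disproportionality scan
#'
#' Computes per-PT contingency tables for a target drug set against a
#' comparator within one stratum, keeps PTs with at least `n_min` target
#' cases, and classifies each by the CI lower bound (RORL): `"strong"`
#' when RORL > 3, `"moderate"` when 1 < RORL <= 3, `"none"` otherwise
#' (the boundary RORL = 1 is not a signal tier).  This is the
#' heatmap-matrix-ready surface.
#'
#' @param fc A `faers_cases` object.
#' @param exposures Exposure table.
#' @param pts PT set to scan (e.g. from [pts_for_primary_soc()]).
#' @param target_ids Caseids of the target arm.
#' @param comparator_ids Caseids of the comparator arm.
#' @param n_min Minimum target case count for a PT to be reported.
#' @return A tibble `pt`, `a`, `b`, `c`, `d`, `n`, `ror`, `ci_lower`,
#'   `ci_upper`, `tier`.
#' @export
scan_pts <- function(fc, exposures, pts, target_ids, comparator_ids,
                     n_min = 3) {
  target_ids <- unique(target_ids)
  comparator_ids <- setdiff(unique(comparator_ids), target_ids)
  reac <- fc$reac |>
    mutate(pt_norm = toupper(trimws(.data$pt))) |>
    filter(.data$pt_norm %in% toupper(trimws(pts))) |>
    inner_join(fc$cases |> select("primaryid", "caseid"), by = "primaryid") |>
    distinct(.data$pt_norm, .data$caseid)
  n_t <- length(target_ids)
  n_c <- length(comparator_ids)
  counts <- reac |>
    group_by(pt = .data$pt_norm) |>
    summarise(a = sum(.data$caseid %in% target_ids),
              c_ = sum(.data$caseid %in% comparator_ids),
              .groups = "drop") |>
    filter(.data$a >= n_min)
  if (nrow(counts) == 0) {
    return(tibble(pt = character(0), a = integer(0), b = integer(0),
                  c = integer(0), d = integer(0), n = integer(0),
                  ror = double(0), ci_lower = double(0),
                  ci_upper = double(0), tier = character(0)))
  }
  res <- compute_ror(counts$a, n_t - counts$a, counts$c_, n_c - counts$c_)
  tier <- dplyr::case_when(
    !res$estimable ~ "not estimable",
    res$ci_lower > 3 ~ "strong",
    res$ci_lower > 1 ~ "moderate",
    TRUE ~ "none")
  bind_cols(tibble(pt = counts$pt), res |> select(-"estimable"),
            tibble(tier = tier)) |>
    arrange(desc(.data$ci_lower))
}
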