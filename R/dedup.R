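# Case-version deduplication.
#
# FAERS distributes every revision of a safety report: an initial version
# ("I") and any number of follow-ups ("F"), each under its own primaryid
# but sharing a caseid, and the same case can recur across quarterly
# files.  Analyses must count each case once, keeping its most recent
# version.

#' Deduplicate raw case reports to one record per case
#'
#' Keeps the most recent version of each case, selected by a total order
#' over (1) latest FDA receipt date, (2) follow-up over initial code,
#' (3) latest event date, (4) largest primaryid.  Missing dates sort
#' before any present date, so versions with complete data are preferred.
#' The order is total (primaryid is unique), which makes the result
#' independent of input row order and the operation idempotent.
#'
#' Deduplication runs on the pooled set of reports across all quarters, so
#' cross-quarter duplicates of the same caseid collapse in the same pass.
#'
#' @param raw A `faers_raw` object from [join_cases()].
#' @return An object of class `faers_cases`: a list with `cases` (one row
#'   per caseid, with a `provenance` list-column of all collapsed
#'   primaryids), the child tables restricted to surviving primaryids, and
#'   `dedup_log` (one row per removed report version: `caseid`,
#'   `survivor`, `removed`).
#' @export
deduplicate <- function(raw) {
  demo <- if (inherits(raw, "faers_cases")) raw$cases else raw$demo
  if (nrow(demo) == 0) {
    return(structure(c(list(cases = demo),
                       raw[c("drug", "reac", "indi", "ther", "outc")],
                       list(dedup_log = tibble(caseid = character(0),
                                               survivor = character(0),
                                               removed = character(0)))),
                     class = "faers_cases"))
  }
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  # fall back to lexicographic rank if primaryid is not numeric
  if (anyNA(pid_num)) pid_num <- xtfrm(demo$primaryid)
  key_date <- function(d) {
    x <- as.numeric(d)
    x[is.na(x)] <- -Inf                   # missing dates sort oldest
    x
  }
  ord <- order(demo$caseid, -key_date(demo$fda_date),
               -as.integer(demo$i_f_cod %in% "F"),
               -key_date(demo$event_date), -pid_num)
  ranked <- demo[ord, , drop = FALSE]
  first <- !duplicated(ranked$caseid)
  survivor <- ranked[first, , drop = FALSE]
  if (!"provenance" %in% names(demo)) {
    survivor$provenance <- unname(split(
      ranked$primaryid, factor(ranked$caseid, levels = survivor$caseid)))
  }
  removed <- ranked[!first, , drop = FALSE]
  dedup_log <- tibble(caseid = removed$caseid,
                      survivor = survivor$primaryid[
                        match(removed$caseid, survivor$caseid)],
                      removed = removed$primaryid)
  keep <- survivor$primaryid
  filt <- lapply(raw[c("drug", "reac", "indi", "ther", "outc")], function(t) {
    t[t$primaryid %in% keep, , drop = FALSE]
  })
  structure(c(list(cases = survivor), filt, list(dedup_log = dedup_log)),
            class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases> ", nrow(x$cases), " deduplicated cases (",
      nrow(x$dedup_log), " report versions removed)\n", sep = "")
  invisible(x)
}

#' Write the deduplication log as CSV
#'
#' @param fc A `faers_cases` object.
#' @param path Output file.
#' @export
write_dedup_log <- function(fc, path) {
  readr::write_csv(fc$dedup_log, path)
  invisible(path)
}
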