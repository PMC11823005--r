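# Builders for small in-code fixtures shared across tests.

# demo-table row(s) with analysis columns already attached, as join_cases
# would produce them
make_demo <- function(primaryid, caseid = primaryid, i_f_cod = "I",
                      fda_date = as.Date("2020-01-01"),
                      event_date = as.Date(NA),
                      event_precision = "missing",
                      sex = "F", age_years = 50, occp_cod = "CN",
                      reporter_country = "US") {
  tibble::tibble(primaryid = as.character(primaryid),
                 caseid = as.character(caseid),
                 i_f_cod = i_f_cod, fda_date = fda_date,
                 event_date = event_date,
                 event_precision = event_precision,
                 sex = sex, age_years = age_years, occp_cod = occp_cod,
                 reporter_country = reporter_country)
}

empty_child <- function(...) {
  cols <- c("primaryid", ...)
  tibble::as_tibble(stats::setNames(
    rep(list(character(0)), length(cols)), cols))
}

# a faers_raw-shaped object from hand-built tables
make_raw <- function(demo,
                     drug = empty_child("drug_seq", "role_cod", "drugname"),
                     reac = empty_child("pt"),
                     indi = empty_child("indi_drug_seq", "indi_pt"),
                     ther = empty_child("dsg_drug_seq", "start_dt",
                                        "end_dt"),
                     outc = empty_child("outc_cod")) {
  structure(list(demo = demo, drug = drug, reac = reac, indi = indi,
                 ther = ther, outc = outc,
                 orphans = tibble::tibble(table = character(0),
                                          n = integer(0)),
                 log = NULL),
            class = "faers_raw")
}

# a deduplicated faers_cases-shaped object (bypasses dedup for unit tests
# that exercise downstream modules in isolation)
make_fc <- function(demo, ...) {
  raw <- make_raw(demo, ...)
  structure(c(list(cases = raw$demo),
              raw[c("drug", "reac", "indi", "ther", "outc")],
              list(dedup_log = tibble::tibble(caseid = character(0),
                                              survivor = character(0),
                                              removed = character(0)))),
            class = "faers_cases")
}

# write one "$"-delimited table file
write_faers_file <- function(path, header, rows) {
  writeLines(c(paste(header, collapse = "$"),
               vapply(rows, paste, character(1), collapse = "$")),
             path)
  path
}

# toy hierarchy built in code, independent of the shipped fixture
toy_hierarchy <- function() {
  tibble::tribble(
    ~pt, ~hlt, ~hlgt, ~soc, ~primary_soc,
    "HEADACHE", "Headaches NEC", "Headaches", "Nervous system disorders", 1,
    "HEAD PAIN", "Headaches NEC", "Headaches", "Nervous system disorders", 1,
    "MIGRAINE", "Migraine headaches", "Headaches",
      "Nervous system disorders", 1,
    "ANXIETY", "Anxiety symptoms", "Anxiety disorders and symptoms",
      "Psychiatric disorders", 1,
    "PANIC ATTACK", "Panic attacks", "Anxiety disorders and symptoms",
      "Psychiatric disorders", 1,
    "NAUSEA", "Nausea symptoms", "GI signs", "Gastrointestinal disorders", 1,
    # multiaxial: HEADACHE also linked (non-primary) under general disorders
    "HEADACHE", "Pain NEC", "General NEC", "General disorders", 0,
    # PT linked only under a non-primary SOC row plus its primary home
    "NAUSEA", "General symptoms", "General NEC", "General disorders", 0)
}

# a 12-case dating fixture covering every onset exclusion reason;
# expectations are the (onset, reason) columns
tto_fixture <- function() {
  spec <- tibble::tribble(
    ~caseid, ~event_dt,   ~start_dt,   ~onset, ~reason,
    "c01",   "20230117",  "20230101",  16L,    NA,           # clean 16 days
    "c02",   "20230101",  "20230101",  NA,     "non-positive",
    "c03",   "20230401",  "20230501",  NA,     "start-after-event",
    "c04",   "",          "20230101",  NA,     "missing date",
    "c05",   "20230117",  "",          NA,     "missing date",
    "c06",   "202301",    "20230101",  NA,     "partial date",
    "c07",   "20230117",  "202301",    NA,     "partial date",
    "c08",   "2023",      "20230101",  NA,     "partial date",
    "c09",   "20230117",  "2023",      NA,     "partial date",
    "c10",   "20230102",  "20230101",  1L,     NA,           # 1 day
    "c11",   "20231231",  "20230101",  364L,   NA,
    "c12",   "",          "",          NA,     "missing date")
  evt <- parse_partial_date(spec$event_dt)
  demo <- make_demo(spec$caseid) |>
    dplyr::mutate(event_date = evt$date, event_precision = evt$precision)
  ther <- tibble::tibble(primaryid = spec$caseid, dsg_drug_seq = "1",
                         start_dt = spec$start_dt, end_dt = "")
  exposures <- tibble::tibble(caseid = spec$caseid, primaryid = spec$caseid,
                              drug_seq = "1", role_cod = "PS",
                              class = "GLP-1RA", generic = "SEMAGLUTIDE")
  list(fc = make_fc(demo, ther = ther), exposures = exposures, spec = spec)
}
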