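test_that("partial-date dialect maps 4/6/8-digit strings by length", {
  pd <- parse_partial_date(c("20230117", "202301", "2023", "", NA,
                             "banana", "20231301", "20230230", "123"))
  expect_equal(pd$precision,
               c("day", "month", "year", "missing", "missing",
                 "missing", "missing", "missing", "missing"))
  expect_equal(pd$date[[1]], as.Date("2023-01-17"))
  expect_true(all(is.na(pd$date[-1])))
})

test_that("age normalization applies the FAERS unit codes", {
  got <- normalize_age(c("45", "5", "24", "104.355", "730", "8766",
                         "30", "-1"),
                       c("YR", "DEC", "MON", "WK", "DY", "HR", "", "YR"))
  expect_equal(got, c(45, 50, 2, 2, 730 / 365.25, 1, 30, NA))
  expect_true(is.na(normalize_age("45", "LIGHTYEARS")))
})

test_that("a well-formed DEMO file parses losslessly with zero rejects", {
  hdr <- c("primaryid", "caseid", "i_f_cod", "event_dt", "fda_dt", "age",
           "age_cod", "sex", "occp_cod", "reporter_country", "mystery_col")
  rows <- list(
    c("101", "11", "I", "202301", "20230214", "45", "YR", "F", "CN", "US",
      "x1"),
    c("102", "12", "F", "20230110", "20230220", "540", "MON", "M", "MD",
      "CA", "x2"),
    c("103", "13", "I", "", "20230301", "", "", "", "", "GB", "x3"))
  f <- withr::local_tempfile(fileext = ".txt")
  write_faers_file(f, hdr, rows)
  t <- read_faers_table(f, "DEMO", "current")
  load <- attr(t, "load")
  expect_equal(load$accepted, 3L)
  expect_equal(load$rejected, 0L)
  # lossless: mandatory fields reproduce the written values byte-for-byte
  for (i in 1:3) {
    expect_equal(unname(unlist(t[i, hdr[1:10]])), rows[[i]][1:10])
  }
  # unknown columns are preserved as opaque extras
  expect_equal(t$mystery_col, c("x1", "x2", "x3"))
})

test_that("malformed rows and empty keys are rejected and accounted for", {
  hdr <- c("primaryid", "pt")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(paste(hdr, collapse = "$"),
               "1$HEADACHE",
               "2$NAUSEA$EXTRA_FIELD",   # wrong column count
               "$ANXIETY",               # empty key
               "3$MIGRAINE"),
             f)
  t <- read_faers_table(f, "REAC", "current")
  load <- attr(t, "load")
  expect_equal(load$accepted, 2L)
  expect_equal(load$rejected, 2L)
  expect_equal(load$accepted + load$rejected, load$rows)
  expect_equal(t$primaryid, c("1", "3"))
})

test_that("a trailing empty field is not a malformed row", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$dsg_drug_seq$start_dt$end_dt", "9$1$20200101$"), f)
  t <- read_faers_table(f, "THER", "current")
  expect_equal(attr(t, "load")$rejected, 0L)
  expect_equal(t$end_dt, "")
})

test_that("a header lacking a mandatory column is a format error", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("pt$something", "HEADACHE$1"), f)
  expect_error(read_faers_table(f, "REAC", "current"), "mandatory")
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f2)
  expect_error(read_faers_table(f2, "REAC", "current"), "header")
})

test_that("join_cases joins children, flags incomplete, excludes orphans", {
  dir <- withr::local_tempdir()
  write_faers_file(file.path(dir, "DEMO23Q1.txt"),
                   c("primaryid", "caseid", "i_f_cod", "event_dt", "fda_dt",
                     "age", "age_cod", "sex", "occp_cod",
                     "reporter_country"),
                   list(c("101", "11", "I", "20230110", "20230201", "45",
                          "YR", "F", "CN", "US"),
                        c("102", "12", "I", "", "20230202", "", "", "M",
                          "MD", "US")))
  write_faers_file(file.path(dir, "DRUG23Q1.txt"),
                   c("primaryid", "drug_seq", "role_cod", "drugname"),
                   list(c("101", "1", "PS", "OZEMPIC"),
                        c("101", "2", "C", "ASPIRIN")))
  write_faers_file(file.path(dir, "REAC23Q1.txt"),
                   c("primaryid", "pt"),
                   list(c("101", "HEADACHE"),
                        c("999", "NAUSEA")))       # orphan
  raw <- join_cases(read_faers(dir))
  expect_equal(nrow(raw$demo), 2L)
  expect_equal(sum(raw$drug$primaryid == "101"), 2L)
  expect_equal(sum(raw$reac$primaryid == "101"), 1L)
  expect_equal(raw$orphans$n[raw$orphans$table == "reac"], 1L)
  # 102 has neither drug nor reaction rows -> incomplete, but kept
  expect_equal(raw$demo$incomplete, c(FALSE, TRUE))
  expect_equal(raw$demo$age_years, c(45, NA))
  expect_equal(raw$demo$event_precision, c("day", "missing"))
})

test_that("the same case encoded in both schema eras joins identically", {
  case_current <- list(
    DEMO = list(c("primaryid", "caseid", "i_f_cod", "event_dt", "fda_dt",
                  "age", "age_cod", "sex", "occp_cod", "reporter_country"),
                c("555", "55", "F", "20110510", "20110601", "61", "YR",
                  "F", "MD", "US")),
    DRUG = list(c("primaryid", "drug_seq", "role_cod", "drugname"),
                c("555", "1", "PS", "VICTOZA")),
    REAC = list(c("primaryid", "pt"), c("555", "MIGRAINE")),
    INDI = list(c("primaryid", "indi_drug_seq", "indi_pt"),
                c("555", "1", "TYPE 2 DIABETES MELLITUS")),
    THER = list(c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
                c("555", "1", "20110401", "")),
    OUTC = list(c("primaryid", "outc_cod"), c("555", "HO")))
  case_legacy <- list(
    DEMO = list(c("ISR", "CASE", "i_f_cod", "event_dt", "fda_dt", "age",
                  "age_cod", "gndr_cod", "occp_cod", "reporter_country"),
                c("555", "55", "F", "20110510", "20110601", "61", "YR",
                  "F", "MD", "US")),
    DRUG = list(c("ISR", "drug_seq", "role_cod", "drugname"),
                c("555", "1", "PS", "VICTOZA")),
    REAC = list(c("ISR", "pt"), c("555", "MIGRAINE")),
    INDI = list(c("ISR", "drug_seq", "indi_pt"),
                c("555", "1", "TYPE 2 DIABETES MELLITUS")),
    THER = list(c("ISR", "drug_seq", "start_dt", "end_dt"),
                c("555", "1", "20110401", "")),
    OUTC = list(c("ISR", "outc_cod"), c("555", "HO")))
  write_case <- function(spec, dir, quarter_suffix) {
    for (kind in names(spec)) {
      write_faers_file(file.path(dir, paste0(kind, quarter_suffix, ".txt")),
                       spec[[kind]][[1]], spec[[kind]][2])
    }
    dir
  }
  d_cur <- write_case(case_current, withr::local_tempdir(), "13Q1")
  d_leg <- write_case(case_legacy, withr::local_tempdir(), "11Q2")
  raw_cur <- join_cases(read_faers(d_cur))
  raw_leg <- join_cases(read_faers(d_leg))
  shared <- c("primaryid", "caseid", "i_f_cod", "event_dt", "fda_dt",
              "age", "age_cod", "sex", "occp_cod", "reporter_country",
              "age_years", "event_date", "fda_date", "incomplete")
  expect_equal(raw_cur$demo[shared], raw_leg$demo[shared])
  for (k in c("drug", "reac", "indi", "ther", "outc")) {
    cols <- setdiff(names(raw_cur[[k]]), "quarter")
    expect_equal(raw_cur[[k]][cols], raw_leg[[k]][cols])
  }
})

test_that("quarter labels parse, order and map to the right era", {
  expect_equal(quarter_era(c("2010q1", "2012q3", "2012q4", "2024q1")),
               c("legacy", "legacy", "current", "current"))
  expect_error(parse_quarter("2013qq"), "unparseable")
})
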