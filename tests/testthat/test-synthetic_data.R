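test_that("the injected-odds arithmetic follows the closed form", {
  # odds = ror * p0/(1-p0); p1 = odds/(1+odds)
  expect_equal(odds_p1(4, 0.05), (4 * 0.05 / 0.95) / (1 + 4 * 0.05 / 0.95),
               tolerance = 1e-15)
  expect_equal(odds_p1(1, 0.3), 0.3, tolerance = 1e-15)
  # saturation guard
  expect_error(sim_config(n_cases = 10, signals = tibble::tibble(
    target = "GLP-1RA", level = "class", group = "headache",
    true_ror = 1e6, stratum = "all")), "saturate")
})

test_that("identical configurations produce byte-identical files", {
  cfg <- sim_config(n_cases = 400, seed = 2024)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_faers(cfg, d1)
  simulate_faers(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_equal(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("every emitted file parses with zero rejected rows", {
  cfg <- sim_config(n_cases = 800, seed = 31)
  dir <- withr::local_tempdir()
  simulate_faers(cfg, dir)
  ft <- read_faers(dir)
  expect_true(all(ft$log$rejected == 0))
  expect_equal(sum(ft$log$accepted), sum(ft$log$rows))
  # both schema eras are exercised by the emitted quarters
  expect_setequal(unique(quarter_era(discover_quarters(dir))),
                  c("legacy", "current"))
})

test_that("raw report counts match the duplicate ledger exactly", {
  cfg <- sim_config(n_cases = 1000, seed = 12, duplicate_rate = 0.2)
  sim <- simulate_cases(cfg)
  ledger <- sim$truth$duplicate_ledger
  expect_equal(nrow(sim$tables$demo), sum(ledger$versions))
  fc <- deduplicate(join_cases(sim$tables))
  expect_equal(nrow(fc$cases), 1000L)
  # follow-up versions share the caseid under a distinct, later primaryid
  dups <- ledger$caseid[ledger$versions > 1]
  demo_dup <- sim$tables$demo[sim$tables$demo$caseid %in% dups, ]
  per <- split(demo_dup, demo_dup$caseid)
  expect_true(all(vapply(per, function(d) {
    length(unique(d$primaryid)) == nrow(d) &&
      d$fda_dt[d$i_f_cod == "F"][1] > min(d$fda_dt)
  }, logical(1))))
})

test_that("empirical cell frequencies track the truth expectations", {
  cfg <- sim_config(n_cases = 50000, seed = 8,
                    duplicate_rate = 0,
                    signals = tibble::tibble(
                      target = "GLP-1RA", level = "class",
                      group = "headache", true_ror = 4, stratum = "all"))
  sim <- simulate_cases(cfg)
  fc <- deduplicate(join_cases(sim$tables))
  exp <- case_exposures(fc)
  t_ids <- exposed_ids(exp, class = "GLP-1RA")
  c_ids <- comparator_ids(exp, unique(fc$cases$caseid), "database")
  ae <- cases_with_pts(fc, cfg$group_pts$headache)
  ct <- build_contingency(t_ids, c_ids, ae)
  tr <- sim$truth$signals
  # three standard errors, binomial per arm
  p1 <- tr$expected_a / (tr$expected_a + tr$expected_b)
  p0 <- tr$expected_c / (tr$expected_c + tr$expected_d)
  se_a <- sqrt((tr$expected_a + tr$expected_b) * p1 * (1 - p1))
  se_c <- sqrt((tr$expected_c + tr$expected_d) * p0 * (1 - p0))
  expect_lt(abs(ct$a - tr$expected_a), 3 * se_a)
  expect_lt(abs(ct$c - tr$expected_c), 3 * se_c)
  # and the implied odds ratio of the expected cells is the injected one
  expect_equal((tr$expected_a * tr$expected_d) /
                 (tr$expected_b * tr$expected_c), 4, tolerance = 1e-10)
})

test_that("the full round-trip check passes against its own truth", {
  cfg <- sim_config(n_cases = 8000, seed = 21,
                    signals = tibble::tibble(
                      target = "GLP-1RA", level = "class",
                      group = "sensory nerve abnormalities",
                      true_ror = 4, stratum = "all"))
  report <- round_trip_check(cfg, withr::local_tempdir())
  expect_true(report$pass[report$check == "dedup case count"])
  expect_true(report$pass[report$check == "rejected rows"])
  # with a strong injected signal and n = 8000 the CI covers the truth
  expect_true(report$pass[grepl("sensory", report$check)])
})
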