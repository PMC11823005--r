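test_that("proportional rows give a null odds ratio", {
  r <- compute_ror(10, 90, 100, 900)
  expect_equal(r$ror, 1)
  expect_true(r$ci_lower < 1 && r$ci_upper > 1)
})

test_that("the Wald log formula reproduces a hand-computed table", {
  r <- compute_ror(20, 80, 50, 850)
  expect_equal(r$ror, 4.25, tolerance = 1e-12)
  # frozen from exp(ln 4.25 -/+ 1.96 * sqrt(1/20 + 1/80 + 1/50 + 1/850))
  expect_equal(r$ci_lower, 2.4107840505, tolerance = 1e-9)
  expect_equal(r$ci_upper, 7.4923757673, tolerance = 1e-9)
  expect_true(r$ci_lower < r$ror && r$ror < r$ci_upper)
})

test_that("a zero cell makes the result not estimable, never corrected", {
  r <- compute_ror(c(3, 0, 5), c(0, 10, 5), c(10, 10, 0), c(100, 100, 9))
  expect_equal(r$estimable, c(FALSE, FALSE, FALSE))
  expect_true(all(is.na(r$ror)))
  f <- flag_signal(r)
  expect_false(any(f$is_signal))
})

test_that("the signal rule needs n >= 3 and a CI lower bound above 1", {
  res <- tibble::tibble(n = c(197, 2, 50, 3, 3),
                        ci_lower = c(4.30, 3.0, 1.00, 1.01, 0.99),
                        estimable = TRUE)
  expect_equal(flag_signal(res)$is_signal,
               c(TRUE, FALSE, FALSE, TRUE, FALSE))
  # the count threshold is configurable
  expect_true(flag_signal(res, n_min = 2)$is_signal[[2]])
})

test_that("contingency cells count cases, not reaction rows", {
  demo <- dplyr::bind_rows(lapply(1:4, function(i) make_demo(as.character(i))))
  reac <- tibble::tibble(
    primaryid = c("1", "1", "3", "2", "4"),
    pt = c("HEADACHE", "HEAD PAIN", "MIGRAINE", "NAUSEA", "NAUSEA"))
  fc <- make_fc(demo, reac = reac)
  ae <- cases_with_pts(fc, c("HEADACHE", "HEAD PAIN", "MIGRAINE"))
  ct <- build_contingency(c("1", "2"), c("3", "4"), ae)
  # case 1 has two matching PTs but counts once
  expect_equal(unlist(ct[, c("a", "b", "c", "d")]),
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  # overlapping membership goes to the target arm only
  ct2 <- build_contingency(c("1", "2"), c("2", "3", "4"), ae)
  expect_equal(ct2$overlap, 1L)
  expect_equal(ct2$c + ct2$d, 2L)
})

test_that("cells match a brute-force per-case recount on synthetic data", {
  cfg <- sim_config(n_cases = 1000, seed = 55, duplicate_rate = 0)
  sim <- simulate_cases(cfg)
  fc <- deduplicate(join_cases(sim$tables))
  exp <- case_exposures(fc)
  truth <- sim$truth$cases
  gp <- cfg$group_pts$headache
  t_ids <- exposed_ids(exp, class = "GLP-1RA")
  c_ids <- comparator_ids(exp, unique(fc$cases$caseid), "database")
  ae <- cases_with_pts(fc, gp)
  ct <- build_contingency(t_ids, c_ids, ae)
  # independent full enumeration: loop over cases, re-derive membership
  # from the generator's truth and the raw reaction rows
  a <- b <- c_ <- d <- 0L
  for (i in seq_len(nrow(truth))) {
    cid <- truth$caseid[[i]]
    pid <- fc$cases$primaryid[fc$cases$caseid == cid]
    has_ae <- any(fc$reac$pt[fc$reac$primaryid == pid] %in% gp)
    if (truth$class[[i]] %in% "GLP-1RA") {
      if (has_ae) a <- a + 1L else b <- b + 1L
    } else {
      if (has_ae) c_ <- c_ + 1L else d <- d + 1L
    }
  }
  expect_equal(unlist(ct[, c("a", "b", "c", "d")]),
               c(a = a, b = b, c = c_, d = d))
})

test_that("swapping arms inverts the ROR and the CI", {
  r <- compute_ror(12, 34, 56, 78)
  s <- compute_ror(56, 78, 12, 34)
  expect_equal(s$ror, 1 / r$ror, tolerance = 1e-12)
  expect_equal(s$ci_lower, 1 / r$ci_upper, tolerance = 1e-12)
  expect_equal(s$ci_upper, 1 / r$ci_lower, tolerance = 1e-12)
})

test_that("the PT scan filters by count and tiers by the CI lower bound", {
  n_t <- 200
  n_c <- 4000
  demo <- dplyr::bind_rows(lapply(seq_len(n_t + n_c),
                                  function(i) make_demo(as.character(i))))
  t_ids <- as.character(1:n_t)
  c_ids <- as.character((n_t + 1):(n_t + n_c))
  reac <- dplyr::bind_rows(
    tibble::tibble(primaryid = t_ids[1:40], pt = "HEADACHE"),
    tibble::tibble(primaryid = c_ids[1:80], pt = "HEADACHE"),
    tibble::tibble(primaryid = t_ids[41:70], pt = "ANXIETY"),
    tibble::tibble(primaryid = c_ids[81:280], pt = "ANXIETY"),
    tibble::tibble(primaryid = t_ids[71:72], pt = "MIGRAINE"),
    tibble::tibble(primaryid = c_ids[300:301], pt = "MIGRAINE"),
    tibble::tibble(primaryid = t_ids[73:78], pt = "NAUSEA"),
    tibble::tibble(primaryid = c_ids[302:1500], pt = "NAUSEA"))
  fc <- make_fc(demo, reac = reac)
  exp <- tibble::tibble(caseid = t_ids, primaryid = t_ids, drug_seq = "1",
                        role_cod = "PS", class = "GLP-1RA",
                        generic = "SEMAGLUTIDE")
  scan <- scan_pts(fc, exp, c("HEADACHE", "ANXIETY", "MIGRAINE", "NAUSEA"),
                   t_ids, c_ids)
  # MIGRAINE has n = 2 < 3: excluded
  expect_false("MIGRAINE" %in% scan$pt)
  # HEADACHE: (40, 160, 80, 3920) -> ROR 12.25, strongly positive
  hd <- scan[scan$pt == "HEADACHE", ]
  expect_equal(hd$ror, (40 / 160) / (80 / 3920), tolerance = 1e-12)
  expect_equal(hd$tier, "strong")
  expect_gt(hd$ci_lower, 3)
  # ANXIETY lands in the moderate band
  ax <- scan[scan$pt == "ANXIETY", ]
  expect_equal(ax$tier, "moderate")
  expect_true(ax$ci_lower > 1 && ax$ci_lower <= 3)
  # NAUSEA is depleted in the target arm
  expect_equal(scan$tier[scan$pt == "NAUSEA"], "none")
})
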