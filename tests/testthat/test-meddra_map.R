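test_that("a consistent toy hierarchy loads and collapses duplicates", {
  h <- load_meddra_hierarchy(toy_hierarchy())
  expect_s3_class(h, "meddra_hierarchy")
  # duplicate (pt, soc) rows collapse
  h2 <- load_meddra_hierarchy(dplyr::bind_rows(toy_hierarchy(),
                                               toy_hierarchy()[1, ]))
  expect_equal(nrow(h2), nrow(h))
})

test_that("a PT with zero or two primary SOCs is a validation error", {
  bad2 <- dplyr::bind_rows(
    toy_hierarchy(),
    tibble::tibble(pt = "HEADACHE", hlt = "X", hlgt = "Y",
                   soc = "Psychiatric disorders", primary_soc = 1))
  expect_error(load_meddra_hierarchy(bad2), "HEADACHE")
  bad0 <- toy_hierarchy()
  bad0$primary_soc[bad0$pt == "MIGRAINE"] <- 0
  expect_error(load_meddra_hierarchy(bad0), "MIGRAINE")
})

test_that("primary-SOC selection follows the primary flag, not all links", {
  h <- load_meddra_hierarchy(toy_hierarchy())
  expect_setequal(pts_for_primary_soc(h, "Nervous system disorders"),
                  c("HEADACHE", "HEAD PAIN", "MIGRAINE"))
  expect_setequal(pts_for_primary_soc(h, "Psychiatric disorders"),
                  c("ANXIETY", "PANIC ATTACK"))
  # HEADACHE and NAUSEA are multiaxially linked under General disorders,
  # but their primary home is elsewhere
  expect_equal(pts_for_primary_soc(h, "General disorders"), character(0)[0])
  expect_warning(got <- pts_for_primary_soc(h, "No such SOC"), "not present")
  expect_equal(got, character(0))
})

test_that("primary SOCs partition the PT universe", {
  h <- load_meddra_hierarchy(toy_hierarchy())
  per_soc <- lapply(unique(h$soc), function(s) {
    suppressWarnings(pts_for_primary_soc(h, s))
  })
  all_pts <- unlist(per_soc)
  expect_equal(sort(all_pts), sort(unique(h$pt)))
  expect_false(any(duplicated(all_pts)))
})

test_that("group selectors resolve by level and union without double count", {
  h <- load_meddra_hierarchy(toy_hierarchy())
  groups <- tibble::tibble(
    group = c("headache", "headache", "anxiety"),
    level = c("HLT", "PT", "HLGT"),
    term = c("Headaches NEC", "HEADACHE", "Anxiety disorders and symptoms"))
  got <- resolve_ae_groups(groups, h)
  # the PT selector overlaps the HLT selector: union, not double count
  expect_equal(got$headache, sort(c("HEADACHE", "HEAD PAIN")))
  # HLGT selector covers all child HLTs (brute-force transitive closure)
  oracle <- unique(toy_hierarchy()$pt[
    toy_hierarchy()$hlgt == "Anxiety disorders and symptoms"])
  expect_setequal(got$anxiety, oracle)
})

test_that("resolution is monotone in selectors and stable under row order", {
  h_rows <- toy_hierarchy()
  base <- tibble::tibble(group = "g", level = "HLT", term = "Headaches NEC")
  more <- dplyr::bind_rows(base, tibble::tibble(group = "g", level = "HLT",
                                                term = "Migraine headaches"))
  h <- load_meddra_hierarchy(h_rows)
  expect_true(all(resolve_ae_groups(base, h)$g %in%
                    resolve_ae_groups(more, h)$g))
  set.seed(5)
  h_perm <- load_meddra_hierarchy(h_rows[sample(nrow(h_rows)), ])
  expect_equal(resolve_ae_groups(more, h_perm), resolve_ae_groups(more, h))
})

test_that("an empty selector is a configuration error", {
  h <- load_meddra_hierarchy(toy_hierarchy())
  expect_error(resolve_ae_groups(
    tibble::tibble(group = "g", level = "HLT", term = "No such HLT"), h),
    "resolves to no PT")
})

test_that("the shipped hierarchy and eight default groups are coherent", {
  h <- synthetic_hierarchy()
  groups <- default_ae_groups()
  expect_setequal(unique(groups$group),
                  c("headache", "migraine", "anxiety", "depression",
                    "suicide-related", "sleep disorders",
                    "olfactory nerve abnormalities",
                    "sensory nerve abnormalities"))
  pts <- resolve_ae_groups(groups, h)
  expect_true(all(lengths(pts) > 0))
  # every group PT belongs to one of the two neuropsychiatric SOCs
  neuro <- c(pts_for_primary_soc(h, "Psychiatric disorders"),
             pts_for_primary_soc(h, "Nervous system disorders"))
  expect_true(all(unlist(pts) %in% neuro))
})
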