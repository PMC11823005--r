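# Synthetic spontaneous-report generator.
#
# Emits FAERS-format quarterly files with known ground truth so the whole
# pipeline — ingestion, deduplication, exposure classification, signal
# detection, time-to-onset — can be verified without the real database.
#
# Probability model for injected signals: comparator cases report a given
# adverse-event group with probability p0; for cases exposed to a signal
# drug the reporting odds are multiplied, p1/(1-p1) = true_ror * p0/(1-p0),
# so the expected 2x2 table has cross-product ratio (a*d)/(b*c) equal to
# the injected true ROR.
#
# Onset times are drawn as round(log-normal) with the location parameter
# set so the distribution's median equals the configured per-drug median,
# reproducing the right-skewed onset pattern typical of spontaneous
# reports (median well below the mean).

SIM_OTHER_DRUGS <- c("ASPIRIN", "LISINOPRIL", "ATORVASTATIN", "OMEPRAZOLE",
                     "LEVOTHYROXINE", "AMLODIPINE")

sim_default_drug_mix <- function() {
  c(DULAGLUTIDE = 0.10, SEMAGLUTIDE = 0.09, TIRZEPATIDE = 0.05,
    LIRAGLUTIDE = 0.04, EXENATIDE = 0.02,
    SITAGLIPTIN = 0.06, GLIMEPIRIDE = 0.04, METFORMIN = 0.10,
    EMPAGLIFLOZIN = 0.04, PIOGLITAZONE = 0.02, INSULIN = 0.06,
    ORLISTAT = 0.03, PHENTERMINE = 0.03, `NALTREXONE-BUPROPION` = 0.03,
    `PHENTERMINE-TOPIRAMATE` = 0.02,
    OTHER = 0.27)
}

# Background per-group reporting rates, calibrated once so that the
# share of GLP-1RA reports carrying any neuropsychiatric PT lands near
# the ~13.5% observed for this drug class.
sim_default_background_ae <- function() {
  c(headache = 0.025, migraine = 0.006, anxiety = 0.015, depression = 0.015,
    `suicide-related` = 0.006, `sleep disorders` = 0.015,
    `olfactory nerve abnormalities` = 0.003,
    `sensory nerve abnormalities` = 0.012)
}

sim_default_extra_pts <- function() {
  c(NAUSEA = 0.12, VOMITING = 0.07, DIARRHOEA = 0.07, FATIGUE = 0.08,
    DIZZINESS = 0.015, IRRITABILITY = 0.005, `INJECTION SITE PAIN` = 0.04)
}

sim_default_signals <- function() {
  tibble(target = c("GLP-1RA", "GLP-1RA", "GLP-1RA", "GLP-1RA",
                    "SEMAGLUTIDE"),
         level = c("class", "class", "class", "class", "generic"),
         group = c("headache", "migraine", "olfactory nerve abnormalities",
                   "sensory nerve abnormalities", "suicide-related"),
         true_ror = c(1.74, 1.28, 2.44, 1.69, 2.55),
         stratum = c("all", "all", "all", "all", "weight-loss"))
}

sim_default_tto <- function() {
  tibble(generic = c("DULAGLUTIDE", "SEMAGLUTIDE", "TIRZEPATIDE",
                     "LIRAGLUTIDE", "EXENATIDE"),
         median_days = c(7, 27, 13, 16, 28))
}

#' Configuration for the synthetic-report generator
#'
#' Defaults reflect the reporting environment the pipeline is built for:
#' a GLP-1RA share of roughly 30% of reports split across the five
#' agents, non-GLP-1RA antidiabetic and anti-obesity comparator drugs,
#' indication mixes dominated by diabetes with substantial missingness,
#' injected class-level signals for headache, migraine, olfactory and
#' sensory nerve abnormalities plus a semaglutide suicide-related signal
#' confined to the weight-loss stratum, right-skewed per-drug onset-time
#' distributions, a 20% duplicate/follow-up rate, and field-level
#' missingness typical of spontaneous reports.
#'
#' @param n_cases Number of unique cases to generate.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the configuration.
#' @param years Calendar years receipts are spread over (linearly
#'   increasing weight, emulating report growth).
#' @param drug_mix Named probabilities over primary-suspect generics
#'   (`OTHER` is the non-dictionary background); must sum to 1.
#' @param background_ae Named per-group background reporting
#'   probabilities p0.
#' @param extra_pts Named probabilities of non-neuropsychiatric
#'   background PTs.
#' @param signals Tibble `target`, `level` (`"class"`/`"generic"`),
#'   `group`, `true_ror`, `stratum` (`"all"`, `"DM"`, `"weight-loss"`).
#' @param tto Tibble `generic`, `median_days` of onset-time medians;
#'   drugs not listed use `tto_default_median`.
#' @param tto_default_median,tto_sdlog Log-normal onset parameters
#'   (median in days; dispersion on the log scale).
#' @param duplicate_rate Fraction of cases emitted with a superseded
#'   initial version in addition to the final one.
#' @param wrong_date_rate,zero_onset_rate Fractions of cases emitted with
#'   an event date before / equal to the therapy start (exercising the
#'   exclusion rules).
#' @param missingness List of rates: `event`, `event_partial`, `start`,
#'   `start_partial`, `age`.
#' @param hierarchy,groups Hierarchy and group selectors used to draw
#'   reaction PTs; default to the shipped synthetic hierarchy and the
#'   eight default groups.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cases = 20000, seed = 1,
                       years = 2010:2023,
                       drug_mix = sim_default_drug_mix(),
                       background_ae = sim_default_background_ae(),
                       extra_pts = sim_default_extra_pts(),
                       signals = sim_default_signals(),
                       tto = sim_default_tto(),
                       tto_default_median = 16, tto_sdlog = 2.2,
                       duplicate_rate = 0.2,
                       wrong_date_rate = 0.02, zero_onset_rate = 0.01,
                       missingness = list(event = 0.22, event_partial = 0.08,
                                          start = 0.28, start_partial = 0.07,
                                          age = 0.459),
                       hierarchy = synthetic_hierarchy(),
                       groups = default_ae_groups()) {
  stopifnot(n_cases >= 1, length(seed) == 1)
  if (abs(sum(drug_mix) - 1) > 1e-8) {
    abort("drug_mix probabilities must sum to 1")
  }
  stopifnot(all(drug_mix >= 0), all(background_ae >= 0 & background_ae <= 1),
            duplicate_rate >= 0, duplicate_rate < 1,
            all(signals$true_ror > 0))
  group_pts <- resolve_ae_groups(groups, hierarchy)
  missing_groups <- setdiff(names(background_ae), names(group_pts))
  if (length(missing_groups) > 0) {
    abort(paste0("background_ae names lack group definitions: ",
                 paste(missing_groups, collapse = ", ")))
  }
  bad_sig <- setdiff(signals$group, names(background_ae))
  if (length(bad_sig) > 0) {
    abort(paste0("signals reference groups without a background rate: ",
                 paste(bad_sig, collapse = ", ")))
  }
  # p1 sanity: extreme true_ror with a large p0 saturates the odds model
  p0 <- background_ae[signals$group]
  odds1 <- signals$true_ror * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  if (any(p1 > 0.999)) {
    abort("injected odds saturate (p1 ~ 1); use a smaller background rate")
  }
  structure(list(n_cases = as.integer(n_cases), seed = as.integer(seed),
                 years = years, drug_mix = drug_mix,
                 background_ae = background_ae, extra_pts = extra_pts,
                 signals = signals, tto = tto,
                 tto_default_median = tto_default_median,
                 tto_sdlog = tto_sdlog,
                 duplicate_rate = duplicate_rate,
                 wrong_date_rate = wrong_date_rate,
                 zero_onset_rate = zero_onset_rate,
                 missingness = missingness,
                 group_pts = group_pts),
            class = "sim_config")
}

# generic -> dictionary class for the shipped dictionary, OTHER -> NA
sim_generic_class <- function(generic) {
  dict <- default_drug_dictionary() |> distinct(.data$generic, .data$class)
  cls <- dict$class[match(generic, dict$generic)]
  cls
}

sim_category <- function(class) {
  dplyr::case_when(class %in% "GLP-1RA" ~ "glp1ra",
                   class %in% antidiabetic_classes() ~ "antidiabetic",
                   class %in% antiobesity_classes() ~ "antiobesity",
                   TRUE ~ "other")
}

# verbatim names: brand or generic, occasionally decorated with dose/form
sim_verbatim <- function(generic) {
  dict <- default_drug_dictionary()
  deco <- c("", "", "", "", " 1 MG", " 0.5 MG PEN", " INJECTION",
            " 2 MG/1.5 ML")
  out <- character(length(generic))
  for (g in unique(generic)) {
    idx <- which(generic == g)
    pool <- if (g == "OTHER") SIM_OTHER_DRUGS
            else dict$name[dict$generic == g]
    decorate <- if (g == "OTHER") "" else sample(deco, length(idx),
                                                 replace = TRUE)
    out[idx] <- paste0(sample(pool, length(idx), replace = TRUE), decorate)
  }
  out
}

#' Generate synthetic cases as FAERS-shaped tables
#'
#' Draws the full case-level model — primary-suspect drug, indication,
#' adverse-event groups (with injected odds where a signal applies),
#' reaction PTs, therapy start and event dates with onset drawn from the
#' per-drug log-normal, demographics with configured missingness,
#' outcomes, concomitant drugs, and superseded initial versions for the
#' configured duplicate fraction — and returns the six FAERS tables in
#' their serialized (all-character) form plus the ground truth.
#'
#' @param config A `sim_config`.
#' @return A list with `tables` (named list `demo`, `drug`, `reac`,
#'   `indi`, `ther`, `outc` of character tibbles in canonical column
#'   layout) and `truth` (see Details).  `truth` holds: `signals` with
#'   p0/p1 and expected cell counts, `tto` with per-drug true medians,
#'   `duplicate_ledger` (caseid, versions), `n_cases`, and the
#'   missingness rates.
#' @export
simulate_cases <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases
  ms <- config$missingness

  caseid <- as.character(10000000 + seq_len(n))
  generic <- sample(names(config$drug_mix), n, replace = TRUE,
                    prob = config$drug_mix)
  class <- sim_generic_class(generic)
  category <- sim_category(class)

  # indication mix conditional on drug category
  ind_mix <- list(
    glp1ra = c(DM = 0.544, `weight-loss` = 0.085, missing = 0.371),
    antidiabetic = c(DM = 0.75, `weight-loss` = 0.02, missing = 0.23),
    antiobesity = c(DM = 0.05, `weight-loss` = 0.72, missing = 0.23),
    other = c(DM = 0.10, `weight-loss` = 0.08, missing = 0.82))
  indication <- character(n)
  for (cat in names(ind_mix)) {
    idx <- which(category == cat)
    if (length(idx) > 0) {
      indication[idx] <- sample(names(ind_mix[[cat]]), length(idx),
                                replace = TRUE, prob = ind_mix[[cat]])
    }
  }

  # adverse-event group draws with injected odds
  group_names <- names(config$background_ae)
  has_group <- matrix(FALSE, n, length(group_names),
                      dimnames = list(NULL, group_names))
  prob_group <- matrix(rep(config$background_ae, each = n), n,
                       length(group_names),
                       dimnames = list(NULL, group_names))
  sig_mask <- function(sig) {
    m <- if (sig$level == "class") class %in% sig$target
         else generic == toupper(sig$target)
    if (sig$stratum != "all") m <- m & indication == sig$stratum
    m
  }
  for (i in seq_len(nrow(config$signals))) {
    sig <- as.list(config$signals[i, ])
    p0 <- config$background_ae[[sig$group]]
    odds <- sig$true_ror * p0 / (1 - p0)
    prob_group[sig_mask(sig), sig$group] <- odds / (1 + odds)
  }
  for (g in group_names) {
    has_group[, g] <- runif(n) < prob_group[, g]
  }

  # expected contingency cells per signal (conditional on drug/indication)
  truth_signals <- purrr::map_dfr(seq_len(nrow(config$signals)), function(i) {
    sig <- as.list(config$signals[i, ])
    p0 <- config$background_ae[[sig$group]]
    strat <- if (sig$stratum == "all") rep(TRUE, n)
             else indication == sig$stratum
    tmask <- sig_mask(sig)
    # comparator: in-stratum cases not exposed to the target's class
    tclass <- if (sig$level == "class") sig$target else "GLP-1RA"
    cmask <- strat & !(class %in% tclass)
    pa <- prob_group[tmask, sig$group]
    pc <- prob_group[cmask & !tmask, sig$group]
    tibble(target = sig$target, level = sig$level, group = sig$group,
           stratum = sig$stratum, true_ror = sig$true_ror,
           p0 = p0, p1 = odds_p1(sig$true_ror, p0),
           expected_a = sum(pa), expected_b = sum(1 - pa),
           expected_c = sum(pc), expected_d = sum(1 - pc))
  })

  # onset times: per-drug log-normal medians
  med <- config$tto$median_days[match(generic, config$tto$generic)]
  med[is.na(med)] <- config$tto_default_median
  # rounded log-normal with a floor of one day: without the floor the
  # sub-half-day mass rounds to 0, gets excluded by the positivity rule,
  # and biases the analyzable median upward; flooring keeps the median at
  # the configured value.  The extreme tail is clamped so emitted
  # calendar dates stay sane (clamp far above the upper quartile).
  onset <- pmax(1L, as.integer(round(rlnorm(n, meanlog = log(med),
                                            sdlog = config$tto_sdlog))))
  onset <- pmin(onset, 2000L)

  # dates: therapy start in the sampled receipt year, event = start + onset,
  # receipt = event + reporting delay
  year <- sample(config$years, n, replace = TRUE,
                 prob = seq_along(config$years))
  start_date <- as.Date(paste0(year, "-01-01")) +
    sample.int(365, n, replace = TRUE) - 1L
  event_date <- start_date + onset
  wrong <- runif(n) < config$wrong_date_rate
  zero <- !wrong & runif(n) < config$zero_onset_rate
  event_date[wrong] <- start_date[wrong] - sample.int(60, sum(wrong),
                                                      replace = TRUE)
  event_date[zero] <- start_date[zero]
  fda_date <- event_date + 7L + as.integer(round(rlnorm(n, log(30), 0.8)))
  fda_date <- pmax(fda_date, start_date + 1L)  # receipts follow initiation

  # date missingness: truncation to month/year exercises partial dates
  fmt_partial <- function(d, r_missing, r_partial) {
    u <- runif(length(d))
    out <- format(d, "%Y%m%d")
    part <- u >= r_missing & u < r_missing + r_partial
    half <- runif(length(d)) < 0.5
    out[part & half] <- format(d[part & half], "%Y%m")
    out[part & !half] <- format(d[part & !half], "%Y")
    out[u < r_missing] <- ""
    out
  }
  event_dt <- fmt_partial(event_date, ms$event, ms$event_partial)
  start_dt <- fmt_partial(start_date, ms$start, ms$start_partial)
  fda_dt <- format(fda_date, "%Y%m%d")       # receipt date always present

  # demographics
  age_band <- sample(c("missing", "<18", "18-65", "65-85", ">85"), n,
                     replace = TRUE,
                     prob = c(ms$age, 0.008, 0.333, 0.198, 0.002))
  age_years <- dplyr::case_when(
    age_band == "<18" ~ runif(n, 8, 17.9),
    age_band == "18-65" ~ runif(n, 18, 64.9),
    age_band == "65-85" ~ runif(n, 65, 85),
    age_band == ">85" ~ runif(n, 85.1, 95),
    TRUE ~ NA_real_)
  in_months <- age_band != "missing" & runif(n) < 0.02
  age <- ifelse(is.na(age_years), "",
                ifelse(in_months, as.character(round(age_years * 12)),
                       as.character(floor(age_years))))
  age_cod <- ifelse(is.na(age_years), "", ifelse(in_months, "MON", "YR"))
  sex <- sample(c("F", "M", ""), n, replace = TRUE,
                prob = c(0.632, 0.315, 0.053))
  occp <- sample(c("CN", "MD", "PH", "OT", ""), n, replace = TRUE,
                 prob = c(0.786, 0.07, 0.04, 0.04, 0.064))
  country <- sample(c("US", "CA", "GB", "FR", "JP", "DE"), n,
                    replace = TRUE,
                    prob = c(0.80, 0.05, 0.05, 0.04, 0.03, 0.03))

  # versions: duplicated cases carry a superseded initial version
  dup <- runif(n) < config$duplicate_rate
  pid_final <- paste0(caseid, "2")
  pid_old <- paste0(caseid, "1")
  i_f_final <- ifelse(dup, "F", sample(c("I", "F"), n, replace = TRUE,
                                       prob = c(0.7, 0.3)))

  demo_final <- tibble(primaryid = pid_final, caseid = caseid,
                       i_f_cod = i_f_final, event_dt = event_dt,
                       fda_dt = fda_dt, age = age, age_cod = age_cod,
                       sex = sex, occp_cod = occp,
                       reporter_country = country)
  old_fda <- fda_date - (30L + sample.int(150, n, replace = TRUE))
  demo_old <- demo_final[dup, ] |>
    mutate(primaryid = pid_old[dup], i_f_cod = "I",
           fda_dt = format(old_fda[dup], "%Y%m%d"))
  demo <- bind_rows(demo_final, demo_old)

  # drug rows: PS suspect + occasional concomitant / secondary suspect
  verbatim <- sim_verbatim(generic)
  drug_ps <- tibble(primaryid = pid_final, drug_seq = "1",
                    role_cod = "PS", drugname = verbatim)
  conmed <- runif(n) < 0.40
  drug_c <- tibble(primaryid = pid_final[conmed], drug_seq = "2",
                   role_cod = "C",
                   drugname = sample(SIM_OTHER_DRUGS, sum(conmed),
                                     replace = TRUE))
  ss <- runif(n) < 0.05
  dict_names <- default_drug_dictionary()$name
  drug_ss <- tibble(primaryid = pid_final[ss], drug_seq = "3",
                    role_cod = "SS",
                    drugname = sample(dict_names, sum(ss), replace = TRUE))
  drug <- bind_rows(drug_ps, drug_c, drug_ss)

  # reactions: one PT per drawn group plus background PTs; every case
  # reports at least one PT
  reac_parts <- list()
  for (g in group_names) {
    idx <- which(has_group[, g])
    if (length(idx) > 0) {
      reac_parts[[g]] <- tibble(
        primaryid = pid_final[idx],
        pt = sample(config$group_pts[[g]], length(idx), replace = TRUE))
    }
  }
  for (p in names(config$extra_pts)) {
    idx <- which(runif(n) < config$extra_pts[[p]])
    if (length(idx) > 0) {
      reac_parts[[paste0("x_", p)]] <- tibble(primaryid = pid_final[idx],
                                              pt = p)
    }
  }
  reac <- bind_rows(reac_parts)
  bare <- setdiff(pid_final, reac$primaryid)
  if (length(bare) > 0) {
    reac <- bind_rows(reac, tibble(
      primaryid = bare,
      pt = sample(names(config$extra_pts), length(bare), replace = TRUE,
                  prob = config$extra_pts)))
  }
  reac <- reac |> arrange(.data$primaryid, .data$pt)

  # indications for the suspect drug
  ind_pt <- dplyr::case_when(
    indication == "DM" ~ "TYPE 2 DIABETES MELLITUS",
    indication == "weight-loss" ~ sample(c("OBESITY", "WEIGHT MANAGEMENT"),
                                         n, replace = TRUE),
    TRUE ~ NA_character_)
  has_ind <- !is.na(ind_pt)
  indi <- tibble(primaryid = pid_final[has_ind], indi_drug_seq = "1",
                 indi_pt = ind_pt[has_ind])

  # therapy dates for the suspect drug
  ther <- tibble(primaryid = pid_final, dsg_drug_seq = "1",
                 start_dt = start_dt, end_dt = "")

  # outcomes (worst-case realism: a fatal case may also carry HO)
  outc_code <- sample(c("", "HO", "DE", "LT", "DS", "OT"), n,
                      replace = TRUE,
                      prob = c(0.63, 0.118, 0.008, 0.007, 0.06, 0.177))
  has_outc <- outc_code != ""
  outc <- tibble(primaryid = pid_final[has_outc],
                 outc_cod = outc_code[has_outc])
  extra_ho <- which(outc_code == "DE" & runif(n) < 0.3)
  if (length(extra_ho) > 0) {
    outc <- bind_rows(outc, tibble(primaryid = pid_final[extra_ho],
                                   outc_cod = "HO"))
  }

  # superseded versions carry the same children under their own primaryid
  dup_ids <- tibble(new = pid_final[dup], old = pid_old[dup])
  clone <- function(t) {
    cl <- t |> inner_join(dup_ids, by = c(primaryid = "new"))
    cl$primaryid <- cl$old
    bind_rows(t, cl |> select(-"old"))
  }
  tables <- list(demo = demo, drug = clone(drug), reac = clone(reac),
                 indi = clone(indi), ther = clone(ther),
                 outc = clone(outc))

  truth <- list(
    cases = tibble(caseid = caseid, generic = generic, class = class,
                   indication = indication, onset_days = onset),
    signals = truth_signals,
    tto = tibble(generic = unique(generic[generic != "OTHER"])) |>
      mutate(true_median = {
        m <- config$tto$median_days[match(.data$generic,
                                          config$tto$generic)]
        ifelse(is.na(m), config$tto_default_median, m)
      }),
    duplicate_ledger = tibble(caseid = caseid,
                              versions = 1L + as.integer(dup)),
    n_cases = n,
    n_reports = nrow(demo),
    missingness = ms)
  list(tables = tables, truth = truth)
}

odds_p1 <- function(true_ror, p0) {
  odds <- true_ror * p0 / (1 - p0)
  odds / (1 + odds)
}

# emission column layout per era (canonical value -> file column name)
sim_emit_layout <- function(era) {
  if (era == "current") {
    list(
      DEMO = c(primaryid = "primaryid", caseid = "caseid",
               i_f_cod = "i_f_cod", event_dt = "event_dt",
               fda_dt = "fda_dt", age = "age", age_cod = "age_cod",
               sex = "sex", occp_cod = "occp_cod",
               reporter_country = "reporter_country"),
      DRUG = c(primaryid = "primaryid", drug_seq = "drug_seq",
               role_cod = "role_cod", drugname = "drugname"),
      REAC = c(primaryid = "primaryid", pt = "pt"),
      INDI = c(primaryid = "primaryid", indi_drug_seq = "indi_drug_seq",
               indi_pt = "indi_pt"),
      THER = c(primaryid = "primaryid", dsg_drug_seq = "dsg_drug_seq",
               start_dt = "start_dt", end_dt = "end_dt"),
      OUTC = c(primaryid = "primaryid", outc_cod = "outc_cod"))
  } else {
    list(
      DEMO = c(primaryid = "ISR", caseid = "CASE", i_f_cod = "i_f_cod",
               event_dt = "event_dt", fda_dt = "fda_dt", age = "age",
               age_cod = "age_cod", sex = "gndr_cod",
               occp_cod = "occp_cod",
               reporter_country = "reporter_country"),
      DRUG = c(primaryid = "ISR", drug_seq = "drug_seq",
               role_cod = "role_cod", drugname = "drugname"),
      REAC = c(primaryid = "ISR", pt = "pt"),
      INDI = c(primaryid = "ISR", indi_drug_seq = "drug_seq",
               indi_pt = "indi_pt"),
      THER = c(primaryid = "ISR", dsg_drug_seq = "drug_seq",
               start_dt = "start_dt", end_dt = "end_dt"),
      OUTC = c(primaryid = "ISR", outc_cod = "outc_cod"))
  }
}

#' Emit synthetic FAERS quarterly files
#'
#' Splits the generated reports into quarters by FDA receipt date, writes
#' each quarter's six tables in the FAERS "$"-delimited dialect — using
#' the legacy ISR-keyed layout for quarters through 2012Q3 and the
#' primaryid-keyed layout afterwards — and serializes the ground truth as
#' a JSON sidecar (`sim_truth.json`).
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the simulation result of [simulate_cases()] with
#'   `dir` and the emitted `quarters` attached.
#' @export
simulate_faers <- function(config, dir) {
  sim <- simulate_cases(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  demo <- sim$tables$demo
  yr <- as.integer(substr(demo$fda_dt, 1, 4))
  mo <- as.integer(substr(demo$fda_dt, 5, 6))
  q <- (mo - 1) %/% 3 + 1
  quarter <- paste0(yr, "q", q)
  pid_quarter <- setNames(quarter, demo$primaryid)
  for (qt in sort(unique(quarter))) {
    era <- quarter_era(qt)
    layout <- sim_emit_layout(era)
    yy <- sprintf("%02d", as.integer(substr(qt, 1, 4)) %% 100)
    qq <- substr(qt, 6, 6)
    for (kind in FAERS_TABLE_KINDS) {
      t <- sim$tables[[tolower(kind)]]
      t <- t[pid_quarter[t$primaryid] == qt, , drop = FALSE]
      cols <- layout[[kind]]
      lines <- c(paste(unname(cols), collapse = "$"),
                 do.call(paste, c(unname(as.list(t[names(cols)])),
                                  list(sep = "$"))))
      writeLines(lines, file.path(dir, paste0(kind, yy, "Q", qq, ".txt")))
    }
  }
  truth <- sim$truth
  jsonlite::write_json(
    list(signals = truth$signals, tto = truth$tto,
         n_cases = truth$n_cases, n_reports = truth$n_reports,
         n_duplicates = sum(truth$duplicate_ledger$versions > 1),
         missingness = truth$missingness),
    file.path(dir, "sim_truth.json"), auto_unbox = TRUE, digits = NA)
  sim$dir <- dir
  sim$quarters <- sort(unique(quarter))
  invisible(sim)
}

#' End-to-end recovery check on synthetic data
#'
#' Runs simulate -> ingest -> deduplicate -> classify -> disproportionality
#' and time-to-onset, and compares the estimates with the generator's
#' ground truth: the dedup case count must match exactly, each injected
#' signal's 95% CI is checked for covering its true ROR, and each
#' per-drug onset median is compared with its planted median.
#'
#' @param config A `sim_config`.
#' @param dir Directory for the emitted files (default a temporary one).
#' @param tto_tolerance Relative tolerance on recovered medians.
#' @return A tibble of checks: `check`, `expected`, `observed`, `pass`.
#' @export
round_trip_check <- function(config, dir = tempfile("simfaers"),
                             tto_tolerance = 0.1) {
  sim <- simulate_faers(config, dir)
  ft <- read_faers(dir)
  fc <- deduplicate(join_cases(ft))
  exp <- case_exposures(fc)
  checks <- list()
  checks$dedup <- tibble(check = "dedup case count",
                         expected = sim$truth$n_cases,
                         observed = nrow(fc$cases),
                         pass = nrow(fc$cases) == sim$truth$n_cases)
  checks$rejects <- tibble(check = "rejected rows",
                           expected = 0,
                           observed = sum(ft$log$rejected),
                           pass = sum(ft$log$rejected) == 0)
  for (i in seq_len(nrow(sim$truth$signals))) {
    sig <- as.list(sim$truth$signals[i, ])
    universe <- stratum_ids(fc, sig$stratum)
    t_ids <- intersect(universe,
                       exposed_ids(exp,
                                   class = if (sig$level == "class")
                                     sig$target,
                                   generic = if (sig$level == "generic")
                                     sig$target))
    c_ids <- comparator_ids(exp, universe, "database")
    ae <- cases_with_pts(fc, config$group_pts[[sig$group]])
    ct <- build_contingency(t_ids, c_ids, ae)
    r <- compute_ror(ct$a, ct$b, ct$c, ct$d)
    checks[[paste0("sig", i)]] <- tibble(
      check = paste0("ROR CI covers truth: ", sig$target, " / ", sig$group,
                     " (", sig$stratum, ")"),
      expected = sig$true_ror, observed = r$ror,
      pass = r$estimable && r$ci_lower <= sig$true_ror &&
        sig$true_ror <= r$ci_upper)
  }
  tto <- compute_tto(fc, exp)
  med <- tto_summary_table(tto)
  truth_tto <- sim$truth$tto
  for (i in seq_len(nrow(truth_tto))) {
    g <- truth_tto$generic[[i]]
    obs <- med$median_days[med$generic == g]
    obs <- if (length(obs) == 0) NA_real_ else obs
    checks[[paste0("tto_", g)]] <- tibble(
      check = paste0("median onset: ", g),
      expected = truth_tto$true_median[[i]], observed = obs,
      pass = !is.na(obs) &&
        abs(obs - truth_tto$true_median[[i]]) <=
          tto_tolerance * truth_tto$true_median[[i]])
  }
  bind_rows(checks)
}
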