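# Drug-name normalization, dictionary-based class assignment, and the
# primary-suspect exposure filter.
#
# FAERS drug names are free text ("Ozempic 1 mg injection", "SEMAGLUTIDE").
# A dictionary maps generic and brand names to a drug class; matching is by
# word boundary within the normalized verbatim name by default, so embedded
# doses and forms do not defeat it.

DEFAULT_NAME_SUFFIXES <- c(
  "PEN", "INJECTION", "INJ", "SOLUTION", "SUSPENSION", "TABLET", "TABLETS",
  "CAPSULE", "CAPSULES", "ORAL", "SUBCUTANEOUS", "PREFILLED", "SYRINGE",
  "AUTOINJECTOR", "AUTO-INJECTOR", "XR", "ER",
  "MG", "ML", "MCG", "G", "UNIT", "UNITS", "%"
)

#' Normalize a verbatim drug name
#'
#' Upper-cases, trims, collapses internal whitespace, and strips trailing
#' dosage/form tokens (e.g. `"1 MG"`, `"PEN"`, `"INJECTION"`) according to
#' a configurable suffix list.  Purely numeric trailing tokens and
#' number+unit tokens such as `"0.5MG"` are also stripped.
#'
#' @param x Character vector of verbatim drug names.
#' @param suffixes Tokens to strip from the end of the name.
#' @return Normalized names.
#' @export
normalize_drug_name <- function(x, suffixes = DEFAULT_NAME_SUFFIXES) {
  up <- toupper(trimws(x))
  up <- stringr::str_squish(up)
  is_strippable <- function(tok) {
    tok %in% suffixes |
      grepl("^[0-9.,/]+$", tok) |
      grepl("^[0-9.]+(MG|MCG|ML|G|IU|UNITS?)(/[0-9.]*(MG|MCG|ML|G|DOSE|DAY|WEEK))?$",
            tok)
  }
  vapply(strsplit(up, " ", fixed = TRUE), function(tok) {
    while (length(tok) > 1 && is_strippable(tok[length(tok)])) {
      tok <- tok[-length(tok)]
    }
    paste(tok, collapse = " ")
  }, character(1))
}

#' The drug dictionary shipped with the package
#'
#' Covers the five GLP-1 receptor agonists (exenatide, liraglutide,
#' dulaglutide, semaglutide, tirzepatide) with their brand names, the
#' common non-GLP-1RA antidiabetic classes (DPP-4 inhibitors,
#' sulfonylureas, metformin, SGLT2 inhibitors, thiazolidinediones,
#' insulins) and the non-GLP-1RA anti-obesity drugs (orlistat,
#' phentermine, naltrexone-bupropion, phentermine-topiramate).  The
#' dictionary is a reconstruction from public labeling; users with their
#' own curated name lists should load a replacement with
#' [load_drug_dictionary()].
#'
#' @return A drug dictionary tibble (`class`, `generic`, `name`,
#'   `match_mode`), one row per matchable name.
#' @export
default_drug_dictionary <- function() {
  if (is.null(.extdata_cache$dict)) {
    .extdata_cache$dict <- load_drug_dictionary(
      system.file("extdata", "drug_dictionary.csv",
                  package = "faersignal", mustWork = TRUE))
  }
  .extdata_cache$dict
}

.extdata_cache <- new.env(parent = emptyenv())

#' Drug classes forming the antidiabetic / anti-obesity comparator pools
#' @return Character vector of class labels.
#' @export
antidiabetic_classes <- function() {
  c("DPP-4 inhibitor", "sulfonylurea", "metformin", "SGLT2 inhibitor",
    "thiazolidinedione", "insulin")
}

#' @rdname antidiabetic_classes
#' @export
antiobesity_classes <- function() {
  "anti-obesity"
}

#' Load and validate a drug dictionary
#'
#' The dictionary is a CSV with columns `class`, `generic`, `brands`
#' (semicolon-separated, may be empty) and `match_mode` (`"word"` for
#' word-boundary substring matching, `"exact"` for whole-name equality).
#' It is expanded to one row per matchable name (the generic itself plus
#' each brand), upper-cased and trimmed.  A name mapped to more than one
#' class or generic is a configuration error; all collisions are listed.
#'
#' @param path CSV file path.
#' @return A tibble with columns `class`, `generic`, `name`, `match_mode`.
#' @export
load_drug_dictionary <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  need <- c("class", "generic", "brands", "match_mode")
  if (!all(need %in% names(raw))) {
    abort(paste0("drug dictionary must have columns ",
                 paste(need, collapse = ", ")))
  }
  dict <- raw |>
    mutate(brands = ifelse(is.na(.data$brands), "", .data$brands)) |>
    rowwise() |>
    reframe(class = .data$class, generic = toupper(trimws(.data$generic)),
            name = toupper(trimws(c(.data$generic,
                                    strsplit(.data$brands, ";")[[1]]))),
            match_mode = .data$match_mode) |>
    filter(nzchar(.data$name)) |>
    distinct()
  collisions <- dict |>
    group_by(.data$name) |>
    filter(n_distinct(.data$class) > 1 | n_distinct(.data$generic) > 1) |>
    ungroup()
  if (nrow(collisions) > 0) {
    offenders <- collisions |>
      group_by(.data$name) |>
      summarise(maps = paste(unique(paste0(.data$class, "/", .data$generic)),
                             collapse = ", "), .groups = "drop")
    abort(paste0("drug dictionary collision(s): ",
                 paste(paste0(offenders$name, " -> ", offenders$maps),
                       collapse = "; ")))
  }
  dict
}

#' Classify drug entries into dictionary classes
#'
#' Matches each drug row's normalized verbatim name against the dictionary
#' and emits one exposure assignment per matched (drug entry x generic),
#' restricted to the requested role codes.  With the default
#' `roles = "PS"` a report whose only dictionary-drug entries carry
#' secondary-suspect, concomitant or interacting roles yields no
#' assignment — the primary-suspect inclusion filter.
#'
#' @param drug Drug table (columns `primaryid`, `drug_seq`, `role_cod`,
#'   `drugname`).
#' @param dict Drug dictionary from [load_drug_dictionary()].
#' @param roles Role codes to keep; `NULL` keeps all four FAERS roles.
#' @return A tibble of exposure assignments: `primaryid`, `drug_seq`,
#'   `role_cod`, `class`, `generic`.
#' @export
classify_drugs <- function(drug, dict = default_drug_dictionary(),
                           roles = "PS") {
  d <- drug
  if (!is.null(roles)) d <- d[toupper(d$role_cod) %in% toupper(roles), ,
                              drop = FALSE]
  if (nrow(d) == 0) {
    return(tibble(primaryid = character(0), drug_seq = character(0),
                  role_cod = character(0), class = character(0),
                  generic = character(0)))
  }
  raw_uniq <- unique(d$drugname)
  norm <- normalize_drug_name(raw_uniq)[match(d$drugname, raw_uniq)]
  uniq <- unique(norm)
  # exact entries: direct lookup; word entries: boundary regex scan
  hits <- vector("list", nrow(dict))
  for (i in seq_len(nrow(dict))) {
    nm <- dict$name[[i]]
    matched <- if (identical(dict$match_mode[[i]], "exact")) {
      uniq == nm
    } else {
      # "-" counts as a word character so a combination generic like
      # PHENTERMINE-TOPIRAMATE is not also hit by its components
      stringr::str_detect(uniq, paste0("(?<![A-Z0-9-])",
                                       stringr::str_escape(nm),
                                       "(?![A-Z0-9-])"))
    }
    if (any(matched)) {
      hits[[i]] <- tibble(norm = uniq[matched],
                          class = dict$class[[i]],
                          generic = dict$generic[[i]])
    }
  }
  lookup <- bind_rows(hits) |> distinct()
  if (nrow(lookup) == 0) {
    return(tibble(primaryid = character(0), drug_seq = character(0),
                  role_cod = character(0), class = character(0),
                  generic = character(0)))
  }
  tibble(primaryid = d$primaryid, drug_seq = d$drug_seq,
         role_cod = toupper(d$role_cod), norm = norm) |>
    inner_join(lookup, by = "norm", relationship = "many-to-many") |>
    select(-"norm") |>
    distinct() |>
    arrange(.data$primaryid, .data$drug_seq, .data$generic)
}

#' Case-level exposures for deduplicated cases
#'
#' Joins drug-entry exposure assignments to the deduplicated case table so
#' downstream counting is per case.
#'
#' @param fc A `faers_cases` object.
#' @param dict Drug dictionary.
#' @param roles Role codes to keep (default primary suspect only).
#' @return A tibble `caseid`, `primaryid`, `drug_seq`, `role_cod`,
#'   `class`, `generic`, one row per assignment.
#' @export
case_exposures <- function(fc, dict = default_drug_dictionary(),
                           roles = "PS") {
  classify_drugs(fc$drug, dict, roles) |>
    inner_join(fc$cases |> select("primaryid", "caseid"), by = "primaryid") |>
    relocate("caseid")
}
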