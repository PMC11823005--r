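# MedDRA-style hierarchy handling.
#
# MedDRA itself is licensed and cannot be redistributed, so the package
# defines a table format (pt / hlt / hlgt / soc / primary_soc) that a
# licensed user can export into, and ships a small synthetic hierarchy
# covering the preferred terms emitted by the synthetic-report generator.
# MedDRA is multiaxial: a PT may sit under several SOCs, but exactly one
# link is flagged as the primary SOC, and cohort selection is by primary
# SOC only.

#' Load and validate a PT/HLT/HLGT/SOC hierarchy table
#'
#' @param path A TSV with columns `pt`, `hlt`, `hlgt`, `soc`,
#'   `primary_soc` (0/1 or logical), one row per PT-to-SOC link.
#'   Alternatively a data frame of the same shape.
#' @return A validated `meddra_hierarchy` tibble with `pt` upper-cased,
#'   duplicate (pt, soc) rows collapsed.  A PT with zero or more than one
#'   primary-SOC row is a validation error naming every offender.
#' @export
load_meddra_hierarchy <- function(path) {
  h <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  }
  need <- c("pt", "hlt", "hlgt", "soc", "primary_soc")
  if (!all(need %in% names(h))) {
    abort(paste0("hierarchy must have columns ", paste(need, collapse = ", ")))
  }
  h <- h |>
    mutate(pt = toupper(trimws(.data$pt)),
           hlt = trimws(.data$hlt),
           hlgt = trimws(.data$hlgt),
           soc = trimws(.data$soc),
           primary_soc = as.logical(as.integer(.data$primary_soc))) |>
    distinct(.data$pt, .data$soc, .keep_all = TRUE)
  prim <- h |>
    group_by(.data$pt) |>
    summarise(n_primary = sum(.data$primary_soc), .groups = "drop")
  bad <- prim |> filter(.data$n_primary != 1)
  if (nrow(bad) > 0) {
    abort(paste0("invalid hierarchy: PT(s) without exactly one primary SOC: ",
                 paste(paste0(bad$pt, " (", bad$n_primary, ")"),
                       collapse = ", ")))
  }
  class(h) <- c("meddra_hierarchy", class(h))
  h
}

#' The synthetic hierarchy shipped with the package
#'
#' A small MedDRA-style table covering the preferred terms used by the
#' synthetic-report generator, including the neuropsychiatric terms of the
#' eight default adverse-event groups, common gastrointestinal and general
#' background terms, and a few multiaxial (non-primary) links.  It is a
#' synthetic stand-in, not MedDRA content.
#'
#' @return A `meddra_hierarchy` tibble.
#' @export
synthetic_hierarchy <- function() {
  if (is.null(.extdata_cache$hierarchy)) {
    .extdata_cache$hierarchy <- load_meddra_hierarchy(
      system.file("extdata", "synthetic_meddra.tsv",
                  package = "faersignal", mustWork = TRUE))
  }
  .extdata_cache$hierarchy
}

#' Preferred terms whose primary SOC is the given SOC
#'
#' @param h A `meddra_hierarchy`.
#' @param soc SOC name (matched case-insensitively, trimmed).
#' @return Character vector of PTs.  An unknown SOC yields an empty set
#'   with a warning.
#' @export
pts_for_primary_soc <- function(h, soc) {
  target <- tolower(trimws(soc))
  if (!target %in% tolower(h$soc)) {
    warn(paste0("SOC not present in hierarchy: ", soc))
    return(character(0))
  }
  sort(unique(h$pt[h$primary_soc & tolower(h$soc) == target]))
}

#' Default adverse-event group definitions
#'
#' The eight neuropsychiatric groups analyzed by the pipeline — headache,
#' migraine, anxiety, depression, suicide-related, sleep disorders,
#' olfactory nerve abnormalities, sensory nerve abnormalities — each
#' defined by one or more HLT/HLGT (or PT) selectors.  The shipped
#' selectors name terms of the synthetic hierarchy; users with licensed
#' MedDRA replace this file with their own term choices.
#'
#' @param path CSV with columns `group`, `level` (`PT`/`HLT`/`HLGT`),
#'   `term`.
#' @return A tibble of selectors.
#' @export
default_ae_groups <- function(path = system.file("extdata", "ae_groups.csv",
                                                 package = "faersignal",
                                                 mustWork = TRUE)) {
  g <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  need <- c("group", "level", "term")
  if (!all(need %in% names(g))) {
    abort(paste0("group definitions must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (!all(toupper(g$level) %in% c("PT", "HLT", "HLGT"))) {
    abort("group selector level must be PT, HLT or HLGT")
  }
  g$level <- toupper(g$level)
  g
}

#' Resolve adverse-event groups to PT sets
#'
#' Each group's selectors are resolved against the hierarchy — a PT
#' selector names the PT itself, an HLT selector all PTs linked under that
#' HLT (on any axis), an HLGT selector all PTs of all child HLTs — and
#' unioned without double counting.  A selector resolving to no PT is a
#' configuration error.
#'
#' @param groups Selector tibble (`group`, `level`, `term`).
#' @param h A `meddra_hierarchy`.
#' @return Named list: group name -> sorted character vector of PTs.
#' @export
resolve_ae_groups <- function(groups, h) {
  resolve_one <- function(level, term) {
    t <- tolower(trimws(term))
    pts <- switch(level,
      PT = h$pt[tolower(h$pt) == t],
      HLT = h$pt[tolower(h$hlt) == t],
      HLGT = h$pt[tolower(h$hlgt) == t])
    unique(pts)
  }
  out <- lapply(split(groups, groups$group), function(g) {
    pts <- character(0)
    for (i in seq_len(nrow(g))) {
      got <- resolve_one(g$level[[i]], g$term[[i]])
      if (length(got) == 0) {
        abort(paste0("group '", g$group[[i]], "': selector ", g$level[[i]],
                     " '", g$term[[i]], "' resolves to no PT"))
      }
      pts <- union(pts, got)
    }
    sort(pts)
  })
  out[unique(groups$group)]
}
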