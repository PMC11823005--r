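# Ingestion of FAERS-format quarterly ASCII tables.
#
# FAERS quarters are distributed as "$"-delimited text files, one per table
# kind (DEMO, DRUG, REAC, INDI, THER, OUTC).  Quarters up to 2012Q3 use the
# legacy schema keyed by ISR/CASE; from 2012Q4 on the files are keyed by
# primaryid/caseid.  A declarative schema registry maps each era's column
# names onto one canonical set so the rest of the pipeline is era-blind.

FAERS_TABLE_KINDS <- c("DEMO", "DRUG", "REAC", "INDI", "THER", "OUTC")

#' FAERS schema registry
#'
#' Declarative mapping from the column names found in FAERS quarterly files
#' (lower-cased) to the canonical column names used throughout the package,
#' one mapping per table kind and schema era.  The legacy era (through
#' 2012Q3) keys reports by `ISR` and cases by `CASE`; these are mapped to
#' `primaryid` and `caseid`.  Columns not named in the registry are carried
#' through unchanged as opaque extras.
#'
#' @return A nested list: `registry[[era]][[kind]]` is a named character
#'   vector `c(file_column = canonical_column)`.
#' @export
faers_schema <- function() {
  current <- list(
    DEMO = c(primaryid = "primaryid", caseid = "caseid",
             i_f_code = "i_f_cod", i_f_cod = "i_f_cod",
             event_dt = "event_dt", fda_dt = "fda_dt",
             age = "age", age_cod = "age_cod",
             sex = "sex", gndr_cod = "sex",
             occp_cod = "occp_cod", reporter_country = "reporter_country"),
    DRUG = c(primaryid = "primaryid", drug_seq = "drug_seq",
             role_cod = "role_cod", drugname = "drugname"),
    REAC = c(primaryid = "primaryid", pt = "pt"),
    INDI = c(primaryid = "primaryid", indi_drug_seq = "indi_drug_seq",
             indi_pt = "indi_pt"),
    THER = c(primaryid = "primaryid", dsg_drug_seq = "dsg_drug_seq",
             start_dt = "start_dt", end_dt = "end_dt"),
    OUTC = c(primaryid = "primaryid", outc_cod = "outc_cod")
  )
  legacy <- list(
    DEMO = c(isr = "primaryid", "case" = "caseid",
             i_f_cod = "i_f_cod",
             event_dt = "event_dt", fda_dt = "fda_dt",
             age = "age", age_cod = "age_cod",
             gndr_cod = "sex",
             occp_cod = "occp_cod", reporter_country = "reporter_country"),
    DRUG = c(isr = "primaryid", drug_seq = "drug_seq",
             role_cod = "role_cod", drugname = "drugname"),
    REAC = c(isr = "primaryid", pt = "pt"),
    INDI = c(isr = "primaryid", drug_seq = "indi_drug_seq",
             indi_pt = "indi_pt"),
    THER = c(isr = "primaryid", drug_seq = "dsg_drug_seq",
             start_dt = "start_dt", end_dt = "end_dt"),
    OUTC = c(isr = "primaryid", outc_cod = "outc_cod")
  )
  list(legacy = legacy, current = current)
}

# Mandatory canonical columns per table kind; a header lacking any of these
# is a format error, not a row-level reject.
faers_mandatory_columns <- function(kind) {
  switch(kind,
    DEMO = c("primaryid", "caseid"),
    DRUG = c("primaryid", "drug_seq", "role_cod", "drugname"),
    REAC = c("primaryid", "pt"),
    INDI = c("primaryid", "indi_pt"),
    THER = c("primaryid", "dsg_drug_seq", "start_dt"),
    OUTC = c("primaryid", "outc_cod"),
    abort(paste0("unknown FAERS table kind: ", kind))
  )
}

#' Parse a quarter label
#'
#' @param quarter Labels like `"2013q2"` (case-insensitive).
#' @return A tibble with columns `quarter`, `year`, `q`.
#' @export
parse_quarter <- function(quarter) {
  m <- stringr::str_match(tolower(quarter), "^(\\d{4})q([1-4])$")
  if (anyNA(m[, 1])) {
    abort(paste0("unparseable quarter label(s): ",
                 paste(quarter[is.na(m[, 1])], collapse = ", ")))
  }
  tibble(quarter = tolower(quarter),
         year = as.integer(m[, 2]), q = as.integer(m[, 3]))
}

#' Schema era of a quarter
#'
#' Quarters through 2012Q3 use the legacy ISR-keyed layout; 2012Q4 onwards
#' use the primaryid-keyed layout.
#'
#' @param quarter Quarter label(s), e.g. `"2011q4"`.
#' @return `"legacy"` or `"current"` per element.
#' @export
quarter_era <- function(quarter) {
  pq <- parse_quarter(quarter)
  ifelse(pq$year < 2012 | (pq$year == 2012 & pq$q <= 3), "legacy", "current")
}

#' Locate the files of one FAERS quarter
#'
#' Files are expected to follow the FDA naming convention
#' `DEMOyyQq.txt`, `DRUGyyQq.txt`, ... in a single directory.
#'
#' @param dir Directory holding the quarter's files.
#' @param quarter Quarter label, e.g. `"2013q2"`.
#' @return A list with `quarter`, `era` and a named vector `paths` of the
#'   table files that exist.
#' @export
quarter_file_set <- function(dir, quarter) {
  pq <- parse_quarter(quarter)
  stopifnot(nrow(pq) == 1)
  yy <- sprintf("%02d", pq$year %% 100)
  fname <- paste0(FAERS_TABLE_KINDS, yy, "Q", pq$q, ".txt")
  paths <- file.path(dir, fname)
  names(paths) <- FAERS_TABLE_KINDS
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0) {
    abort(paste0("no FAERS files for quarter ", quarter, " under ", dir))
  }
  list(quarter = pq$quarter, era = quarter_era(quarter), paths = paths)
}

#' Discover FAERS quarters in a directory
#'
#' @param dir Directory to scan.
#' @return Character vector of quarter labels, sorted.
#' @export
discover_quarters <- function(dir) {
  f <- list.files(dir)
  m <- stringr::str_match(f, "^(DEMO|DRUG|REAC|INDI|THER|OUTC)(\\d{2})Q([1-4])\\.txt$")
  m <- m[!is.na(m[, 1]), , drop = FALSE]
  if (nrow(m) == 0) return(character(0))
  sort(unique(paste0("20", m[, 3], "q", m[, 4])))
}

#' Read one FAERS table file
#'
#' Parses a "$"-delimited FAERS table.  The delimiter carries no quoting;
#' a row whose field count differs from the header's is rejected and
#' counted, as is a row with an empty report key.  Files are decoded as
#' Latin-1 (FAERS files contain non-UTF-8 bytes).  Columns not known to the
#' schema registry are preserved under their original (lower-cased) names.
#'
#' @param path File path.
#' @param kind Table kind, one of `DEMO`, `DRUG`, `REAC`, `INDI`, `THER`,
#'   `OUTC`.
#' @param era `"legacy"` or `"current"`.
#' @param registry Schema registry, see [faers_schema()].
#' @return A tibble of character columns (canonical names first), with a
#'   `"load"` attribute: a one-row tibble of `kind`, `rows`, `accepted`,
#'   `rejected`.
#' @export
read_faers_table <- function(path, kind, era = "current",
                             registry = faers_schema()) {
  kind <- match.arg(kind, FAERS_TABLE_KINDS)
  era <- match.arg(era, c("legacy", "current"))
  lines <- readr::read_lines(path, locale = readr::locale(encoding = "latin1"))
  if (length(lines) == 0) {
    abort(paste0("format error: ", path, " is empty (missing header)"))
  }
  header <- tolower(trimws(strsplit(lines[[1]], "$", fixed = TRUE)[[1]]))
  mapping <- registry[[era]][[kind]]
  canon <- unname(mapping[header])          # NA where column is an extra
  out_names <- ifelse(is.na(canon), header, canon)
  missing_cols <- setdiff(faers_mandatory_columns(kind), out_names)
  if (length(missing_cols) > 0) {
    abort(paste0("format error in ", path, ": missing mandatory column(s) ",
                 paste(missing_cols, collapse = ", "),
                 " for ", kind, " (", era, " schema)"))
  }
  ncol <- length(header)
  body <- lines[-1]
  body <- body[nzchar(body)]
  n_raw <- length(body)
  # field count per line; strsplit drops trailing empty fields, so count
  # delimiters instead and pad.
  n_fields <- stringr::str_count(body, stringr::fixed("$")) + 1L
  ok <- n_fields == ncol
  rejected <- sum(!ok)
  body <- body[ok]
  if (length(body) > 0) {
    parts <- strsplit(body, "$", fixed = TRUE)
    mat <- matrix("", nrow = length(body), ncol = ncol)
    for (j in seq_len(ncol)) {
      mat[, j] <- trimws(vapply(parts, function(p) {
        if (length(p) >= j) p[[j]] else ""
      }, character(1)))
    }
    df <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                    .name_repair = "minimal")
    names(df) <- out_names
  } else {
    df <- as_tibble(setNames(rep(list(character(0)), ncol), out_names),
                    .name_repair = "minimal")
  }
  # reject rows whose mandatory report key is unparseable (empty)
  key_ok <- nzchar(df$primaryid)
  rejected <- rejected + sum(!key_ok)
  df <- df[key_ok, , drop = FALSE]
  # canonical columns first, extras after
  canon_first <- intersect(unname(mapping), names(df))
  df <- df[, c(canon_first, setdiff(names(df), canon_first)), drop = FALSE]
  attr(df, "load") <- tibble(kind = kind, rows = n_raw,
                             accepted = nrow(df), rejected = rejected)
  df
}

#' Read all tables of one quarter
#'
#' @param qfs A quarter file set from [quarter_file_set()].
#' @param registry Schema registry.
#' @return A list with `tables` (named list of tibbles, one per table kind
#'   present) and `log` (per-file row counts).
#' @export
read_quarter <- function(qfs, registry = faers_schema()) {
  tables <- lapply(names(qfs$paths), function(kind) {
    read_faers_table(qfs$paths[[kind]], kind, qfs$era, registry)
  })
  names(tables) <- names(qfs$paths)
  log <- bind_rows(lapply(tables, attr, "load"))
  log$quarter <- qfs$quarter
  list(tables = tables, log = log[, c("quarter", "kind", "rows",
                                      "accepted", "rejected")])
}

#' Read and pool FAERS quarters from a directory
#'
#' Reads every quarter found under `dir` (or the subset named in
#' `quarters`), resolving the legacy/current schema per quarter, and pools
#' the per-kind tables with a `quarter` column added.
#'
#' @param dir Directory of FAERS quarterly files.
#' @param quarters Optional character vector of quarter labels to read.
#' @return An object of class `faers_tables`: a list with `tables`
#'   (named list `demo`, `drug`, `reac`, `indi`, `ther`, `outc`) and
#'   `log` (load log across files).
#' @export
read_faers <- function(dir, quarters = NULL) {
  quarters <- quarters %||% discover_quarters(dir)
  if (length(quarters) == 0) {
    abort(paste0("no FAERS quarterly files found under ", dir))
  }
  reads <- lapply(quarters, function(q) read_quarter(quarter_file_set(dir, q)))
  pool <- function(kind) {
    parts <- purrr::compact(lapply(seq_along(reads), function(i) {
      t <- reads[[i]]$tables[[kind]]
      if (is.null(t)) return(NULL)
      t$quarter <- quarters[[i]]
      t
    }))
    if (length(parts) == 0) {
      return(tibble(primaryid = character(0), quarter = character(0)))
    }
    bind_rows(parts)
  }
  tables <- lapply(FAERS_TABLE_KINDS, pool)
  names(tables) <- tolower(FAERS_TABLE_KINDS)
  structure(list(tables = tables,
                 log = bind_rows(lapply(reads, `[[`, "log"))),
            class = "faers_tables")
}

#' Parse FAERS partial dates
#'
#' FAERS dates are digit strings of length 8 (`YYYYMMDD`, day precision),
#' 6 (`YYYYMM`, month precision) or 4 (`YYYY`, year precision); anything
#' else — including a calendar-invalid 8-digit string — is treated as
#' missing.
#'
#' @param x Character vector of raw date fields.
#' @return A tibble with columns `raw`, `precision` (one of `"day"`,
#'   `"month"`, `"year"`, `"missing"`) and `date` (a `Date`, non-`NA` only
#'   at day precision).
#' @export
parse_partial_date <- function(x) {
  x <- as.character(x)
  raw <- ifelse(is.na(x), "", trimws(x))
  digits <- grepl("^\\d+$", raw)
  prec <- rep("missing", length(raw))
  prec[digits & nchar(raw) == 4] <- "year"
  prec[digits & nchar(raw) == 6] <- "month"
  prec[digits & nchar(raw) == 8] <- "day"
  # month validity for 6/8-digit forms
  mm <- suppressWarnings(as.integer(substr(raw, 5, 6)))
  bad_month <- prec %in% c("month", "day") & (is.na(mm) | mm < 1 | mm > 12)
  prec[bad_month] <- "missing"
  date <- as.Date(rep(NA_character_, length(raw)))
  is_day <- prec == "day"
  if (any(is_day)) {
    d <- as.Date(raw[is_day], format = "%Y%m%d")
    date[is_day] <- d
    prec[is_day][is.na(d)] <- "missing"   # e.g. Feb 30
  }
  tibble(raw = raw, precision = prec, date = date)
}

#' Normalize FAERS age to years
#'
#' Applies the FAERS age-unit codes: `DEC` decades, `YR` years, `MON`
#' months, `WK` weeks, `DY` days, `HR` hours.  A present value with a
#' missing unit is taken as years (common FAERS practice); an unknown unit
#' code yields `NA`.
#'
#' @param value Character or numeric age values.
#' @param unit Character unit codes.
#' @return Numeric age in years.
#' @export
normalize_age <- function(value, unit) {
  v <- suppressWarnings(as.numeric(value))
  u <- toupper(trimws(ifelse(is.na(unit), "", unit)))
  factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
              DY = 1 / 365.25, HR = 1 / 8766)
  f <- unname(factor[u])
  f[u == ""] <- 1                         # missing unit: treat as years
  out <- v * f
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Join per-table records into raw case reports
#'
#' Attaches parsed dates and normalized age to the demographic table and
#' restricts child tables (drugs, reactions, indications, therapy dates,
#' outcomes) to reports present in DEMO.  Orphan child rows (a primaryid
#' with no DEMO record) are excluded and counted; reports lacking any drug
#' or any reaction are flagged incomplete but kept.
#'
#' @param ft A `faers_tables` object from [read_faers()], or a bare named
#'   list of tables with the same shape.
#' @return An object of class `faers_raw`: a list with `demo` (one row per
#'   report, with `fda_date`, `event_date`, `event_precision`,
#'   `age_years`, `incomplete` added), the filtered child tables, an
#'   `orphans` count table, and the load `log` when available.
#' @export
join_cases <- function(ft) {
  tables <- if (inherits(ft, "faers_tables")) ft$tables else ft
  demo <- tables$demo
  if (is.null(demo) || nrow(demo) == 0) {
    abort("no DEMO records: cannot build case reports")
  }
  # duplicate primaryids within the pooled DEMO (e.g. the same report
  # re-distributed across quarters) keep their first occurrence
  demo <- demo[!duplicated(demo$primaryid), , drop = FALSE]
  fda <- parse_partial_date(demo$fda_dt)
  evt <- parse_partial_date(demo$event_dt)
  demo$fda_date <- fda$date
  demo$fda_precision <- fda$precision
  demo$event_date <- evt$date
  demo$event_precision <- evt$precision
  demo$age_years <- normalize_age(demo$age, demo$age_cod)
  ids <- demo$primaryid
  child <- function(kind) {
    t <- tables[[kind]]
    if (is.null(t)) {
      t <- tibble(primaryid = character(0))
    }
    t
  }
  kinds <- c("drug", "reac", "indi", "ther", "outc")
  filtered <- list()
  orphans <- integer(length(kinds))
  names(orphans) <- kinds
  for (k in kinds) {
    t <- child(k)
    keep <- t$primaryid %in% ids
    orphans[[k]] <- sum(!keep)
    filtered[[k]] <- t[keep, , drop = FALSE]
  }
  has_drug <- demo$primaryid %in% filtered$drug$primaryid
  has_reac <- demo$primaryid %in% filtered$reac$primaryid
  demo$incomplete <- !(has_drug & has_reac)
  structure(
    c(list(demo = demo), filtered,
      list(orphans = enframe(orphans, name = "table", value = "n"),
           log = if (inherits(ft, "faers_tables")) ft$log else NULL)),
    class = "faers_raw")
}

#' @export
print.faers_raw <- function(x, ...) {
  cat("<faers_raw> ", nrow(x$demo), " reports; ",
      nrow(x$drug), " drug rows; ", nrow(x$reac), " reaction rows; ",
      sum(x$orphans$n), " orphan child rows excluded\n", sep = "")
  invisible(x)
}
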