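#' Read FAERS-format quarterly ASCII tables
#'
#' Reads the dollar-delimited DEMO, DRUG, REAC, THER and OUTC tables of one or
#' more FAERS quarterly extracts into typed tibbles. Multiple files per table
#' (e.g. several quarters) are concatenated before any cleaning, since
#' duplicate case versions routinely span quarters.
#'
#' Dates are parsed from 8-digit `YYYYMMDD` strings; 6-digit `YYYYMM` and
#' 4-digit `YYYY` values are recorded as partial (the year is kept, the
#' day-resolution date is absent). Ages are converted to years using the FAERS
#' unit codes YR, MON, DY and DEC; other unit codes leave the age absent.
#'
#' @param paths Either a directory containing files whose names start with
#'   `DEMO`, `DRUG`, `REAC`, `THER`, `OUTC` (case-insensitive), or a named
#'   list/vector with elements `demo`, `drug`, `reac`, `ther`, `outc`, each a
#'   character vector of file paths.
#' @param delim Field delimiter, `"$"` for FAERS extracts.
#' @return A `faers_tables` object: a list of tibbles `demo`, `drug`, `reac`,
#'   `ther`, `outc` with parsed columns (lower-case names), retaining all
#'   original columns as character. Child-table records whose `primaryid` does
#'   not appear in DEMO are dropped with a warning.
#' @export
read_faers_tables <- function(paths, delim = "$") {
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    paths <- find_faers_files(paths)
  }
  need <- c("demo", "drug", "reac", "ther", "outc")
  paths <- as.list(paths)
  names(paths) <- tolower(names(paths))
  missing_tab <- setdiff(c("demo", "drug", "reac"), names(paths))
  if (length(missing_tab)) {
    abort(paste0("Missing FAERS table file(s): ", paste(missing_tab, collapse = ", ")))
  }
  raw <- lapply(setNames(need, need), function(tab) {
    fs <- paths[[tab]]
    if (is.null(fs)) return(tibble(PRIMARYID = character(0)))
    parts <- lapply(fs, read_one_faers_file, delim = delim)
    dplyr::bind_rows(parts)
  })
  parse_raw_tables(raw)
}

find_faers_files <- function(dir) {
  all <- list.files(dir, full.names = TRUE)
  pick <- function(stem) all[grepl(paste0("^", stem), basename(all), ignore.case = TRUE)]
  list(demo = pick("DEMO"), drug = pick("DRUG"), reac = pick("REAC"),
       ther = pick("THER"), outc = pick("OUTC"))
}

read_one_faers_file <- function(path, delim = "$") {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  # Real FAERS files are mixed-encoding; read as UTF-8 with latin1 fallback.
  tb <- tryCatch(
    readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                      quote = "", trim_ws = TRUE, progress = FALSE,
                      na = character(0)),
    error = function(e) {
      readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                        quote = "", trim_ws = TRUE, progress = FALSE,
                        na = character(0),
                        locale = readr::locale(encoding = "latin1"))
    })
  names(tb) <- toupper(names(tb))
  tb
}

require_columns <- function(tb, cols, table) {
  miss <- setdiff(cols, names(tb))
  if (length(miss)) {
    abort(paste0("FAERS ", table, " table is missing mandatory column(s): ",
                 paste(miss, collapse = ", ")))
  }
}

col_or_na <- function(tb, col) {
  if (col %in% names(tb)) {
    x <- trimws(as.character(tb[[col]]))
    x[x == ""] <- NA_character_
    x
  } else rep(NA_character_, nrow(tb))
}

# Shared by read_faers_tables() and the synthetic generator, so generated
# corpora parse exactly like files read from disk.
parse_raw_tables <- function(raw) {
  demo_raw <- raw$demo
  require_columns(demo_raw, c("PRIMARYID", "CASEID"), "DEMO")
  require_columns(raw$drug, c("PRIMARYID", "ROLE_COD", "DRUGNAME"), "DRUG")
  require_columns(raw$reac, c("PRIMARYID", "PT"), "REAC")

  fda <- parse_faers_date(col_or_na(demo_raw, "FDA_DT"))
  evt <- parse_faers_date(col_or_na(demo_raw, "EVENT_DT"))
  n_bad <- sum(fda$precision %in% "invalid") + sum(evt$precision %in% "invalid")
  if (n_bad > 0) warn(paste0(n_bad, " unparseable date value(s) in DEMO set to absent"))

  demo <- tibble(
    primaryid = col_or_na(demo_raw, "PRIMARYID"),
    caseid = col_or_na(demo_raw, "CASEID"),
    caseversion = {
      v <- suppressWarnings(as.integer(col_or_na(demo_raw, "CASEVERSION")))
      dplyr::coalesce(v, 1L)
    },
    fda_date = fda$date,
    fda_year = fda$year,
    event_date = evt$date,
    event_year = evt$year,
    sex = dplyr::case_match(toupper(col_or_na(demo_raw, "SEX")),
                            "F" ~ "female", "M" ~ "male", .default = "unknown"),
    age_years = age_to_years(col_or_na(demo_raw, "AGE"), col_or_na(demo_raw, "AGE_COD")),
    country = col_or_na(demo_raw, "OCCR_COUNTRY"),
    reporter = dplyr::case_match(toupper(col_or_na(demo_raw, "OCCP_COD")),
                                 "MD" ~ "physician", "PH" ~ "pharmacist",
                                 "CN" ~ "consumer",
                                 c("OT", "LW", "RN", "HP") ~ "other",
                                 .default = "unknown")
  )
  if (any(is.na(demo$primaryid)) || any(is.na(demo$caseid))) {
    abort("DEMO contains empty PRIMARYID or CASEID values")
  }

  drug <- tibble(
    primaryid = col_or_na(raw$drug, "PRIMARYID"),
    drug_seq = col_or_na(raw$drug, "DRUG_SEQ"),
    role_cod = toupper(col_or_na(raw$drug, "ROLE_COD")),
    drugname = col_or_na(raw$drug, "DRUGNAME"),
    prod_ai = col_or_na(raw$drug, "PROD_AI")
  )
  reac <- tibble(
    primaryid = col_or_na(raw$reac, "PRIMARYID"),
    pt = normalize_term(col_or_na(raw$reac, "PT"), fold = FALSE)
  )
  reac$pt_norm <- normalize_term(reac$pt)
  ther_start <- parse_faers_date(col_or_na(raw$ther, "START_DT"))
  ther <- tibble(
    primaryid = col_or_na(raw$ther, "PRIMARYID"),
    dsg_drug_seq = col_or_na(raw$ther, "DSG_DRUG_SEQ"),
    start_date = ther_start$date,
    start_year = ther_start$year
  )
  out_code <- toupper(col_or_na(raw$outc, "OUTC_COD"))
  outc <- tibble(
    primaryid = col_or_na(raw$outc, "PRIMARYID"),
    outc_cod = out_code,
    outcome = dplyr::case_match(out_code,
                                "DE" ~ "death", "LT" ~ "life-threatening",
                                "HO" ~ "hospitalization", "DS" ~ "disability",
                                "CA" ~ "congenital anomaly",
                                .default = "other serious")
  )
  outc$outcome[is.na(outc$outc_cod)] <- NA_character_

  tabs <- list(demo = demo, drug = drug, reac = reac, ther = ther, outc = outc)
  # Referential integrity: child records must point at a DEMO report.
  ids <- demo$primaryid
  for (tab in c("drug", "reac", "ther", "outc")) {
    orphan <- !(tabs[[tab]]$primaryid %in% ids)
    if (any(orphan)) {
      warn(paste0(sum(orphan), " orphan record(s) dropped from ", toupper(tab)))
      tabs[[tab]] <- tabs[[tab]][!orphan, , drop = FALSE]
    }
  }
  structure(tabs, class = "faers_tables", raw = raw)
}

#' Write FAERS-format tables to disk
#'
#' Writes the raw (as-read or as-generated) dollar-delimited tables of a
#' `faers_tables` object to `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt` and
#' `OUTC.txt` under `dir`. Output is byte-deterministic for a given object.
#'
#' @param tables A `faers_tables` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_faers_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "faers_tables"))
  raw <- attr(tables, "raw")
  if (is.null(raw)) abort("faers_tables object carries no raw tables to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # keep only rows still present after any filtering (e.g. deduplication)
  for (tab in names(raw)) {
    keep_ids <- unique(tables[[tab]]$primaryid)
    rw <- raw[[tab]]
    rw <- rw[rw$PRIMARYID %in% keep_ids, , drop = FALSE]
    path <- file.path(dir, paste0(toupper(tab), ".txt"))
    readr::write_delim(rw, path, delim = "$", na = "")
  }
  invisible(dir)
}

#' Deduplicate FAERS cases
#'
#' FAERS distributes successive versions of the same safety report as separate
#' records sharing a case number. Exactly one record is retained per `caseid`:
#' the one with the latest FDA submission date, ties broken by highest
#' `caseversion`, then highest `primaryid` (compared as zero-padded strings).
#' Child tables are filtered to the retained reports.
#'
#' @param tables A `faers_tables` object.
#' @return A `faers_tables` object with unique `caseid`s and an attribute
#'   `dedup_audit`, a one-row tibble with columns `input`, `retained`,
#'   `removed`. Retrieve it with `dedup_audit()`.
#' @export
deduplicate_reports <- function(tables) {
  stopifnot(inherits(tables, "faers_tables"))
  demo <- tables$demo
  n_in <- nrow(demo)
  if (n_in == 0) {
    attr(tables, "dedup_audit") <- tibble(input = 0L, retained = 0L, removed = 0L)
    return(tables)
  }
  wid <- max(nchar(demo$primaryid))
  pid_pad <- stringr::str_pad(demo$primaryid, wid, pad = "0")
  date_key <- ifelse(is.na(demo$fda_date), -Inf, as.numeric(demo$fda_date))
  ord <- order(demo$caseid, date_key, demo$caseversion, pid_pad, method = "radix")
  demo_sorted <- demo[ord, , drop = FALSE]
  keep <- !duplicated(demo_sorted$caseid, fromLast = TRUE)
  demo_out <- demo_sorted[keep, , drop = FALSE]
  demo_out <- demo_out[order(stringr::str_pad(demo_out$primaryid, wid, pad = "0")), , drop = FALSE]
  ids <- demo_out$primaryid
  out <- tables
  out$demo <- demo_out
  for (tab in c("drug", "reac", "ther", "outc")) {
    out[[tab]] <- tables[[tab]][tables[[tab]]$primaryid %in% ids, , drop = FALSE]
  }
  attr(out, "dedup_audit") <- tibble(input = n_in, retained = nrow(demo_out),
                                     removed = n_in - nrow(demo_out))
  out
}

#' @rdname deduplicate_reports
#' @export
dedup_audit <- function(tables) {
  attr(tables, "dedup_audit") %||%
    tibble(input = NA_integer_, retained = NA_integer_, removed = NA_integer_)
}

#' @export
print.faers_tables <- function(x, ...) {
  cat("<faers_tables>\n")
  for (tab in names(x)) cat(sprintf("  %s: %d records\n", toupper(tab), nrow(x[[tab]])))
  aud <- attr(x, "dedup_audit")
  if (!is.null(aud)) {
    cat(sprintf("  deduplicated: %d -> %d (%d removed)\n",
                aud$input, aud$retained, aud$removed))
  }
  invisible(x)
}
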