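role_levels <- c("PS", "SS", "C", "I")

#' Match reports against a drug-name query
#'
#' Scans the DRUG table for records whose `drugname` or `prod_ai` contains the
#' query (or any synonym) and returns, per report, whether it matched and the
#' strongest role code among matching records (PS > SS > C > I). Names are
#' uppercased and punctuation is stripped before comparison, so
#' `"tucatinib."` matches `"TUCATINIB"`.
#'
#' @param drug The `drug` tibble of a `faers_tables` object (columns
#'   `primaryid`, `role_cod`, `drugname`, `prod_ai`).
#' @param query Drug name to search for (the generic name, typically).
#' @param synonyms Optional character vector of additional names (brand
#'   names etc.), or a path to a file with one name per line.
#' @param mode `"substring"` (default) matches the query anywhere inside a
#'   normalised name; `"exact"` requires a whole-token match. Substring mode
#'   matches a superset of exact mode.
#' @return Tibble with one row per report that has any drug record:
#'   `primaryid`, `matched` (logical), `role` (strongest matching role, NA if
#'   unmatched).
#' @export
match_drug <- function(drug, query, synonyms = NULL, mode = c("substring", "exact")) {
  mode <- match.arg(mode)
  stopifnot(nzchar(query))
  if (is.character(synonyms) && length(synonyms) == 1 && file.exists(synonyms)) {
    synonyms <- readr::read_lines(synonyms)
  }
  queries <- unique(normalize_drug_name(c(query, synonyms)))
  queries <- queries[nzchar(queries)]
  nm <- normalize_drug_name(dplyr::coalesce(drug$drugname, ""))
  ai <- normalize_drug_name(dplyr::coalesce(drug$prod_ai, ""))
  hit <- rep(FALSE, nrow(drug))
  for (q in queries) {
    if (mode == "substring") {
      hit <- hit | grepl(q, nm, fixed = TRUE) | grepl(q, ai, fixed = TRUE)
    } else {
      qq <- paste0(" ", q, " ")
      hit <- hit | grepl(qq, paste0(" ", nm, " "), fixed = TRUE) |
        grepl(qq, paste0(" ", ai, " "), fixed = TRUE)
    }
  }
  role_rank <- match(drug$role_cod, role_levels)  # NA for unknown role codes
  drug |>
    mutate(.hit = hit, .rank = ifelse(hit, role_rank, NA_integer_)) |>
    summarise(matched = any(.data$.hit),
              role = if (all(is.na(.data$.rank))) NA_character_ else
                role_levels[min(.data$.rank, na.rm = TRUE)],
              .by = "primaryid")
}

#' Split deduplicated reports into exposed and background cohorts
#'
#' Marks as *exposed* every report that mentions the query drug with a matched
#' role in `roles` (default: primary suspect only); all other reports form the
#' background. Reports with no reaction records cannot enter a
#' report-level contingency analysis and are dropped with a warning.
#'
#' @param tables A deduplicated `faers_tables` object.
#' @param query,synonyms,mode Passed to [match_drug()].
#' @param roles Role codes that qualify a matched report as exposed.
#' @return A `faers_cohort` object: list with `reports` (the demo tibble plus
#'   `exposed` and `matched_role` columns), `events` (distinct report-PT
#'   pairs), `drug`, `ther`, `outc`, and an attribute `cohort_counts`.
#' @export
partition_cohort <- function(tables, query, synonyms = NULL, roles = "PS",
                             mode = c("substring", "exact")) {
  stopifnot(inherits(tables, "faers_tables"))
  mode <- match.arg(mode)
  roles <- toupper(roles)
  stopifnot(all(roles %in% role_levels))

  demo <- tables$demo
  with_events <- unique(tables$reac$primaryid[!is.na(tables$reac$pt_norm) &
                                                nzchar(tables$reac$pt_norm)])
  dropped <- sum(!(demo$primaryid %in% with_events))
  if (dropped > 0) {
    warn(paste0(dropped, " report(s) without any reaction record dropped from analysis"))
    demo <- demo[demo$primaryid %in% with_events, , drop = FALSE]
  }

  m <- match_drug(tables$drug, query, synonyms = synonyms, mode = mode)
  reports <- demo |>
    left_join(m, by = "primaryid") |>
    mutate(matched = dplyr::coalesce(.data$matched, FALSE),
           exposed = .data$matched & .data$role %in% roles,
           matched_role = ifelse(.data$matched, .data$role, NA_character_)) |>
    select(-"role")

  # one PT counted once per report: the counting unit is the report
  events <- tables$reac |>
    filter(.data$primaryid %in% reports$primaryid,
           !is.na(.data$pt_norm), nzchar(.data$pt_norm)) |>
    distinct(.data$primaryid, .data$pt_norm, .keep_all = TRUE)

  counts <- tibble(exposed = sum(reports$exposed),
                   background = sum(!reports$exposed),
                   dropped_no_event = dropped)
  if (counts$exposed == 0) warn("Exposed cohort is empty; downstream counts will have a = 0")

  structure(list(reports = reports, events = events,
                 drug = tables$drug[tables$drug$primaryid %in% reports$primaryid, ],
                 ther = tables$ther[tables$ther$primaryid %in% reports$primaryid, ],
                 outc = tables$outc[tables$outc$primaryid %in% reports$primaryid, ]),
            class = "faers_cohort",
            cohort_counts = counts,
            query = list(query = query, synonyms = synonyms,
                         roles = roles, mode = mode))
}

#' @rdname partition_cohort
#' @export
cohort_counts <- function(cohort) attr(cohort, "cohort_counts")

#' @export
print.faers_cohort <- function(x, ...) {
  cc <- cohort_counts(x)
  q <- attr(x, "query")
  cat(sprintf("<faers_cohort> query '%s' (roles %s, %s match)\n",
              q$query, paste(q$roles, collapse = "/"), q$mode))
  cat(sprintf("  exposed %d | background %d | report-PT pairs %d\n",
              cc$exposed, cc$background, nrow(x$events)))
  invisible(x)
}

#' Read a PT-to-SOC mapping table
#'
#' Reads a two-column tab-separated file with header `pt<TAB>soc` mapping each
#' MedDRA preferred term to its primary system organ class. A small toy
#' dictionary ships with the package
#' (`system.file("extdata", "meddra_toy.tsv", package = "signalmine")`);
#' licensed MedDRA users supply their own table.
#'
#' @param path Path to the mapping file.
#' @param version Optional dictionary version string recorded in outputs.
#' @return Tibble with columns `pt`, `soc`, `pt_norm`; attribute `version`.
#' @export
read_meddra_map <- function(path, version = NA_character_) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  names(tb) <- tolower(names(tb))
  require_columns(setNames(tb, toupper(names(tb))), c("PT", "SOC"), "PT-to-SOC map")
  tb <- tb |>
    mutate(pt = normalize_term(.data$pt, fold = FALSE),
           soc = normalize_term(.data$soc, fold = FALSE),
           pt_norm = normalize_term(.data$pt)) |>
    distinct(.data$pt_norm, .keep_all = TRUE)
  structure(tb, version = version)
}

#' Assign system organ classes to preferred terms
#'
#' Looks each PT up in the mapping after normalisation (trim, collapse
#' internal whitespace, case-fold); original casing is preserved in the
#' output. PTs absent from the map receive the sentinel SOC `"UNMAPPED"` and a
#' warning, so signal detection remains total over the observed vocabulary.
#'
#' @param x A character vector of PTs, or a `faers_cohort` (whose `events`
#'   gain an `soc` column).
#' @param map A mapping from [read_meddra_map()].
#' @return A tibble `(pt, soc)` for character input; an augmented
#'   `faers_cohort` otherwise.
#' @export
assign_soc <- function(x, map) {
  lookup <- setNames(map$soc, map$pt_norm)
  fill_soc <- function(pt) {
    soc <- unname(lookup[normalize_term(pt)])
    n_un <- sum(is.na(soc))
    if (n_un > 0) {
      warn(paste0(n_un, " PT record(s) not in the SOC map assigned to 'UNMAPPED'"))
      soc[is.na(soc)] <- "UNMAPPED"
    }
    soc
  }
  if (inherits(x, "faers_cohort")) {
    x$events$soc <- fill_soc(x$events$pt)
    attr(x, "meddra_version") <- attr(map, "version")
    x
  } else {
    tibble(pt = as.character(x), soc = fill_soc(x))
  }
}
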