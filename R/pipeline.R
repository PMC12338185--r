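#' Run the full signal-mining pipeline
#'
#' End-to-end orchestration: read FAERS tables (or accept them in memory),
#' deduplicate cases, partition into the target-drug primary-suspect cohort
#' and background, map PTs to SOCs, build PT- and SOC-level contingency
#' tables, compute the four disproportionality statistics with combined
#' signal flags, and produce the descriptive summaries (report year, sex,
#' age, reporter, country, outcomes, time to onset). With `out_dir` set, the
#' result tables are written as TSVs together with a JSON run manifest
#' holding the audit counts (reports read, after deduplication, exposed,
#' report-PT pairs) and the full configuration for provenance. Outputs are
#' deterministic: the same inputs and configuration yield identical files.
#'
#' @param input A directory of FAERS ASCII files or a `faers_tables` object.
#' @param drug Target drug name (generic).
#' @param synonyms Optional synonym vector or file (one name per line).
#' @param roles Qualifying role codes for the exposed cohort (default PS).
#' @param meddra Path to a PT-to-SOC map file, or a map from
#'   [read_meddra_map()]; `NULL` uses the packaged toy dictionary.
#' @param out_dir Optional output directory.
#' @param zero_cell,yates,priors,min_a Passed to [disproportionality()].
#' @param mode Drug-name match mode, `"substring"` or `"exact"`.
#' @return Invisibly, a `signalmine_run` list: `cohort`, `signals_pt`,
#'   `signals_soc`, `descriptives`, `tto`, `manifest`.
#' @export
run_signal_pipeline <- function(input, drug, synonyms = NULL, roles = "PS",
                                meddra = NULL, out_dir = NULL,
                                zero_cell = "haldane", yates = FALSE,
                                priors = bcpnn_priors(), min_a = 3,
                                mode = "substring") {
  tables <- if (inherits(input, "faers_tables")) input else read_faers_tables(input)
  n_read <- nrow(tables$demo)
  tables <- deduplicate_reports(tables)
  audit <- dedup_audit(tables)

  if (is.null(meddra)) {
    meddra <- system.file("extdata", "meddra_toy.tsv", package = "signalmine")
  }
  map <- if (is.character(meddra)) read_meddra_map(meddra) else meddra

  cohort <- partition_cohort(tables, drug, synonyms = synonyms, roles = roles,
                             mode = mode)
  cohort <- assign_soc(cohort, map)
  cc <- cohort_counts(cohort)

  ct_pt <- build_contingency(cohort, "pt")
  ct_soc <- build_contingency(cohort, "soc")
  sig_pt <- disproportionality(ct_pt, priors = priors, zero_cell = zero_cell,
                               yates = yates, min_a = min_a)
  sig_soc <- disproportionality(ct_soc, priors = priors, zero_cell = zero_cell,
                                yates = yates, min_a = min_a)

  fields <- c("report_year", "sex", "age_group", "reporter", "country", "outcomes")
  descr <- purrr::map(setNames(fields, fields),
                      ~ summarize_categorical(cohort, .x))
  tto <- time_to_onset(cohort)
  exposed_pairs <- cohort$events |>
    semi_join(cohort$reports |> filter(.data$exposed), by = "primaryid") |>
    nrow()

  manifest <- list(
    counts = list(reports_read = n_read,
                  after_dedup = audit$retained,
                  duplicates_removed = audit$removed,
                  exposed_reports = cc$exposed,
                  background_reports = cc$background,
                  dropped_no_event = cc$dropped_no_event,
                  exposed_report_pt_pairs = exposed_pairs,
                  pt_terms = nrow(ct_pt), soc_terms = nrow(ct_soc),
                  pt_combined_signals = sum(sig_pt$combined_signal),
                  soc_combined_signals = sum(sig_soc$combined_signal)),
    config = list(drug = drug, synonyms = synonyms, roles = roles,
                  mode = mode, zero_cell = zero_cell, yates = yates,
                  priors = unclass(priors), min_a = min_a,
                  meddra_version = attr(map, "version"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(tidy(sig_pt), file.path(out_dir, "signals_pt.tsv"))
    readr::write_tsv(tidy(sig_soc), file.path(out_dir, "signals_soc.tsv"))
    readr::write_tsv(as_tibble(ct_pt), file.path(out_dir, "contingency_pt.tsv"))
    readr::write_tsv(as_tibble(ct_soc), file.path(out_dir, "contingency_soc.tsv"))
    readr::write_tsv(dplyr::bind_rows(descr), file.path(out_dir, "descriptives.tsv"))
    readr::write_tsv(tto$records, file.path(out_dir, "onset_records.tsv"))
    readr::write_tsv(tto$summary, file.path(out_dir, "onset_summary.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(structure(list(cohort = cohort, signals_pt = sig_pt,
                           signals_soc = sig_soc, descriptives = descr,
                           tto = tto, manifest = manifest),
                      class = "signalmine_run"))
}

#' @export
print.signalmine_run <- function(x, ...) {
  m <- x$manifest$counts
  cat("<signalmine_run>\n")
  cat(sprintf("  reports read %d; after dedup %d; exposed %d; background %d\n",
              m$reports_read, m$after_dedup, m$exposed_reports, m$background_reports))
  cat(sprintf("  exposed report-PT pairs %d; PT terms %d (combined signals %d); SOC terms %d (combined signals %d)\n",
              m$exposed_report_pt_pairs, m$pt_terms, m$pt_combined_signals,
              m$soc_terms, m$soc_combined_signals))
  invisible(x)
}
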