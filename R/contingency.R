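#' Build fourfold contingency tables for every term
#'
#' For each distinct term (PT, or SOC after [assign_soc()]) observed anywhere
#' in the corpus, counts the fourfold table at report level: `a` exposed
#' reports with the term, `b` exposed reports without it, `c`/`d` likewise in
#' the background. A report contributes at most 1 to a term even when several
#' of its reaction records map to it, so `a + b` equals the exposed cohort
#' size for every term and `c + d` the background size.
#'
#' Terms never reported in the exposed arm (`a = 0`) are excluded from the
#' returned table — every signal threshold requires at least 3 exposed
#' reports — but kept in the `all_terms` attribute for audit.
#'
#' @param cohort A `faers_cohort` from [partition_cohort()] (with SOCs
#'   assigned when `level = "soc"`).
#' @param level `"pt"` or `"soc"`.
#' @return Tibble with columns `term`, `level`, `soc` (PT level only), `a`,
#'   `b`, `c`, `d`, `n`, ordered by descending `a`.
#' @export
build_contingency <- function(cohort, level = c("pt", "soc")) {
  stopifnot(inherits(cohort, "faers_cohort"))
  level <- match.arg(level)
  reports <- cohort$reports
  n_exp <- sum(reports$exposed)
  n_bg <- sum(!reports$exposed)
  if (n_exp + n_bg == 0) abort("Cohort contains no reports")

  ev <- cohort$events
  if (level == "soc") {
    if (is.null(ev$soc)) abort("SOC-level tables require assign_soc() first")
    ev <- ev |> distinct(.data$primaryid, term = .data$soc)
  } else {
    # keep one display casing per normalised PT
    disp <- ev |> distinct(.data$pt_norm, .keep_all = TRUE) |>
      select("pt_norm", term = "pt", any_of("soc"))
    ev <- ev |> distinct(.data$primaryid, .data$pt_norm) |>
      left_join(disp, by = "pt_norm") |> select(-"pt_norm")
  }
  counts <- ev |>
    left_join(reports |> select("primaryid", "exposed"), by = "primaryid") |>
    summarise(a = sum(.data$exposed), c = sum(!.data$exposed),
              .by = setdiff(names(ev), "primaryid"))
  out <- counts |>
    mutate(level = level, b = n_exp - .data$a, d = n_bg - .data$c,
           n = n_exp + n_bg) |>
    select(any_of(c("term", "level", "soc")), "a", "b", "c", "d", "n") |>
    arrange(desc(.data$a), .data$term)
  structure(out[out$a > 0, , drop = FALSE], all_terms = out)
}
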