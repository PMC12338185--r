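age_breaks <- c(-Inf, 18, 45, 60, 75, 90, Inf)
age_labels <- c("<18", "18-44", "45-59", "60-74", "75-89", ">=90")

#' Categorical characteristic summary
#'
#' Counts and percentages for one characteristic of the exposed cohort,
#' mirroring the descriptive tables of spontaneous-report studies. Age is
#' stratified into <18, 18-44, 45-59, 60-74, 75-89 and >=90 years; country is
#' summarised as US vs other; outcomes are counted per outcome record (a
#' report may contribute several), with the outcome-record total as
#' denominator. All other fields count reports, with an explicit "unknown"
#' category, and percentages use either the sum of displayed categories
#' (default) or a supplied report total.
#'
#' @param cohort A `faers_cohort`; summaries describe its exposed reports.
#'   Alternatively a plain reports tibble for the demographic fields.
#' @param field One of `"report_year"`, `"sex"`, `"age_group"`, `"reporter"`,
#'   `"country"`, `"outcomes"`.
#' @param denominator_rule `"sum-of-categories"` (default) or `"all-reports"`.
#' @return Tibble: `characteristic`, `category`, `count`, `percent`, with the
#'   denominator as attribute.
#' @export
summarize_categorical <- function(cohort,
                                  field = c("report_year", "sex", "age_group",
                                            "reporter", "country", "outcomes"),
                                  denominator_rule = c("sum-of-categories", "all-reports")) {
  field <- match.arg(field)
  denominator_rule <- match.arg(denominator_rule)
  if (inherits(cohort, "faers_cohort")) {
    reports <- cohort$reports |> filter(.data$exposed)
    outc <- cohort$outc |> filter(.data$primaryid %in% reports$primaryid)
  } else {
    reports <- as_tibble(cohort)
    outc <- attr(cohort, "outc")
    if (field == "outcomes" && is.null(outc)) abort("outcomes need a faers_cohort")
  }

  values <- switch(field,
    report_year = ifelse(is.na(reports$fda_year), "unknown",
                         as.character(reports$fda_year)),
    sex = reports$sex,
    age_group = {
      g <- cut(reports$age_years, breaks = age_breaks, labels = age_labels,
               right = FALSE)
      ifelse(is.na(g), "unknown", as.character(g))
    },
    reporter = reports$reporter,
    country = ifelse(is.na(reports$country), "unknown",
                     ifelse(toupper(reports$country) == "US", "United States", "Other")),
    outcomes = outc$outcome[!is.na(outc$outcome)]
  )
  tab <- tibble(category = values) |> count(.data$category, name = "count")
  # fixed display order: frequency-descending with unknown last
  tab <- tab |>
    arrange(.data$category == "unknown", desc(.data$count), .data$category)
  denom <- if (denominator_rule == "all-reports" && field != "outcomes") {
    nrow(reports)
  } else {
    sum(tab$count)
  }
  out <- tab |>
    mutate(characteristic = field,
           percent = categorical_percent(.data$count, max(denom, 1L))) |>
    select("characteristic", "category", "count", "percent")
  structure(out, denominator = denom, denominator_rule = denominator_rule)
}

#' Median and quartiles
#'
#' Median with 1st and 3rd quartiles by the linear-interpolation convention
#' (R's default quantile type 7).
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @return One-row tibble `median`, `q1`, `q3`, `n`; all-`NA` input yields an
#'   absent (NA) result.
#' @export
#' @examples
#' median_iqr(c(1, 2, 3, 4))
median_iqr <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) == 0) return(tibble(median = NA_real_, q1 = NA_real_,
                                    q3 = NA_real_, n = 0L))
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  tibble(median = q[2], q1 = q[1], q3 = q[3], n = length(x))
}

tto_bucket_labels <- c("<7", "7-28", "28-60", ">=60", "unknown")

#' Time from therapy start to adverse-event onset
#'
#' For each exposed report, the onset time is the calendar-day difference
#' between the report's event date (DEMO) and the therapy start date of the
#' matched target-drug record (linked through `DSG_DRUG_SEQ`; earliest start
#' if several). Both dates must be full-resolution; partial dates yield an
#' unknown onset rather than a fabricated day. Negative differences (start
#' after event) are excluded with a warning. Onsets are bucketed into the
#' half-open intervals [0,7), [7,28), [28,60), [60,Inf) days, so "within the
#' first month" is the union of the first two buckets.
#'
#' @param cohort A `faers_cohort` from [partition_cohort()].
#' @return A `tto_result` list: `records` (primaryid, onset_days, bucket),
#'   `summary` (bucket counts and percentages over all onset records
#'   including unknown), and `stats` ([median_iqr()] of the known onsets).
#' @export
time_to_onset <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cohort"))
  q <- attr(cohort, "query")
  reports <- cohort$reports |> filter(.data$exposed)
  m <- match_drug(cohort$drug |> filter(.data$primaryid %in% reports$primaryid),
                  q$query, synonyms = q$synonyms, mode = q$mode)
  # therapy start of the matched target-drug record(s)
  drug_hits <- cohort$drug |>
    filter(.data$primaryid %in% reports$primaryid) |>
    semi_join(m |> filter(.data$matched), by = "primaryid")
  nm_hit <- {
    queries <- unique(normalize_drug_name(c(q$query, q$synonyms)))
    queries <- queries[nzchar(queries)]
    nm <- normalize_drug_name(dplyr::coalesce(drug_hits$drugname, ""))
    ai <- normalize_drug_name(dplyr::coalesce(drug_hits$prod_ai, ""))
    Reduce(`|`, lapply(queries, function(qq)
      grepl(qq, nm, fixed = TRUE) | grepl(qq, ai, fixed = TRUE)))
  }
  dated <- drug_hits[nm_hit, , drop = FALSE] |>
    inner_join(cohort$ther, by = c("primaryid", "drug_seq" = "dsg_drug_seq")) |>
    filter(!is.na(.data$start_date))
  starts <- if (nrow(dated) == 0) {
    tibble(primaryid = character(0), start_date = as.Date(character(0)))
  } else {
    dated |> summarise(start_date = min(.data$start_date), .by = "primaryid")
  }

  rec <- reports |>
    select("primaryid", "event_date") |>
    left_join(starts, by = "primaryid") |>
    mutate(onset_days = as.integer(.data$event_date - .data$start_date))
  neg <- !is.na(rec$onset_days) & rec$onset_days < 0
  if (any(neg)) {
    warn(paste0(sum(neg), " report(s) with therapy start after the event date excluded"))
    rec <- rec[!neg, , drop = FALSE]
  }
  rec <- rec |>
    mutate(bucket = ifelse(is.na(.data$onset_days), "unknown",
                           as.character(cut(.data$onset_days,
                                            breaks = c(0, 7, 28, 60, Inf),
                                            labels = tto_bucket_labels[1:4],
                                            right = FALSE)))) |>
    select("primaryid", "onset_days", "bucket")
  summary <- tibble(bucket = factor(rec$bucket, levels = tto_bucket_labels)) |>
    count(.data$bucket, name = "count", .drop = FALSE) |>
    mutate(bucket = as.character(.data$bucket),
           percent = categorical_percent(.data$count, max(nrow(rec), 1L)))
  structure(list(records = rec, summary = summary,
                 stats = median_iqr(rec$onset_days)),
            class = "tto_result")
}

#' @export
print.tto_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<tto_result> %d onset records (%d with known onset)\n",
              nrow(x$records), s$n))
  if (s$n > 0) cat(sprintf("  median %.2f days (IQR %.2f-%.2f)\n", s$median, s$q1, s$q3))
  print(x$summary)
  invisible(x)
}

#' Bar chart of time-to-onset interval buckets
#'
#' @param x A `tto_result` from [time_to_onset()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_time_to_onset <- function(x, ...) {
  stopifnot(inherits(x, "tto_result"))
  df <- x$summary |> mutate(bucket = factor(.data$bucket, levels = tto_bucket_labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bucket, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%%", .data$percent)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = "Days from therapy start to event", y = "Reports") +
    ggplot2::theme_minimal()
}
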