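test_that("median and quartiles use linear interpolation", {
  expect_equal(median_iqr(30), tibble::tibble(median = 30, q1 = 30, q3 = 30, n = 1L))
  m <- median_iqr(c(1, 2, 3, 4))
  expect_equal(unlist(m[c("median", "q1", "q3")], use.names = FALSE),
               c(2.5, 1.75, 3.25))
  expect_equal(median_iqr(numeric(0))$n, 0L)
  expect_true(is.na(median_iqr(NA_real_)$median))
})

test_that("median_iqr matches a sort-based interpolation oracle", {
  withr::with_seed(303, {
    for (i in 1:1000) {
      x <- switch(sample(3, 1),
                  rnorm(sample(2:40, 1)),
                  rpois(sample(2:40, 1), 20),
                  rlnorm(sample(2:40, 1)))
      m <- median_iqr(x)
      expect_equal(m$median, oracle_quartiles(x, 0.5))
      expect_equal(m$q1, oracle_quartiles(x, 0.25))
      expect_equal(m$q3, oracle_quartiles(x, 0.75))
    }
  })
})

test_that("categorical summaries compute percentages over the right denominators", {
  demo <- c(
    sprintf("%d$C%d$1$20230301$F$57$YR$US$MD$20230115", 1:6, 1:6),
    "7$C7$1$20230301$M$17$YR$JP$CN$20230115",
    "8$C8$1$20240301$$$$$$"
  )
  drug <- sprintf("%d$1$PS$TUCATINIB$TUCATINIB", 1:8)
  reac <- sprintf("%d$Fatigue", 1:8)
  outc <- c("1$HO", "1$DE", "2$OT", "3$RI")       # report 1 contributes twice
  tabs <- read_faers_tables(write_faers_fixture(demo, drug, reac, outc = outc))
  coh <- partition_cohort(tabs, "tucatinib")

  sx <- summarize_categorical(coh, "sex")
  expect_equal(attr(sx, "denominator"), 8)
  expect_equal(sx$count[sx$category == "female"], 6L)
  expect_equal(sx$percent[sx$category == "female"], 75)
  expect_equal(sum(sx$count), attr(sx, "denominator"))

  yr <- summarize_categorical(coh, "report_year")
  expect_equal(yr$count[yr$category == "2024"], 1L)

  ag <- summarize_categorical(coh, "age_group")
  expect_equal(ag$count[ag$category == "45-59"], 6L)
  expect_equal(ag$count[ag$category == "<18"], 1L)
  expect_equal(ag$count[ag$category == "unknown"], 1L)

  co <- summarize_categorical(coh, "country")
  expect_equal(co$count[co$category == "United States"], 6L)

  # outcomes count records, not reports: denominator 4, RI folds into other serious
  oc <- summarize_categorical(coh, "outcomes")
  expect_equal(attr(oc, "denominator"), 4)
  expect_equal(oc$count[oc$category == "other serious"], 2L)
  expect_equal(oc$percent[oc$category == "hospitalization"], 25)

  single <- summarize_categorical(coh$reports[1, ], "sex")
  expect_equal(single$percent, 100)
})

test_that("age strata use the fixed bucket boundaries", {
  ages <- c(17.9, 18, 44.9, 45, 59.9, 60, 74.9, 75, 89.9, 90)
  g <- cut(ages, breaks = c(-Inf, 18, 45, 60, 75, 90, Inf),
           labels = c("<18", "18-44", "45-59", "60-74", "75-89", ">=90"),
           right = FALSE)
  reports <- tibble::tibble(age_years = ages)
  out <- summarize_categorical(reports, "age_group")
  expect_equal(sum(out$count), length(ages))
  for (lab in levels(g)) {
    cnt <- out$count[out$category == lab]
    expect_equal(if (length(cnt)) cnt else 0L, sum(g == lab), info = lab)
  }
})

test_that("time to onset uses therapy-start linkage, half-open buckets and exclusions", {
  demo <- c(
    "1$C1$1$20230301$F$57$YR$US$MD$20230131",   # 30 days -> "28-60"
    "2$C2$1$20230301$F$57$YR$US$MD$20230107",   # 6 days  -> "<7"
    "3$C3$1$20230301$F$57$YR$US$MD$20230108",   # 7 days  -> "7-28"
    "4$C4$1$20230301$F$57$YR$US$MD$202303",     # partial event date -> unknown
    "5$C5$1$20230301$F$57$YR$US$MD$20230101",   # start after event -> excluded
    "6$C6$1$20230301$F$57$YR$US$MD$20230301"    # start on the target drug seq only
  )
  drug <- c(sprintf("%d$1$PS$TUCATINIB$TUCATINIB", 1:6),
            "6$2$C$METFORMIN$METFORMIN")
  reac <- sprintf("%d$Fatigue", 1:6)
  ther <- c("1$1$20230101", "2$1$20230101", "3$1$20230101", "4$1$20230101",
            "5$1$20230201",
            "6$2$20230225")                      # co-medication start: not used
  tabs <- read_faers_tables(write_faers_fixture(demo, drug, reac, ther))
  coh <- partition_cohort(tabs, "tucatinib")
  expect_warning(tto <- time_to_onset(coh), "start after the event")

  rec <- tto$records
  expect_equal(rec$onset_days[rec$primaryid == "1"], 30L)
  expect_equal(rec$bucket[rec$primaryid == "1"], "28-60")
  expect_equal(rec$bucket[rec$primaryid == "2"], "<7")
  expect_equal(rec$bucket[rec$primaryid == "3"], "7-28")
  expect_equal(rec$bucket[rec$primaryid == "4"], "unknown")
  expect_false("5" %in% rec$primaryid)
  expect_equal(rec$bucket[rec$primaryid == "6"], "unknown")  # no matched-drug start

  # buckets partition the onset records and percentages sum to ~100
  expect_equal(sum(tto$summary$count), nrow(rec))
  expect_equal(sum(tto$summary$percent), 100, tolerance = 0.05)
  expect_s3_class(plot_time_to_onset(tto), "ggplot")
})

test_that("onset medians recover the generator's log-normal target", {
  sim <- generate_faers(faers_config(seed = 31, n_exposed = 1500, n_background = 100,
                                     missingness = list(age = 0, sex = 0, event_date = 0,
                                                        event_date_partial = 0,
                                                        therapy_start = 0, country = 0)))
  coh <- partition_cohort(deduplicate_reports(sim$tables), "tucatinib", synonyms = "TUKYSA")
  tto <- time_to_onset(coh)
  # log-normal with median 30: sample median within a few days at n ~ 1500
  expect_gt(tto$stats$median, 22)
  expect_lt(tto$stats$median, 40)
})
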