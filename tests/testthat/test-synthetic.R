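test_that("identical seed and config produce byte-identical corpora", {
  cfg <- faers_config(seed = 41, n_exposed = 120, n_background = 600)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_faers(cfg, dir = d1)
  generate_faers(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the corpus
  d3 <- withr::local_tempdir()
  generate_faers(faers_config(seed = 42, n_exposed = 120, n_background = 600), dir = d3)
  expect_false(identical(readLines(file.path(d1, "DEMO.txt")),
                         readLines(file.path(d3, "DEMO.txt"))))
})

test_that("generated corpora round-trip losslessly through the reader", {
  cfg <- faers_config(seed = 43, n_exposed = 150, n_background = 700)
  dir <- withr::local_tempdir()
  sim <- generate_faers(cfg, dir = dir)
  back <- read_faers_tables(dir)
  for (tab in c("demo", "drug", "reac", "ther", "outc")) {
    expect_equal(nrow(back[[tab]]), nrow(sim$tables[[tab]]), info = tab)
  }
  ord <- function(tb) tb[order(tb$primaryid), , drop = FALSE]
  expect_equal(as.data.frame(ord(back$demo)), as.data.frame(ord(sim$tables$demo)))
  expect_equal(as.data.frame(ord(back$reac)), as.data.frame(ord(sim$tables$reac)))
})

test_that("deduplication removes exactly the ledger's stale duplicates", {
  sim <- generate_faers(faers_config(seed = 44, n_exposed = 200, n_background = 1000,
                                     duplicate_rate = 0.1))
  led <- sim$ledger
  dd <- deduplicate_reports(sim$tables)
  aud <- dedup_audit(dd)
  expect_equal(aud$removed, led$totals$n_duplicates)
  expect_equal(aud$retained, led$totals$n_retained)
  removed_ids <- setdiff(sim$tables$demo$primaryid, dd$demo$primaryid)
  expect_setequal(removed_ids, led$duplicates$stale_primaryid)
  expect_true(all(led$duplicates$retained_primaryid %in% dd$demo$primaryid))
})

test_that("every report carries at least one event and exposed reports the PS drug", {
  sim <- generate_faers(faers_config(seed = 45, n_exposed = 100, n_background = 400))
  tabs <- sim$tables
  expect_true(all(tabs$demo$primaryid %in% tabs$reac$primaryid))
  m <- match_drug(tabs$drug, "tucatinib", synonyms = "TUKYSA")
  dd <- deduplicate_reports(tabs)
  exp_ids <- m$primaryid[m$matched & m$role == "PS"]
  expect_equal(sum(dd$demo$primaryid %in% exp_ids), 100L)
})

test_that("exposed-arm incidence converges to the planted rate", {
  # rate-ratio planting: exposed rate is literally min(1, rho * rate)
  cfg <- faers_config(seed = 46, n_exposed = 50000, n_background = 2000,
                      duplicate_rate = 0, rho_scale = "rate_ratio")
  sim <- generate_faers(cfg)
  led <- sim$ledger$terms
  exp_ids <- sim$tables$demo$primaryid[seq_len(50000)]
  ev <- sim$tables$reac[sim$tables$reac$primaryid %in% exp_ids, ]
  for (pt in c("Diarrhoea", "Nausea", "Fatigue")) {
    row <- led[led$pt == pt, ]
    target <- min(1, row$rho * row$rate)
    expect_equal(row$p_exposed, target)
    phat <- length(unique(ev$primaryid[ev$pt == pt])) / 50000
    se <- sqrt(target * (1 - target) / 50000)
    expect_lt(abs(phat - target), 3 * se + 1e-9, label = pt)
  }
  # default planting: the relative-reporting-ratio rate, equal to the
  # background rate when rho = 1
  cfg2 <- faers_config(seed = 47, n_exposed = 2000, n_background = 20000)
  led2 <- generate_faers(cfg2)$ledger$terms
  expect_equal(led2$p_exposed[led2$pt == "Fatigue"], led2$rate[led2$pt == "Fatigue"])
  dia <- led2[led2$pt == "Diarrhoea", ]
  expect_equal(dia$p_exposed,
               dia$rho * dia$rate * 20000 / (22000 - dia$rho * 2000))
})

test_that("infeasible planted rates are clipped with a warning", {
  cfg <- faers_config(seed = 48, n_exposed = 200, n_background = 1000,
                      planted_signals = tibble::tibble(pt = "Fatigue", rho = 40),
                      rho_scale = "rate_ratio")
  expect_warning(sim <- generate_faers(cfg), "clipped")
  expect_equal(sim$ledger$terms$p_exposed[sim$ledger$terms$pt == "Fatigue"], 1)
})

test_that("reconstruction round-trips a self-generated table's printed statistics", {
  tab <- c(a = 40, b = 160, c = 800, d = 19000)
  s <- dispro_stats(tab["a"], tab["b"], tab["c"], tab["d"])
  rec <- reconstruct_row(a = unname(tab["a"]), ror = round(s$ror, 2),
                         prr = round(s$prr, 2), chi2 = round(s$chi2, 2))
  s2 <- dispro_stats(rec$a, rec$b, rec$c, rec$d)
  expect_equal(round(s2$ror, 2), round(s$ror, 2))
  expect_equal(round(s2$prr, 2), round(s$prr, 2))
  expect_equal(round(s2$chi2, 2), round(s$chi2, 2))
})

test_that("inconsistent printed statistics are reported as not reconstructible", {
  expect_error(reconstruct_row(a = 3, ror = 13.5, prr = 6, chi2 = 50),
               "not reconstructible")
  expect_error(reconstruct_row(a = 10, ror = 2, prr = 8, chi2 = 25),
               "not reconstructible")
})
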