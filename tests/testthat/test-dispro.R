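random_tables <- function(n, seed, max_cell = 500) {
  withr::with_seed(seed, {
    tibble::tibble(term = paste0("t", seq_len(n)),
                   a = sample(max_cell, n, TRUE), b = sample(max_cell, n, TRUE),
                   c = sample(max_cell, n, TRUE), d = sample(max_cell, n, TRUE))
  })
}

test_that("hand-checked fourfold table reproduces all four statistics", {
  r <- dispro_stats(3, 2, 10, 90)
  expect_equal(r$ror, 13.5)
  expect_equal(r$se_ln_ror, sqrt(1 / 3 + 1 / 2 + 1 / 10 + 1 / 90))
  expect_equal(round(r$ror_l, 2), 2.01)
  expect_equal(round(r$ror_u, 1), 90.7)
  expect_equal(r$prr, 6)
  expect_equal(round(r$chi2, 2), 10.97)
  expect_equal(r$ic_raw, log2(315 / 65))
  expect_equal(round(r$ic_raw, 3), 2.277)
  expect_equal(r$ebgm, 315 / 65)
  expect_equal(round(r$ebgm05, 2), 0.72)
  # ROR signals but EBGM05 < 1, so the combined criterion fails
  expect_true(r$ror_signal)
  expect_false(r$ebgm_signal)
  expect_false(r$combined_signal)
})

test_that("the count gate blocks signals with fewer than 3 exposed reports", {
  r <- dispro_stats(2, 1, 5, 5000)
  expect_gt(r$ror, 100)
  expect_false(r$ror_signal)
  expect_false(r$combined_signal)
})

test_that("proportional tables are exactly null for every statistic", {
  r <- dispro_stats(25, 25, 25, 25)
  expect_equal(r$ror, 1)
  expect_equal(r$prr, 1)
  expect_equal(r$ebgm, 1)
  expect_equal(r$ic_raw, 0)
  expect_equal(r$chi2, 0)
  # scaled proportional rows (a/b == c/d) stay null
  withr::with_seed(5, {
    for (i in 1:25) {
      a <- sample(200, 1); b <- sample(200, 1); k <- sample(20, 1)
      r <- dispro_stats(a, b, k * a, k * b)
      expect_equal(r$ror, 1)
      expect_equal(r$prr, 1)
      expect_equal(r$ebgm, 1)
      expect_equal(r$ic_raw, 0)
      expect_equal(r$chi2, 0)
    }
  })
})

test_that("symmetric BCPNN table gives gamma 4 and E(IC) exactly zero", {
  b <- bcpnn_stats(25, 25, 25, 25)
  expect_identical(b$gamma, 4)
  expect_identical(b$ic_expect, 0)
  expect_lte(b$ic025, b$ic_expect)
})

test_that("EBGM equals 2^IC and point estimates are monotone in a", {
  tabs <- random_tables(300, seed = 101)
  res <- disproportionality(tabs)
  expect_equal(res$ebgm, 2^res$ic_raw, tolerance = 1e-12)
  base <- dispro_stats(5, 50, 40, 900)
  for (a in c(6, 10, 20, 50)) {
    nxt <- dispro_stats(a, 50, 40, 900)
    expect_gte(nxt$ror, base$ror)
    expect_gte(nxt$prr, base$prr)
    expect_gte(nxt$ebgm, base$ebgm)
    expect_gte(nxt$ic_raw, base$ic_raw)
    base <- nxt
  }
})

test_that("statistics match the independent transcription oracle on random tables", {
  tabs <- random_tables(200, seed = 77)
  res <- disproportionality(tabs)
  res <- res[match(tabs$term, res$term), ]          # undo reporting order
  for (i in seq_len(nrow(tabs))) {
    o <- oracle_stats(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_equal(res$ror[i], o$ror, tolerance = 1e-10)
    expect_equal(res$ror_l[i], o$ror_l, tolerance = 1e-10)
    expect_equal(res$prr[i], o$prr, tolerance = 1e-10)
    expect_equal(res$chi2[i], o$chi2, tolerance = 1e-10)
    expect_equal(res$ic_raw[i], o$ic, tolerance = 1e-10)
    expect_equal(res$ic_expect[i], o$eic, tolerance = 1e-10)
    expect_equal(res$ic025[i], o$ic025, tolerance = 1e-10)
    expect_equal(res$ebgm[i], o$ebgm, tolerance = 1e-10)
    expect_equal(res$ebgm05[i], o$ebgm05, tolerance = 1e-10)
    # interval ordering invariants
    expect_lte(res$ror_l[i], res$ror[i]); expect_lte(res$ror[i], res$ror_u[i])
    expect_lte(res$prr_l[i], res$prr[i]); expect_lte(res$prr[i], res$prr_u[i])
    expect_lte(res$ebgm05[i], res$ebgm[i])
    expect_lte(res$ic025[i], res$ic_expect[i])
  }
})

test_that("zero cells follow the configured policy", {
  # c = 0: haldane adds 0.5 to every cell and flags the row
  h <- dispro_stats(4, 10, 0, 100)
  expect_true(h$corrected)
  expect_true(is.finite(h$ror))
  expect_equal(h$ror, (4.5 * 100.5) / (10.5 * 0.5))
  s <- dispro_stats(4, 10, 0, 100, zero_cell = "strict")
  expect_false(s$corrected)
  expect_true(is.infinite(s$ror))
  # chi-square stays on raw counts under either policy
  expect_equal(h$chi2, s$chi2)
  # a = 0: raw IC is -Inf, Bayesian moments finite
  z <- bcpnn_stats(0, 20, 30, 500)
  expect_identical(z$ic_raw, -Inf)
  expect_true(is.finite(z$ic_expect))
  expect_true(is.finite(z$ic025))
})

test_that("Yates continuity correction shrinks chi-square", {
  plain <- dispro_stats(12, 40, 30, 400)
  yates <- dispro_stats(12, 40, 30, 400, yates = TRUE)
  expect_lt(yates$chi2, plain$chi2)
  expect_equal(yates$chi2,
               unname(suppressWarnings(stats::chisq.test(
                 matrix(c(12, 40, 30, 400), 2, byrow = TRUE))$statistic)))
})

test_that("results order for reporting: SOC by count, PTs by ROR within SOC block", {
  ct <- tibble::tibble(
    term = c("P1", "P2", "P3"), level = "pt",
    soc = c("S_big", "S_big", "S_small"),
    a = c(5, 40, 30), b = c(95, 60, 70), c = c(50, 100, 300), d = c(950, 900, 700)
  )
  res <- disproportionality(ct)
  expect_equal(res$term, c("P2", "P1", "P3"))   # S_big block (a: 45) before S_small (30)
  soc_ct <- tibble::tibble(term = c("S1", "S2"), level = "soc",
                           a = c(10, 90), b = c(90, 10), c = c(100, 100), d = c(900, 900))
  expect_equal(disproportionality(soc_ct)$term, c("S2", "S1"))
})

test_that("tidy, glance and autoplot expose the results", {
  res <- disproportionality(tibble::tibble(term = c("X", "Y"), a = c(30, 3),
                                           b = c(70, 97), c = c(100, 100),
                                           d = c(900, 900)))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("term", "ror", "ebgm05", "combined_signal") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_terms, 2L)
  expect_equal(gl$n_exposed, 100)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
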