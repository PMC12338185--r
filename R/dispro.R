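#' BCPNN prior hyperparameters
#'
#' Priors of the single-drug/single-event information-component posterior:
#' `alpha`/`beta` are the prior totals of the drug and event margins,
#' `alpha1`/`beta1` the prior counts, `gamma11` the prior joint count. The
#' joint prior total `gamma` is not fixed but recomputed per table as
#' `gamma11 * (N+alpha) * (N+beta) / ((a+b+alpha1) * (a+c+beta1))`, which
#' centres the posterior IC at 0 under independence. Defaults follow the
#' Bate et al. (1998) convention.
#'
#' @param alpha,beta Prior margin totals (default 2).
#' @param alpha1,beta1 Prior margin counts (default 1).
#' @param gamma11 Prior joint count (default 1).
#' @return A `bcpnn_priors` list.
#' @export
bcpnn_priors <- function(alpha = 2, beta = 2, alpha1 = 1, beta1 = 1, gamma11 = 1) {
  stopifnot(alpha > 0, beta > 0, alpha1 > 0, beta1 > 0, gamma11 > 0)
  structure(list(alpha = alpha, beta = beta, alpha1 = alpha1, beta1 = beta1,
                 gamma11 = gamma11), class = "bcpnn_priors")
}

# Haldane zero-cell handling: +0.5 on all four cells, only when the table is
# degenerate (any of b, c, d zero) and the term was actually reported with
# the drug (a >= 1). Applied to the ratio estimators and their Wald SEs;
# chi-square and the Bayesian IC are well defined on the raw counts.
haldane_cells <- function(a, b, c, d, zero_cell) {
  corrected <- a >= 1 & (b == 0 | c == 0 | d == 0)
  if (zero_cell == "strict") corrected <- rep(FALSE, length(a))
  k <- ifelse(corrected, 0.5, 0)
  list(a = a + k, b = b + k, c = c + k, d = d + k, corrected = corrected)
}

#' Reporting odds ratio
#'
#' `ROR = (a*d)/(b*c)` with Wald 95% CI on the log scale,
#' `SE(lnROR) = sqrt(1/a + 1/b + 1/c + 1/d)`.
#'
#' @param a,b,c,d Fourfold-table cell counts (vectorised).
#' @param zero_cell `"haldane"` adds 0.5 to all cells of degenerate tables
#'   (any of `b`, `c`, `d` zero with `a >= 1`); `"strict"` leaves such tables
#'   undefined (`NaN`/`Inf`).
#' @return Tibble: `ror`, `se_ln_ror`, `ror_l`, `ror_u`, `corrected`.
#' @export
ror_stats <- function(a, b, c, d, zero_cell = c("haldane", "strict")) {
  zero_cell <- match.arg(zero_cell)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  h <- haldane_cells(a, b, c, d, zero_cell)
  ror <- (h$a * h$d) / (h$b * h$c)
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  tibble(ror = ror, se_ln_ror = se,
         ror_l = exp(log(ror) - 1.96 * se), ror_u = exp(log(ror) + 1.96 * se),
         corrected = h$corrected)
}

#' Proportional reporting ratio and Pearson chi-square
#'
#' `PRR = (a/(a+b)) / (c/(c+d))` with
#' `SE(lnPRR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))` and the Pearson statistic
#' `chi2 = N*(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, optionally with the Yates
#' continuity correction.
#'
#' @inheritParams ror_stats
#' @param yates Apply the Yates continuity correction to chi-square.
#' @return Tibble: `prr`, `se_ln_prr`, `prr_l`, `prr_u`, `chi2`, `corrected`.
#' @export
prr_stats <- function(a, b, c, d, zero_cell = c("haldane", "strict"), yates = FALSE) {
  zero_cell <- match.arg(zero_cell)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  h <- haldane_cells(a, b, c, d, zero_cell)
  prr <- (h$a / (h$a + h$b)) / (h$c / (h$c + h$d))
  se <- sqrt(1 / h$a - 1 / (h$a + h$b) + 1 / h$c - 1 / (h$c + h$d))
  n <- a + b + c + d
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(dev - n / 2, 0)
  chi2 <- n * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  tibble(prr = prr, se_ln_prr = se,
         prr_l = exp(log(prr) - 1.96 * se), prr_u = exp(log(prr) + 1.96 * se),
         chi2 = chi2, corrected = h$corrected)
}

#' BCPNN information component
#'
#' The raw information component is
#' `IC = log2( a*N / ((a+b)*(a+c)) )`, the log2 ratio of the observed joint
#' reporting probability to the product of its margins. The posterior
#' expectation and variance under the single-drug/single-event BCPNN model
#' are
#' \deqn{E(IC) = \log_2 \frac{(a+\gamma_{11})(N+\alpha)(N+\beta)}
#'   {(N+\gamma)(a+b+\alpha_1)(a+c+\beta_1)}}
#' with `gamma` recomputed per table (see [bcpnn_priors()]) and
#' \deqn{V(IC) = \frac{1}{(\ln 2)^2}\left[
#'   \frac{N-a+\gamma-\gamma_{11}}{(a+\gamma_{11})(1+N+\gamma)} +
#'   \frac{N-(a+b)+\alpha-\alpha_1}{(a+b+\alpha_1)(1+N+\alpha)} +
#'   \frac{N-(a+c)+\beta-\beta_1}{(a+c+\beta_1)(1+N+\beta)} \right]}
#' The signal bound is `IC025 = E(IC) - 2*sqrt(V(IC))`. When `a = 0` the raw
#' IC is `-Inf`; the Bayesian quantities remain finite.
#'
#' @inheritParams ror_stats
#' @param priors A [bcpnn_priors()] object.
#' @return Tibble: `ic_raw`, `ic_expect`, `ic_var`, `ic025`, `gamma`.
#' @export
bcpnn_stats <- function(a, b, c, d, priors = bcpnn_priors()) {
  stopifnot(inherits(priors, "bcpnn_priors"))
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  ab <- a + b
  ac <- a + c
  ic_raw <- log2(a * n / (ab * ac))
  ic_raw[a == 0] <- -Inf
  g11 <- priors$gamma11; a1 <- priors$alpha1; b1 <- priors$beta1
  al <- priors$alpha; be <- priors$beta
  gamma <- g11 * (n + al) * (n + be) / ((ab + a1) * (ac + b1))
  ic_expect <- log2((a + g11) * (n + al) * (n + be) /
                      ((n + gamma) * (ab + a1) * (ac + b1)))
  ic_var <- ((n - a + gamma - g11) / ((a + g11) * (1 + n + gamma)) +
               (n - ab + al - a1) / ((ab + a1) * (1 + n + al)) +
               (n - ac + be - b1) / ((ac + b1) * (1 + n + be))) / log(2)^2
  tibble(ic_raw = ic_raw, ic_expect = ic_expect, ic_var = ic_var,
         ic025 = ic_expect - 2 * sqrt(ic_var), gamma = gamma)
}

#' Empirical Bayes geometric mean (relative reporting ratio form)
#'
#' `EBGM = a*N / ((a+b)*(a+c))`, the observed-to-expected relative reporting
#' ratio, with a Wald 95% interval on the log scale using
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`; the lower bound is EBGM05. This is the
#' simplified relative-reporting-ratio estimator (identical to `2^IC_raw`),
#' not the DuMouchel MGPS posterior mean.
#'
#' @inheritParams ror_stats
#' @return Tibble: `ebgm`, `se_ln_ebgm`, `ebgm05`, `ebgm_u`, `corrected`.
#' @export
ebgm_stats <- function(a, b, c, d, zero_cell = c("haldane", "strict")) {
  zero_cell <- match.arg(zero_cell)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  h <- haldane_cells(a, b, c, d, zero_cell)
  n <- h$a + h$b + h$c + h$d
  ebgm <- h$a * n / ((h$a + h$b) * (h$a + h$c))
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  tibble(ebgm = ebgm, se_ln_ebgm = se,
         ebgm05 = exp(log(ebgm) - 1.96 * se), ebgm_u = exp(log(ebgm) + 1.96 * se),
         corrected = h$corrected)
}

#' All four disproportionality statistics with signal flags
#'
#' Computes ROR, PRR + chi-square, the BCPNN information component and EBGM
#' for every row of a contingency table built by [build_contingency()] (or
#' any data frame with columns `a`, `b`, `c`, `d`), applies the per-algorithm
#' signal thresholds and the combined criterion, and orders the output for
#' reporting.
#'
#' Signal thresholds: ROR and PRR require `a >= 3` and a 95% CI lower limit
#' above 1; BCPNN requires `IC025 > 0`; EBGM requires `EBGM05 > 1`. The
#' combined signal requires all four.
#'
#' @param tables Data frame with columns `a`, `b`, `c`, `d` (and optionally
#'   `term`, `level`, `soc`).
#' @param priors A [bcpnn_priors()] object.
#' @param zero_cell,yates Passed to the per-statistic functions.
#' @param min_a Minimum exposed-report count in the ROR/PRR thresholds.
#' @return A `dispro_tbl` (tibble subclass) with all statistics, intervals,
#'   per-algorithm flags and `combined_signal`.
#' @export
#' @examples
#' disproportionality(data.frame(term = "X", a = 3, b = 2, c = 10, d = 90))
disproportionality <- function(tables, priors = bcpnn_priors(),
                               zero_cell = c("haldane", "strict"),
                               yates = FALSE, min_a = 3) {
  zero_cell <- match.arg(zero_cell)
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  tb <- as_tibble(tables)
  a <- tb$a; b <- tb$b; c <- tb$c; d <- tb$d
  stopifnot(all(a + b + c + d > 0), all(c(a, b, c, d) >= 0))
  res <- dplyr::bind_cols(
    tb,
    ror_stats(a, b, c, d, zero_cell),
    prr_stats(a, b, c, d, zero_cell, yates) |> select(-"corrected"),
    bcpnn_stats(a, b, c, d, priors),
    ebgm_stats(a, b, c, d, zero_cell) |> select(-"corrected")
  )
  if (!"n" %in% names(res)) res$n <- a + b + c + d
  res <- evaluate_signals(res, min_a = min_a)
  structure(res, class = c("dispro_tbl", class(tibble())),
            priors = priors, zero_cell = zero_cell, yates = yates, min_a = min_a)
}

#' Apply the combined signal criteria and reporting order
#'
#' Flags each term under the four algorithm thresholds and their conjunction,
#' then orders rows for reporting: SOC-level tables by descending exposed
#' count `a`; PT-level tables in SOC blocks (blocks by descending total
#' exposed count, terms within a block by descending ROR).
#'
#' @param results Data frame with the statistic columns produced by
#'   [disproportionality()] (at minimum `a`, `ror_l`, `prr_l`, `ic025`,
#'   `ebgm05`).
#' @param min_a Minimum exposed-report count for the ROR/PRR thresholds.
#' @return The input with logical columns `ror_signal`, `prr_signal`,
#'   `bcpnn_signal`, `ebgm_signal`, `combined_signal`, reordered.
#' @export
evaluate_signals <- function(results, min_a = 3) {
  res <- results |>
    mutate(ror_signal = .data$a >= min_a & is.finite(.data$ror_l) & .data$ror_l > 1,
           prr_signal = .data$a >= min_a & is.finite(.data$prr_l) & .data$prr_l > 1,
           bcpnn_signal = is.finite(.data$ic025) & .data$ic025 > 0,
           ebgm_signal = is.finite(.data$ebgm05) & .data$ebgm05 > 1) |>
    mutate(combined_signal = .data$ror_signal & .data$prr_signal &
             .data$bcpnn_signal & .data$ebgm_signal)
  lev <- if ("level" %in% names(res)) res$level[1] else NA_character_
  if (identical(lev, "soc")) {
    res <- res |> arrange(desc(.data$a), .data$term)
  } else if ("soc" %in% names(res)) {
    res <- res |>
      mutate(.soc_a = sum(.data$a), .by = "soc") |>
      arrange(desc(.data$.soc_a), .data$soc, desc(.data$ror), .data$term) |>
      select(-".soc_a")
  } else {
    res <- res |> arrange(desc(.data$ror))
  }
  res
}

#' Single-table disproportionality calculator
#'
#' Convenience wrapper computing all four statistics for one fourfold table.
#'
#' @param a,b,c,d Cell counts.
#' @param ... Passed to [disproportionality()].
#' @return A one-row `dispro_tbl`.
#' @export
#' @examples
#' dispro_stats(3, 2, 10, 90)
dispro_stats <- function(a, b, c, d, ...) {
  disproportionality(tibble(a = a, b = b, c = c, d = d), ...)
}

#' @export
#' @method tidy dispro_tbl
tidy.dispro_tbl <- function(x, ...) {
  as_tibble(x) |>
    select(any_of(c("term", "soc", "level", "a", "ror", "ror_l", "ror_u",
                    "prr", "prr_l", "prr_u", "chi2", "ic_raw", "ic025",
                    "ebgm", "ebgm05", "ror_signal", "prr_signal",
                    "bcpnn_signal", "ebgm_signal", "combined_signal")))
}

#' @export
#' @method glance dispro_tbl
glance.dispro_tbl <- function(x, ...) {
  tibble(n_terms = nrow(x),
         n_exposed = if (nrow(x)) x$a[1] + x$b[1] else 0L,
         n_background = if (nrow(x)) x$c[1] + x$d[1] else 0L,
         ror_signals = sum(x$ror_signal),
         prr_signals = sum(x$prr_signal),
         bcpnn_signals = sum(x$bcpnn_signal),
         ebgm_signals = sum(x$ebgm_signal),
         combined_signals = sum(x$combined_signal))
}

#' Forest plot of disproportionality results
#'
#' Plots each term's ROR and 95% CI on a log axis, coloured by the combined
#' four-algorithm signal flag.
#'
#' @param object A `dispro_tbl`.
#' @param max_terms Plot at most this many terms (by descending ROR).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot dispro_tbl
autoplot.dispro_tbl <- function(object, max_terms = 30, ...) {
  df <- as_tibble(object) |>
    filter(is.finite(.data$ror), is.finite(.data$ror_l), .data$ror_l > 0) |>
    arrange(desc(.data$ror)) |>
    head(max_terms)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror,
                                   y = stats::reorder(.data$term, .data$ror),
                                   colour = .data$combined_signal)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ror_l, xmax = .data$ror_u),
                            height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ROR (95% CI, log scale)", y = NULL,
                  colour = "Combined signal") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
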