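chi2_pearson <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

#' Reconstruct a fourfold table from a published signal-table row
#'
#' Given the exposed-with-event count `a` and the ROR, PRR and chi-square
#' printed at 2 decimals in a signal table, searches for integer cell counts
#' `(b, c, d)` whose recomputed statistics all round back to the printed
#' values, enabling closure checks of the remaining columns (EBGM, IC) that
#' the printed row implies.
#'
#' The printed triple does not pin the background size directly; the search
#' exploits the structure of the problem instead of brute force. For each
#' candidate `b` (the PRR/ROR windows bound `b/a` through
#' `PRR = (1 + ROR*b/a)/(1 + b/a)`), the background event rate `q = c/(c+d)`
#' follows from PRR, and the background size is the root of the chi-square
#' equation, which is monotone in the table's scale; when chi-square has no
#' finite root below the size cap, the rate is instead solved at the cap.
#' Because the integer lattice gets finer as `N` grows, the squared-log-error
#' minimiser the function returns favours the largest table size consistent
#' with `max_n` whenever the printed values admit one — matching how such
#' rows arise from very large spontaneous-report databases.
#'
#' @param a Printed exposed-with-event count.
#' @param ror,prr,chi2 Printed values (2 decimals).
#' @param max_n Cap on the reconstructed table total `a+b+c+d`.
#' @param b_max Cap on `b` (default `5*a`).
#' @return One-row tibble `a`, `b`, `c`, `d`, `n` plus the recomputed `ror`,
#'   `prr`, `chi2`, `ebgm`, `ic` and the squared-log-error `objective`.
#'   Errors with "not reconstructible" if no integer table in bounds rounds
#'   to the printed values.
#' @export
#' @examples
#' reconstruct_row(a = 3, ror = 13.5, prr = 6, chi2 = 10.97)
reconstruct_row <- function(a, ror, prr, chi2, max_n = 1e7, b_max = 5 * a) {
  stopifnot(a >= 1, ror > 0, prr > 0, chi2 >= 0)
  half <- 0.005
  r_lo <- ror - half; r_hi <- ror + half
  p_lo <- prr - half; p_hi <- prr + half

  # bound b/a from PRR = (1 + ROR*x)/(1 + x): x = (PRR-1)/(ROR-PRR)
  xs <- c()
  for (p in c(p_lo, p_hi)) for (r in c(r_lo, r_hi)) {
    den <- r - p
    if (abs(den) > 1e-12) {
      x <- (p - 1) / den
      if (is.finite(x) && x > 0) xs <- c(xs, x)
    }
  }
  sign_change <- (r_lo - p_hi) < 0 && (r_hi - p_lo) > 0
  if (length(xs) < 4 || sign_change) {
    b_range <- seq_len(b_max)                     # window unbounded: scan all b
  } else {
    b_range <- max(1, floor(a * min(xs))):min(b_max, ceiling(a * max(xs)))
  }

  best <- NULL
  check_candidate <- function(b, q, B) {
    if (!is.finite(q) || !is.finite(B) || q <= 0 || q >= 1 || B < 2) return(invisible())
    c0 <- round(q * B); d0 <- round((1 - q) * B)
    grid <- expand.grid(cc = c0 + (-8:8), dd = d0 + (-8:8))
    grid <- grid[grid$cc >= 1 & grid$dd >= 1 & a + b + grid$cc + grid$dd <= max_n, ]
    if (nrow(grid) == 0) return(invisible())
    cc <- grid$cc; dd <- grid$dd
    ror_v <- (a * dd) / (b * cc)
    prr_v <- (a / (a + b)) / (cc / (cc + dd))
    chi_v <- chi2_pearson(a, b, cc, dd)
    ok <- abs(round(ror_v, 2) - ror) < 1e-9 &
      abs(round(prr_v, 2) - prr) < 1e-9 &
      abs(round(chi_v, 2) - chi2) < 1e-9
    if (!any(ok)) return(invisible())
    obj <- log(ror_v / ror)^2 + log(prr_v / prr)^2 + log(chi_v / chi2)^2
    obj[!ok] <- Inf
    i <- which.min(obj)
    if (is.null(best) || obj[i] < best$objective) {
      best <<- tibble(a = a, b = b, c = cc[i], d = dd[i],
                      n = a + b + cc[i] + dd[i],
                      ror = ror_v[i], prr = prr_v[i], chi2 = chi_v[i],
                      objective = obj[i])
    }
    invisible()
  }

  for (b in b_range) {
    m <- a + b
    pe <- a / m
    B_hi <- max_n - m
    if (B_hi < 2) next

    # (i) q from the PRR midpoint, background size from the chi-square root
    q1 <- pe / prr
    if (q1 > 0 && q1 < 1 && abs(pe - q1) > 1e-12) {
      chi_inf <- m * (pe - q1)^2 / (q1 * (1 - q1))
      f <- function(B) chi2_pearson(a, b, q1 * B, (1 - q1) * B) - chi2
      if (chi_inf > chi2 && f(B_hi) >= 0) {
        root <- tryCatch(uniroot(f, lower = 1e-9, upper = B_hi, tol = 1e-7)$root,
                         error = function(e) NA_real_)
        check_candidate(b, q1, root)
      }
    }
    # (ii) background size at the cap, rate from the chi-square root
    g <- function(q) chi2_pearson(a, b, q * B_hi, (1 - q) * B_hi) - chi2
    if (prr >= 1) { q_lo <- 1e-12; q_hi <- pe - 1e-12 } else { q_lo <- pe + 1e-12; q_hi <- 1 - 1e-12 }
    if (q_hi > q_lo) {
      v_lo <- g(q_lo); v_hi <- g(q_hi)
      if (is.finite(v_lo) && is.finite(v_hi) && v_lo * v_hi < 0) {
        q2 <- tryCatch(uniroot(g, lower = q_lo, upper = q_hi, tol = 1e-14)$root,
                       error = function(e) NA_real_)
        if (is.finite(q2)) {
          prr_imp <- pe / q2
          ror_imp <- (a / b) * (1 - q2) / q2
          if (prr_imp >= p_lo - 1e-9 && prr_imp <= p_hi + 1e-9 &&
              ror_imp >= r_lo - 1e-9 && ror_imp <= r_hi + 1e-9) {
            check_candidate(b, q2, B_hi)
          }
        }
      }
    }
  }

  if (is.null(best)) {
    abort(sprintf(
      "not reconstructible: no integer table with b <= %d, N <= %g reproduces a=%g, ROR=%.2f, PRR=%.2f, chi2=%.2f",
      b_max, max_n, a, ror, prr, chi2))
  }
  best$ebgm <- best$a * best$n / ((best$a + best$b) * (best$a + best$c))
  best$ic <- log2(best$ebgm)
  best
}
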