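# Independent scalar transcription of the four statistics, written straight
# from the definitions with no shared code with the package. chi-square goes
# through stats::chisq.test as an external cross-check.
oracle_stats <- function(a, b, c, d,
                         alpha = 2, beta = 2, alpha1 = 1, beta1 = 1, gamma11 = 1) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  ror <- (a / c) / (b / d)
  se_ror <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  prr <- (a / (a + b)) / (c / (c + d))
  se_prr <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  chi2 <- unname(suppressWarnings(
    stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                      correct = FALSE)$statistic))
  pxy <- a / n; px <- (a + b) / n; py <- (a + c) / n
  ic <- log2(pxy / (px * py))
  gamma <- gamma11 * (n + alpha) * (n + beta) / ((a + b + alpha1) * (a + c + beta1))
  eic <- log2((a + gamma11) * (n + alpha) * (n + beta) /
                ((n + gamma) * (a + b + alpha1) * (a + c + beta1)))
  vic <- (1 / log(2)^2) *
    ((n - a + gamma - gamma11) / ((a + gamma11) * (1 + n + gamma)) +
       (n - (a + b) + alpha - alpha1) / ((a + b + alpha1) * (1 + n + alpha)) +
       (n - (a + c) + beta - beta1) / ((a + c + beta1) * (1 + n + beta)))
  ebgm <- a * n / ((a + c) * (a + b))
  list(ror = ror, ror_l = exp(log(ror) - 1.96 * se_ror),
       ror_u = exp(log(ror) + 1.96 * se_ror),
       prr = prr, prr_l = exp(log(prr) - 1.96 * se_prr),
       prr_u = exp(log(prr) + 1.96 * se_prr),
       chi2 = chi2, ic = ic, eic = eic, vic = vic,
       ic025 = eic - 2 * sqrt(vic),
       ebgm = ebgm, ebgm05 = exp(log(ebgm) - 1.96 * se_ror))
}

# sort-based quartile oracle: linear interpolation between order statistics
oracle_quartiles <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  val <- x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
  unname(val)
}

faers_headers <- c(
  demo = "PRIMARYID$CASEID$CASEVERSION$FDA_DT$SEX$AGE$AGE_COD$OCCR_COUNTRY$OCCP_COD$EVENT_DT",
  drug = "PRIMARYID$DRUG_SEQ$ROLE_COD$DRUGNAME$PROD_AI",
  reac = "PRIMARYID$PT",
  ther = "PRIMARYID$DSG_DRUG_SEQ$START_DT",
  outc = "PRIMARYID$OUTC_COD"
)

# write a hand-built FAERS fixture (vectors of $-delimited record lines)
write_faers_fixture <- function(demo, drug = character(), reac = character(),
                                ther = character(), outc = character(),
                                dir = withr::local_tempdir(.local_envir = parent.frame())) {
  recs <- list(demo = demo, drug = drug, reac = reac, ther = ther, outc = outc)
  for (tab in names(recs)) {
    writeLines(c(faers_headers[[tab]], recs[[tab]]),
               file.path(dir, paste0(toupper(tab), ".txt")))
  }
  dir
}

toy_map_path <- function() {
  system.file("extdata", "meddra_toy.tsv", package = "signalmine")
}

# a tiny deterministic cohort used across tests: 5 exposed reports (3 with
# event E) and 100 background reports (10 with E), everyone also reporting F
tiny_cohort <- function() {
  n_bg <- 100
  demo <- c(
    sprintf("E%02d$CE%02d$1$20230301$F$57$YR$US$MD$20230115", 1:5, 1:5),
    sprintf("B%03d$CB%03d$1$20230301$F$60$YR$US$MD$20230115", 1:n_bg, 1:n_bg)
  )
  drug <- c(
    sprintf("E%02d$1$PS$TUCATINIB$TUCATINIB", 1:5),
    sprintf("B%03d$1$PS$METFORMIN$METFORMIN", 1:n_bg)
  )
  reac <- c(
    sprintf("E%02d$Diarrhoea", 1:3),
    sprintf("E%02d$Fatigue", 1:5),
    sprintf("B%03d$Diarrhoea", 1:10),
    sprintf("B%03d$Fatigue", 1:n_bg)
  )
  dir <- write_faers_fixture(demo, drug, reac, dir = withr::local_tempdir(.local_envir = parent.frame()))
  tabs <- read_faers_tables(dir)
  partition_cohort(tabs, "tucatinib")
}
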