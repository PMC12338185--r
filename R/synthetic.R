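#' Default PT catalogue for synthetic corpora
#'
#' A small vocabulary of MedDRA-style preferred terms with primary SOCs and
#' per-report background reporting rates, loosely shaped like the event mix
#' seen around an oral oncology drug. `"Drug ineffective"` doubles as the
#' filler complaint guaranteeing every report carries at least one event.
#'
#' @return Tibble with columns `pt`, `soc`, `rate`.
#' @export
default_pt_catalog <- function() {
  tibble::tribble(
    ~pt, ~soc, ~rate,
    "Diarrhoea", "Gastrointestinal disorders", 0.02,
    "Nausea", "Gastrointestinal disorders", 0.03,
    "Vomiting", "Gastrointestinal disorders", 0.02,
    "Palmar-plantar erythrodysaesthesia syndrome", "Skin and subcutaneous tissue disorders", 0.01,
    "Rash", "Skin and subcutaneous tissue disorders", 0.02,
    "Hepatic enzyme increased", "Investigations", 0.015,
    "Fatigue", "General disorders and administration site conditions", 0.05,
    "Drug ineffective", "General disorders and administration site conditions", 0.05,
    "Pyrexia", "General disorders and administration site conditions", 0.03,
    "Headache", "Nervous system disorders", 0.03,
    "Dizziness", "Nervous system disorders", 0.02,
    "Anaemia", "Blood and lymphatic system disorders", 0.01,
    "Insomnia", "Psychiatric disorders", 0.015,
    "Arthralgia", "Musculoskeletal and connective tissue disorders", 0.02
  )
}

default_planted_signals <- function() {
  tibble::tribble(
    ~pt, ~rho,
    "Diarrhoea", 5,
    "Palmar-plantar erythrodysaesthesia syndrome", 5,
    "Nausea", 2,
    "Hepatic enzyme increased", 2,
    "Fatigue", 1,
    "Headache", 1
  )
}

#' Configuration for the synthetic FAERS generator
#'
#' Defines a synthetic spontaneous-report corpus: cohort sizes, the PT
#' catalogue with background rates, planted drug-event association strengths,
#' duplicate-case and missingness rates, demographic mixes and the
#' therapy-to-onset delay model. Identical seed and configuration yield a
#' byte-identical corpus.
#'
#' `planted_signals` gives each planted PT a relative reporting ratio
#' `rho`: with the default `rho_scale = "relative_reporting"`, rho is the
#' observed-to-expected ratio against the whole corpus (the estimand of
#' EBGM), achieved by an exposed-arm rate `rho*rate*n_bg/(N - rho*n_exposed)`
#' — which reduces to `rho*rate` when the exposed cohort is a small fraction
#' of the corpus. `rho_scale = "rate_ratio"` plants the literal
#' `min(1, rho*rate)`. Rates are clipped to [0, 1] with a warning.
#'
#' @param seed Integer RNG seed.
#' @param n_exposed,n_background Reports carrying the target drug as primary
#'   suspect, and background reports.
#' @param drug_name,brand_names Target generic name and brand synonyms
#'   sprinkled over the exposed reports' free-text drug names.
#' @param pt_catalog Tibble `pt`, `soc`, `rate` (per-report background rate).
#' @param planted_signals Tibble `pt`, `rho`; catalogue PTs not listed behave
#'   as `rho = 1`.
#' @param duplicate_rate Fraction of cases additionally emitted as a stale
#'   earlier version (same caseid, lower caseversion, earlier FDA date).
#' @param missingness Named list of absent-probabilities: `age`, `sex`,
#'   `event_date`, `event_date_partial` (emit `YYYYMM`), `therapy_start`,
#'   `country`.
#' @param sex_split,reporter_mix,outcome_mix,country_mix Categorical mixes.
#' @param age_mixture List `mean`, `sd` of the age distribution (years).
#' @param onset_model List `median_days`, `sdlog` of the log-normal
#'   therapy-start-to-event delay.
#' @param rho_scale `"relative_reporting"` or `"rate_ratio"` (see above).
#' @return A `faers_sim_config` list.
#' @export
faers_config <- function(seed = 1L,
                         n_exposed = 2000L, n_background = 20000L,
                         drug_name = "TUCATINIB", brand_names = "TUKYSA",
                         pt_catalog = default_pt_catalog(),
                         planted_signals = default_planted_signals(),
                         duplicate_rate = 0.05,
                         missingness = list(age = 0.60, sex = 0.02,
                                            event_date = 0.40,
                                            event_date_partial = 0.06,
                                            therapy_start = 0.10, country = 0.02),
                         sex_split = c(F = 0.970, M = 0.013, UNK = 0.017),
                         age_mixture = list(mean = 57, sd = 12),
                         country_mix = c(US = 0.80, other = 0.20),
                         reporter_mix = c(MD = 0.485, CN = 0.337, PH = 0.178),
                         outcome_mix = c(OT = 0.430, HO = 0.412, DE = 0.144,
                                         DS = 0.008, LT = 0.004, CA = 0.002),
                         onset_model = list(median_days = 30, sdlog = 1.9),
                         rho_scale = c("relative_reporting", "rate_ratio")) {
  rho_scale <- match.arg(rho_scale)
  pt_catalog <- as_tibble(pt_catalog)
  if (nrow(pt_catalog) == 0) abort("pt_catalog must contain at least one PT")
  stopifnot(all(c("pt", "soc", "rate") %in% names(pt_catalog)),
            all(pt_catalog$rate >= 0 & pt_catalog$rate <= 1),
            n_exposed >= 0, n_background >= 0, n_exposed + n_background > 0,
            duplicate_rate >= 0, duplicate_rate <= 1,
            all(unlist(missingness) >= 0), all(unlist(missingness) <= 1),
            all(planted_signals$rho >= 0))
  if (!all(planted_signals$pt %in% pt_catalog$pt)) {
    abort("planted_signals lists PTs absent from pt_catalog")
  }
  structure(list(seed = as.integer(seed), n_exposed = as.integer(n_exposed),
                 n_background = as.integer(n_background),
                 drug_name = drug_name, brand_names = brand_names,
                 pt_catalog = pt_catalog, planted_signals = planted_signals,
                 duplicate_rate = duplicate_rate, missingness = missingness,
                 sex_split = sex_split / sum(sex_split),
                 age_mixture = age_mixture,
                 country_mix = country_mix / sum(country_mix),
                 reporter_mix = reporter_mix / sum(reporter_mix),
                 outcome_mix = outcome_mix / sum(outcome_mix),
                 onset_model = onset_model, rho_scale = rho_scale),
            class = "faers_sim_config")
}

# exposed-arm per-report rate implementing the planted association strength
planted_exposed_rate <- function(rate, rho, n_exposed, n_background, rho_scale) {
  if (rho_scale == "rate_ratio") {
    p1 <- rho * rate
  } else {
    n <- n_exposed + n_background
    denom <- n - rho * n_exposed
    p1 <- ifelse(denom > 0, rho * rate * n_background / denom, 1)
  }
  clipped <- p1 > 1 | p1 < 0
  if (any(clipped)) warn(paste0(sum(clipped), " planted exposed rate(s) clipped to [0, 1]"))
  pmin(pmax(p1, 0), 1)
}

comed_names <- c("CAPECITABINE", "TRASTUZUMAB", "METFORMIN", "LISINOPRIL",
                 "OMEPRAZOLE", "ATORVASTATIN", "LEVOTHYROXINE", "ONDANSETRON")

fmt_dt <- function(d) format(d, "%Y%m%d")

#' Generate a synthetic FAERS corpus with known structure
#'
#' Emits DEMO/DRUG/REAC/THER/OUTC tables in the exact FAERS ASCII dialect the
#' reader consumes, together with a ground-truth ledger: realised per-term
#' counts per arm among retained (post-deduplication) reports, the planted
#' rates, and the duplicate map. Exposed reports carry the target drug with
#' role PS (plus random co-medications in other roles); every report carries
#' at least one event (reports drawing no catalogue PT receive the filler
#' complaint). A `duplicate_rate` fraction of cases is emitted twice: the
#' stale version shares the caseid with a lower caseversion and an earlier
#' FDA date, so case-level deduplication must remove exactly the ledger's
#' duplicate count.
#'
#' @param config A [faers_config()].
#' @param dir Optional directory: writes the five tables plus
#'   `ledger_terms.tsv` and `ledger_duplicates.tsv`.
#' @return A `faers_sim` list: `tables` (a `faers_tables`), `ledger` (list
#'   `terms`, `duplicates`, `totals`).
#' @export
generate_faers <- function(config, dir = NULL) {
  stopifnot(inherits(config, "faers_sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n_exp <- config$n_exposed
  n_bg <- config$n_background
  n <- n_exp + n_bg
  exposed <- c(rep(TRUE, n_exp), rep(FALSE, n_bg))
  caseid <- as.character(50000000L + seq_len(n))
  miss <- config$missingness

  # dates: therapy start, log-normal onset delay, event, then FDA receipt
  days <- seq(as.Date("2020-01-01"), as.Date("2024-06-30"), by = "day")
  start_date <- sample(days, n, replace = TRUE)
  onset <- round(rlnorm(n, log(config$onset_model$median_days),
                        config$onset_model$sdlog))
  event_date <- start_date + onset
  fda_date <- event_date + rpois(n, 30)

  age <- pmin(pmax(round(rnorm(n, config$age_mixture$mean, config$age_mixture$sd)), 18), 95)
  age_unit <- sample(c("YR", "MON"), n, replace = TRUE, prob = c(0.9, 0.1))
  age_val <- ifelse(age_unit == "MON", as.character(age * 12L), as.character(age))
  age_val[runif(n) < miss$age] <- ""
  sex <- sample(names(config$sex_split), n, replace = TRUE, prob = config$sex_split)
  sex[sex == "UNK" | runif(n) < miss$sex] <- ""
  country <- ifelse(runif(n) < config$country_mix[["US"]], "US",
                    sample(c("JP", "DE", "FR", "GB", "CA"), n, replace = TRUE))
  country[runif(n) < miss$country] <- ""
  reporter <- sample(names(config$reporter_mix), n, replace = TRUE,
                     prob = config$reporter_mix)

  event_dt <- fmt_dt(event_date)
  partial <- runif(n) < miss$event_date_partial
  event_dt[partial] <- substr(event_dt[partial], 1, 6)
  event_dt[runif(n) < miss$event_date] <- ""
  start_dt <- fmt_dt(start_date)
  start_dt[runif(n) < miss$therapy_start] <- ""

  # PT incidence: independent Bernoulli draws per catalogue term
  cat <- config$pt_catalog |>
    left_join(config$planted_signals, by = "pt") |>
    mutate(rho = dplyr::coalesce(.data$rho, 1))
  cat$p_exposed <- planted_exposed_rate(cat$rate, cat$rho, n_exp, n_bg, config$rho_scale)
  reac_list <- vector("list", nrow(cat))
  hit_any <- rep(FALSE, n)
  for (k in seq_len(nrow(cat))) {
    p <- ifelse(exposed, cat$p_exposed[k], cat$rate[k])
    hit <- rbinom(n, 1L, p) == 1L
    hit_any <- hit_any | hit
    reac_list[[k]] <- tibble(idx = which(hit), pt = cat$pt[k])
  }
  filler <- config$pt_catalog$pt[match("Drug ineffective", config$pt_catalog$pt)]
  if (is.na(filler)) filler <- cat$pt[which.max(cat$rate)]
  need_filler <- which(!hit_any)
  reac_idx <- dplyr::bind_rows(reac_list,
                               tibble(idx = need_filler, pt = rep(filler, length(need_filler))))

  # drug records: target as PS on exposed reports, plus co-medications
  name_pool <- c(config$drug_name, paste0(config$drug_name, "."),
                 tolower(config$drug_name), config$brand_names)
  target_name <- sample(name_pool, n_exp, replace = TRUE)
  n_comed <- rbinom(n, 2, 0.4) + ifelse(exposed, 0L, 1L)  # background >= 1 drug
  comed_rows <- tibble(
    idx = rep(seq_len(n), n_comed),
    drugname = sample(comed_names, sum(n_comed), replace = TRUE)
  ) |>
    mutate(role = ifelse(!exposed[.data$idx] & !duplicated(.data$idx), "PS",
                         sample(c("SS", "C", "I"), dplyr::n(), replace = TRUE)))

  retained_version <- rep(1L, n)
  n_dup <- round(config$duplicate_rate * n)
  dup_idx <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
  retained_version[dup_idx] <- 2L
  primaryid <- paste0(caseid, retained_version)

  demo <- tibble(
    PRIMARYID = primaryid, CASEID = caseid,
    CASEVERSION = as.character(retained_version), FDA_DT = fmt_dt(fda_date),
    SEX = sex, AGE = age_val, AGE_COD = ifelse(age_val == "", "", age_unit),
    OCCR_COUNTRY = country, OCCP_COD = reporter, EVENT_DT = event_dt
  )
  target_drug <- tibble(PRIMARYID = primaryid[exposed], DRUG_SEQ = "1",
                        ROLE_COD = "PS", DRUGNAME = target_name,
                        PROD_AI = config$drug_name)
  comed_seq <- as.character(ifelse(exposed[comed_rows$idx], 1L, 0L) +
                              stats::ave(comed_rows$idx, comed_rows$idx, FUN = seq_along))
  drug <- dplyr::bind_rows(
    target_drug,
    tibble(PRIMARYID = primaryid[comed_rows$idx], DRUG_SEQ = comed_seq,
           ROLE_COD = comed_rows$role, DRUGNAME = comed_rows$drugname,
           PROD_AI = comed_rows$drugname)
  )
  reac <- tibble(PRIMARYID = primaryid[reac_idx$idx], PT = reac_idx$pt)
  ther <- tibble(PRIMARYID = primaryid[exposed], DSG_DRUG_SEQ = "1",
                 START_DT = start_dt[exposed])
  n_out <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.6, 0.15))
  outc <- tibble(
    PRIMARYID = rep(primaryid, n_out),
    OUTC_COD = sample(names(config$outcome_mix), sum(n_out), replace = TRUE,
                      prob = config$outcome_mix)
  )

  # stale earlier versions of duplicated cases
  if (n_dup > 0) {
    stale_pid <- paste0(caseid[dup_idx], "1")
    stale_demo <- demo[dup_idx, , drop = FALSE] |>
      mutate(PRIMARYID = stale_pid, CASEVERSION = "1",
             FDA_DT = fmt_dt(fda_date[dup_idx] - sample(30:200, n_dup, replace = TRUE)))
    demo <- dplyr::bind_rows(demo, stale_demo)
    stale_map <- setNames(stale_pid, primaryid[dup_idx])
    add_stale <- function(tb) {
      sel <- tb[tb$PRIMARYID %in% names(stale_map), , drop = FALSE]
      sel$PRIMARYID <- unname(stale_map[sel$PRIMARYID])
      dplyr::bind_rows(tb, sel)
    }
    drug <- add_stale(drug); reac <- add_stale(reac)
    ther <- add_stale(ther); outc <- add_stale(outc)
  }

  raw <- list(demo = demo, drug = drug, reac = reac, ther = ther, outc = outc)
  tables <- parse_raw_tables(raw)

  truth <- tibble(primaryid = primaryid[reac_idx$idx], pt = reac_idx$pt,
                  arm = ifelse(exposed[reac_idx$idx], "exposed", "background")) |>
    distinct() |>
    count(.data$pt, .data$arm, name = "true_count") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "true_count",
                       values_fill = 0L, names_prefix = "count_") |>
    full_join(cat |> select("pt", "soc", "rate", "rho", "p_exposed"), by = "pt") |>
    mutate(across(dplyr::starts_with("count_"), ~ dplyr::coalesce(.x, 0L)))
  for (cc in c("count_exposed", "count_background")) {
    if (!cc %in% names(truth)) truth[[cc]] <- 0L
  }
  ledger <- list(
    terms = truth,
    duplicates = {
      stale_ids <- paste0(caseid[dup_idx], "1")
      tibble(caseid = caseid[dup_idx], stale_primaryid = stale_ids,
             retained_primaryid = primaryid[dup_idx])
    },
    totals = list(n_emitted = n + n_dup, n_retained = n, n_exposed = n_exp,
                  n_background = n_bg, n_duplicates = n_dup)
  )
  out <- structure(list(tables = tables, ledger = ledger),
                   class = "faers_sim", config = config)
  if (!is.null(dir)) {
    write_faers_tables(tables, dir)
    readr::write_tsv(ledger$terms, file.path(dir, "ledger_terms.tsv"))
    readr::write_tsv(ledger$duplicates, file.path(dir, "ledger_duplicates.tsv"))
  }
  out
}

#' @export
print.faers_sim <- function(x, ...) {
  t <- x$ledger$totals
  cat(sprintf("<faers_sim> %d reports (%d exposed, %d background, %d stale duplicates)\n",
              t$n_emitted, t$n_exposed, t$n_background, t$n_duplicates))
  invisible(x)
}
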