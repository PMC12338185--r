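---
title: "Disproportionality signal mining on FAERS-format spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal mining on FAERS-format spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(signalmine)
library(dplyr)
```

## The problem

Spontaneous-report databases such as FAERS collect voluntary reports linking
drugs to adverse events (AEs). They have no denominator — nobody knows how
many patients took a drug without an event — so absolute risks cannot be
estimated. What can be estimated is *disproportionality*: whether an event is
reported together with a drug more often than the rest of the database would
predict. Each (drug, event) pair is summarised by a fourfold table of report
counts:

|              | event | no event |
|--------------|-------|----------|
| drug         | a     | b        |
| other drugs  | c     | d        |

with `N = a + b + c + d`. The package implements the full path from raw
FAERS-format quarterly extracts to ranked signal tables built on these
counts, for any target drug; its validation corpus is modelled on a
primary-suspect cohort of the HER2 inhibitor tucatinib.

## From raw tables to analysable reports

FAERS quarterly extracts are dollar-delimited text tables: DEMO
(demographics, one row per report version), DRUG (one row per drug record,
with role codes PS/SS/C/I), REAC (one row per MedDRA preferred term, PT),
THER (therapy dates) and OUTC (outcome codes). `read_faers_tables()` parses
them with typed columns; the cleaning rules are:

* **Deduplication.** Successive versions of a case share a case number.
  `deduplicate_reports()` keeps, per `caseid`, the record with the latest FDA
  submission date. The tie-breaks — higher `caseversion`, then higher
  zero-padded `primaryid` — are not dictated by any FAERS rule; they were
  chosen so the result is deterministic whatever the input order. Records
  with no submission date lose against any dated record.
* **Partial dates.** `YYYYMM` and `YYYY` values keep their year (usable for
  report-year summaries) but give no day-resolution date, so they are never
  used in time-to-onset arithmetic: inventing a day would bias onset times.
* **Ages.** Converted to years using the FAERS unit codes YR, MON (/12), DY
  (/365.25) and DEC (×10); any other unit code leaves the age absent rather
  than guessed. Outcome codes beyond the six reported categories (e.g. RI)
  fold into "other serious".
* **Counting unit.** The report. A PT repeated in several REAC rows of one
  report counts once; a report with several PTs of one system organ class
  (SOC) counts once for that SOC. Consequently `a + b` is the exposed cohort
  size for every term at a level.

The exposed cohort is every deduplicated report that mentions the target
drug (free-text `DRUGNAME` or `PROD_AI`, case-insensitive, punctuation
stripped, with a user-extensible synonym list for brand names) in a
qualifying role — by default primary suspect only. All other reports form
the background; nothing is discarded, and reports naming the drug in
non-qualifying roles stay in the background. PTs map to their primary SOC
through a user-supplied two-column table (licensed MedDRA is not bundled; a
toy dictionary ships for testing); PTs missing from the map get the sentinel
SOC `UNMAPPED` so the analysis stays total, and secondary SOC assignments
are out of scope.

## The four statistics

`disproportionality()` computes, per term:

* **ROR** `= (a·d)/(b·c)`, with Wald 95% CI from
  `SE(lnROR) = sqrt(1/a + 1/b + 1/c + 1/d)`.
* **PRR** `= (a/(a+b)) / (c/(c+d))`, with
  `SE(lnPRR) = sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d))`, plus the Pearson
  chi-square without continuity correction (a Yates variant is a flag).
* **BCPNN information component**: the raw
  `IC = log2(a·N / ((a+b)(a+c)))`, and the posterior moments `E(IC)`,
  `V(IC)` of the single-drug/single-event model with priors
  `alpha = beta = 2`, `alpha1 = beta1 = gamma11 = 1` and the joint prior
  total `gamma` recomputed per table so that independence maps to IC = 0.
  The signal bound is `IC025 = E(IC) − 2·sqrt(V(IC))`. In the symmetric
  table a = b = c = d = 25 these defaults give `gamma = 4` and `E(IC) = 0`
  exactly, a useful closed-form check.
* **EBGM**, here the simplified relative-reporting-ratio form
  `a·N/((a+b)(a+c))` — identically `2^IC_raw` — with a Wald interval using
  the ROR-type SE; its lower bound is EBGM05. This is *not* DuMouchel's MGPS
  posterior mean; the full empirical-Bayes machinery (hyperparameter
  estimation by EM, posterior shrinkage) is deliberately out of scope, and
  the printed signal tables this package mirrors use the simplified form.

Thresholds: ROR and PRR signal when `a ≥ 3` and the CI lower limit exceeds
1; BCPNN when `IC025 > 0`; EBGM when `EBGM05 > 1`. `combined_signal`
requires all four — the conjunction trades sensitivity for a lower
false-positive rate. No multiple-testing adjustment is applied, matching
standard practice for these threshold rules; that is a known limitation, not
an oversight. Terms never reported with the drug (`a = 0`) are excluded from
output since no threshold can pass.

**Zero cells.** When a term is reported with essentially only the drug
(`b`, `c` or `d` zero with `a ≥ 1`), the ratio estimators degenerate. The
default policy adds Haldane's 0.5 to all four cells *of that row only* and
flags it `corrected`; chi-square and the Bayesian moments are well defined
on raw counts and stay uncorrected. A `strict` policy leaves such rows
undefined instead. Non-degenerate rows are never touched, so rankings of
ordinary rows are unaffected.

```{r}
dispro_stats(3, 2, 10, 90) |> tidy()
```

## Descriptive summaries

`summarize_categorical()` reproduces the usual cohort-description tables.
Percent denominators follow the internal-consistency rule: demographic
blocks use the sum of displayed categories (including "unknown"), outcomes
use the number of outcome *records* (a report may contribute several), and
onset buckets use all onset records including unknown. Age strata are fixed
at <18, 18–44, 45–59, 60–74, 75–89, ≥90 years; quartiles use linear
interpolation (R's type 7 — no convention is universal, this one is R's
default and is pinned by tests against a sort-based oracle).

Time to onset is the calendar-day difference between the report's event date
and the therapy start of the matched drug record (linked via
`DSG_DRUG_SEQ`), with buckets on half-open intervals
`[0,7), [7,28), [28,60), [60,∞)` days. The boundary convention puts day 28
in the upper bucket, so "within the first month" is exactly the first two
buckets. Starts after the event are excluded with a warning; partial dates
yield "unknown".

## The synthetic corpus generator

`generate_faers()` emits a complete five-table corpus in the exact dialect
the reader consumes, plus a ground-truth ledger, so every pipeline stage is
testable offline. It emulates: case versioning (a configurable fraction of
cases appears twice, the stale version with a lower caseversion and earlier
FDA date — deduplication must remove exactly those); free-text drug-name
noise (case variants, trailing punctuation, a brand synonym); missing and
partial dates; demographic mixes shaped like a breast-cancer cohort
(female-dominant, median age near 57); log-normal onset delays targeting a
~30-day median with a wide spread (`sdlog = 1.9`, chosen so the quartiles
sit near 8 and 105 days); and per-PT event draws.

Two simplifications matter when interpreting green tests: PTs are drawn
independently within a report (real reports have strongly co-occurring
terms), and drug-name noise is limited to case/punctuation (no misspelling
model). Passing tests therefore validate counting, deduplication and the
statistics — not robustness to messy real-world nomenclature.

Each planted signal has a strength `rho`, defined as the **relative
reporting ratio** — the observed-to-expected ratio against the whole corpus,
which is exactly what EBGM estimates. The generator achieves it with an
exposed-arm rate `rho·rate·n_bg/(N − rho·n_exposed)`; when the exposed
cohort is a small fraction of the corpus this is the familiar
`rho × background rate`, but at the validation sizes (2,000 exposed /
20,000 background) the exact form is needed for `rho` to be the estimand —
with the naive rate ratio, the exposed arm inflates the event margin and
EBGM converges below `rho`. A `rate_ratio` mode provides the literal scaled
rate for rate-convergence checks. Because every FAERS report must carry at
least one reaction, reports drawing no catalogue PT receive a filler
complaint ("Drug ineffective"); the filler keeps margins exact but is itself
mildly depleted in the exposed arm, so it is never used as a planted or null
test term.

The validation design used by the test suite runs 200 seeded corpora at
2,000/20,000 with planted `rho` of 1, 2 and 5, checking EBGM interval
coverage, combined-signal detection of the `rho = 5` terms and the absence
of flags on `rho = 1` terms. One caveat the tests make visible: the
as-printed EBGM interval uses the odds-ratio-style SE
`sqrt(1/a+1/b+1/c+1/d)`, which overstates the sampling variance of the
relative reporting ratio (the fixed margins and the overlap of `a` with
`a + c` remove much of it). The interval is therefore conservative — its
realised coverage of `rho` sits near 98–100% rather than 95%, increasingly
so for large `rho`. It never under-covers, so EBGM05 signal decisions err
toward fewer false positives.

## Reconstructing published rows

`reconstruct_row()` inverts a printed signal-table row: given `a` and the
ROR, PRR and chi-square printed at two decimals, it searches for integer
`(b, c, d)` whose recomputed statistics round back to the printed values,
letting the remaining columns (EBGM, IC) be checked for internal
consistency. The printed triple hardly constrains the background size —
chi-square is nearly scale-free once the background dominates — but the
integer lattice gets finer as `N` grows, so the squared-log-error minimiser
lies at the largest admissible table; the search works at the configured cap
(`N ≤ 1e7`, the realistic scale of a pooled FAERS extract) and falls back to
the finite chi-square root that does pin small tables. Inconsistent inputs
produce an explicit "not reconstructible" error rather than a nearest
guess.

```{r}
reconstruct_row(a = 2098, ror = 3.19, prr = 2.71, chi2 = 2462.95)
```

## End to end

```{r, warning = FALSE}
dir <- tempfile()
generate_faers(faers_config(seed = 1, n_exposed = 500, n_background = 5000),
               dir = dir)
run <- run_signal_pipeline(dir, drug = "tucatinib", synonyms = "TUKYSA")
glance(run$signals_pt)
tidy(run$signals_pt) |>
  filter(combined_signal) |>
  select(term, soc, a, ror, prr, chi2, ic025, ebgm, ebgm05)
```

`autoplot()` on a result table draws the ROR forest plot;
`plot_time_to_onset()` charts the onset buckets. The `exec/signal-mine`
script exposes `run`, `simulate` and `stats` subcommands for shell use.

## Known limitations

* Crude (unstratified) tables only; age/sex/year-adjusted
  disproportionality and time-scan statistics are out of scope.
* Duplicate detection is case-number identity only; probabilistic
  same-patient linkage across case numbers is not attempted.
* The EBGM here is the simplified relative reporting ratio, and its
  interval is conservative (see above); MGPS shrinkage would be needed for
  stable estimates at very small counts.
* A signal is a statistical disproportion in a reporting database, not
  evidence of causality; reporting artefacts (notoriety, channelling) pass
  straight through the arithmetic.
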