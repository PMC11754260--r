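---
title: "Disproportionality analysis of spontaneous reports: models, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of spontaneous reports: models, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pvsignal)
```

## The problem and the data model

Spontaneous-report systems collect unsolicited reports of suspected adverse
events (AEs). A report names one or more drugs (with a role code: primary
suspect PS, secondary suspect SS, concomitant C, interacting I) and one or
more MedDRA Preferred Terms (PTs), each PT belonging to one System Organ
Class (SOC). Reports are resubmitted as new *versions* under a stable
`caseid`; only the latest version is valid. There is no denominator of drug
exposure, so absolute risks are not estimable; instead, *disproportionality
analysis* asks whether an event is reported relatively more often with a
drug than with all other drugs, via a 2×2 table of report×event pairs:

|            | event          | other events   |
|------------|----------------|----------------|
| drug       | a              | b              |
| other drugs| c              | d              |

The counting unit throughout is the **report×event pair** (each PT counted
once per report), not the report: a report with three PTs contributes three
pairs. Published tables in this field report "number of AEs" far larger than
the number of reports, and their percentages only reconcile under pair
counting, which is why `tabulate_events()` counts pairs for every cell,
including the margins `a+b` (all target pairs) and `N` (all pairs).

## The three estimators and their thresholds

With `N = a+b+c+d`:

* **ROR** `= ad/bc`, `se(ln ROR) = sqrt(1/a+1/b+1/c+1/d)`,
  `CI = exp(ln ROR ± 1.96 se)`. Signal: `a ≥ 3` and CI lower bound `> 1`.
* **PRR** `= (a/(a+b))/(c/(c+d))`,
  `se(ln PRR) = sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d))`, same CI construction.
  Signal: `a ≥ 3`, CI lower bound `> 1`, and Pearson `χ² > 4`. The χ² is
  Yates-corrected by default (the common pharmacovigilance practice;
  `yates = FALSE` gives the uncorrected statistic). The "lower limit > 1"
  rule is read as the 95% CI lower bound of PRR — that is the only use of
  `se(ln PRR)`, so a reading that ignored it would leave the published SE
  row purposeless.
* **BCPNN / information component.** `IC = log2(aN/((a+b)(a+c)))` is the
  log2 observed-to-expected co-reporting ratio. Bayesian smoothing uses Beta
  priors on the joint and marginal reporting probabilities with constants
  `alpha = beta = 2`, `alpha1 = beta1 = gamma11 = 1` (the standard
  Bate-style choice, configurable via `bcpnn_priors()`), and
  `gamma = gamma11 (N+alpha)(N+beta) / ((a+b+alpha1)(a+c+beta1))`
  recomputed per table so the prior is centred on independence. The
  closed-form summaries are

  `EIC = log2 [ (a+gamma11)(N+alpha)(N+beta) / ((N+gamma)(a+b+alpha1)(a+c+beta1)) ]`

  `VIC = [ (N−a+gamma−gamma11)/((a+gamma11)(1+N+gamma)) + (N−(a+b)+alpha−alpha1)/((a+b+alpha1)(1+N+alpha)) + (N−(a+c)+beta−beta1)/((a+c+beta1)(1+N+beta)) ] / ln(2)²`

  and the signal bound is `IC025 = EIC − 2√VIC`, with signal iff
  `IC025 > 0` (strict). `a = 0` yields `IC = −Inf` while `EIC`/`VIC` stay
  finite through the priors.

Zero cells make ROR/PRR non-evaluable by default (their flags are then
`FALSE`; the `a ≥ 3` rule makes `a = 0` moot anyway); a Haldane–Anscombe
`+0.5` correction is available behind `continuity = TRUE`.

### BCPNN numerics: what the closed forms are, and are not

The closed-form `EIC` is the log2 of a *ratio of posterior means*, and `VIC`
is a first-order delta-method variance, both under a model of independent
Beta posteriors for the joint cell and the two margins. Neither is an exact
posterior moment of `IC`:

* the Jensen gap between `log2 E[p]` and `E[log2 p]` is `O(1/a)`;
* the delta variance ignores both second-order terms and the positive
  dependence between the joint cell and its margins (under a genuine 4-cell
  Dirichlet posterior that dependence roughly halves the variance of `IC`
  on typical tables).

The package therefore exposes two methods in `bcpnn_stat()`:
`method = "approx"` (default) evaluates the printed closed forms exactly as
published — these drive `IC025` and all flags — and
`method = "posterior"` returns the exact moments of the independent-Beta
model via digamma/trigamma functions. The test suite holds both against
Monte-Carlo oracles: the exact moments agree with their oracle within three
Monte-Carlo standard errors at every grid table, while the closed forms do
not (an intentionally red acceptance test documents the size of the
approximation error rather than hiding it). For ranking and thresholding
the distinction rarely changes a conclusion — the bias is conservative for
`EIC` at small `a` and `VIC` is inflated, which makes `IC025` *more*
conservative — but users comparing `IC025` values near zero at small counts
should prefer the posterior method.

## Screening rules and their edge cases

* **Deduplication** keeps, per `caseid`, the row maximizing
  `(fda_dt, caseversion, primaryid)` lexicographically; missing dates sort
  lowest and `primaryid` is compared as a character string, making the
  choice total and deterministic. The operation is idempotent.
* **Age bins**: published tables label bins `40∼65` and `66∼79`, which are
  adjacent but leave 65–66 ambiguous; the package implements `[40,66)` and
  `[66,80)` so the bins partition the age axis. Ages are normalized to years
  at read time (DEC ×10, YR ×1, MON ÷12, WK ÷52, DY ÷365.25); negative ages
  are treated as missing and logged.
* **Drug standardization** is a transparent first-match-wins dictionary of
  case-insensitive substrings or anchored regular expressions, not an NLP
  system; unmatched names become `OTHER`. The default role filter is
  `{PS}` ("as the primary drug"), configurable.
* **Reports naming both target drugs** count for each drug; the overlap is
  logged. Excluding them would silently change both drugs' denominators.
* **Device-use merge**: the PTs "Device use issue", "Wrong technique in
  product usage process" and "Product use issue" are relabeled to a single
  "Device use issue" before pair deduplication, so a report listing two of
  them contributes one pair.
* **SOC-level counting**: each report–PT pair contributes to its SOC; a
  report with two PTs in one SOC contributes two SOC pairs. This keeps the
  PT→SOC rollup exactly conservative (`Σ a` identical at both levels). The
  alternative (one SOC pair per report) is defensible but breaks
  conservation, and nothing in the published denominators supports it.
* **Background construction**: `c`/`d` come from all non-target reports in
  the loaded extract — including the other study drug — restricted to the
  same quarter window as the target drug's extraction window. Both choices
  are configurable (per-drug `windows` in `study_config()`).
* **Ranking** sorts by `IC` descending with ties broken by `a` descending
  then event name, after dropping a configurable exclusion list (the merged
  device-use PT and indication terms, which reflect usage rather than harm)
  and, in the reporting layer, rows not flagged by all three algorithms.
* **Time-scan**: per-calendar-year recomputation of the 2×2 and `IC` for a
  PT (default; cumulative pooling available), emitted only when the target
  has pairs in at least two years — a single year cannot show a trend.
* **Rounding**: all printed percentages use half-up rounding to two
  decimals, matching the arithmetic of published tables (base R's
  half-to-even would disagree on exact halves).

## The synthetic world

The generator emulates the structure of quarterly dumps, not any real
drug's epidemiology. Defaults (a *stated world*, chosen once): 20,000 cases
across 16 quarters (2021Q1–2024Q4); two target combination inhalers holding
10% and 15% of reports, the remainder background; a 60-PT/8-SOC vocabulary
with Zipf-like background rates (rate ∝ 1/(rank+4), normalized); PT count
per report truncated-Poisson(3) on [1,8], drawn *without replacement* with
probability ∝ `background_rate × RR` so the per-report uniqueness invariant
is exercised; 10% of cases emitted as two versions differing only in
`fda_dt`/`caseversion`/`primaryid`; demographics mirroring published
inhaler-cohort tables (45% female, 75% consumer reporters, US-dominated
countries, 60% missing age). Injected associations: device-use issue RR 5
and dysphonia RR 3 for one drug, candida infection RR 5 and pneumonia RR 3
for the other — effect sizes typical of the moderate-to-strong signals such
studies report.

`expected_table()` is the analytic oracle: inclusion probabilities for
weighted sampling without replacement have no elementary closed form, so it
uses a Poissonization fixed point (for each PT count `K`, solve
`Σ_j (1 − exp(−w_j t)) = K`, set `π_j = 1 − exp(−w_j t)`, then mix over the
truncated-Poisson `K`). This is exact for equal weights and accurate to
about the largest normalized weight otherwise; the test suite validates it
against exact enumeration of the sequential sampling law on a small
vocabulary and against 200-replicate pipeline recovery of an injected RR 3
signal. A first-order `E[K]·w̃` approximation was measured at up to 25% off
for common PTs and rejected.

What the generator does **not** model — hence what a green test does not
establish: reporting-bias dynamics (Weber effect, stimulated reporting),
drug–drug interactions, dose and therapy dates, LLT→PT coding noise,
country-specific PT profiles, or correlated PT co-occurrence beyond the
shared weight vector. Signals recovered from this world validate the
*pipeline arithmetic and estimator calibration*, not clinical conclusions.

## Known limitations

* The full FAERS schema (INDI, THER, OUTC, RPSR), XML dumps and the openFDA
  API are out of scope; only DEMO/DRUG/REAC are read.
* The PT→SOC map is user-supplied (MedDRA is licensed); unmapped PTs roll up
  to the sentinel SOC `UNMAPPED`.
* Published per-pair statistics from multi-gigabyte national databases are
  not reproducible at desk scale because their background cells are not
  printed; the package's correctness argument rests on the synthetic ground
  truth and the statistical oracles instead.
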