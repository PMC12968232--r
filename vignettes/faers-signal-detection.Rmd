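---
title: "Methods: disproportionality screening and time-to-onset analysis of FAERS reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening and time-to-onset analysis of FAERS reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`faersignal` implements a complete post-marketing pharmacovigilance workflow
over FDA Adverse Event Reporting System (FAERS) quarterly files, built for
studies of the cystic-fibrosis CFTR-modulator combination
lumacaftor/ivacaftor (Orkambi) but configurable for any target drug.  This
vignette is the package's own account of the statistical machinery, the
choices behind its defaults, and what its synthetic-data validation does and
does not demonstrate.

## Data model and case processing

FAERS publishes "$"-delimited quarterly tables: DEMO (demographics), DRUG,
REAC (reactions coded as MedDRA preferred terms, PTs), INDI, THER (therapy
dates) and OUTC (outcomes).  A *case* (CASEID) may appear as several report
versions (PRIMARYID).  Deduplication follows the FDA-recommended rule: keep
the version with the most recent FDA receipt date per case and, on ties, the
highest PRIMARYID.  An FDA_DT that does not parse as an 8-digit date sorts
as oldest, so a parseable version always beats an unparseable one — the rule
has to order these somehow, and preferring interpretable metadata is the
conservative choice.  From 2019Q4 onward, cases named in the quarterly
"deleted case" lists are removed after deduplication.

Target-drug exposure is exact matching of normalized drug names (uppercase,
punctuation collapsed) against a configurable synonym list, restricted to
the primary-suspect (PS) role.  Substring matching is deliberately avoided:
`IVACAFTOR` must not silently capture combination products such as
`LUMACAFTOR/IVACAFTOR`.

Ages are converted to years (decades ×10, months /12, weeks /52.14, days
/365.25, hours /8766) and weights to kilograms (pounds × 0.453592).  The
unit of counting for every disproportionality statistic is the **PT
record** — one row per (report, distinct PT).  A report listing three
distinct reactions contributes three records; a PT repeated within one
report collapses to one record.  This distinction matters because spontaneous
reports typically carry about two reactions each, so report-level and
record-level denominators differ by a factor of ~2.  PT-to-SOC (system organ
class) mapping is supplied by the user as a two-column table — the MedDRA
dictionary is licensed and is never bundled; unmapped PTs keep the sentinel
class `UNMAPPED` so every record belongs to exactly one SOC.

Indication filtering (e.g. restricting to cystic-fibrosis reports) is off by
default and available as a configuration switch, since the large majority of
target-drug reports carry the approved indication anyway and filtering
discards reports with missing indication fields.

## Disproportionality statistics

Every screen is built on the 2×2 contingency table

|                  | target event | other events |
|------------------|--------------|--------------|
| target drug      | a            | b            |
| all other drugs  | c            | d            |

**Reporting odds ratio.** `ROR = ad/bc` with the Wald interval
`exp(log ROR ± z·sqrt(1/a + 1/b + 1/c + 1/d))`.  When any cell is zero the
Haldane correction adds 0.5 to all four cells and the row is marked
`corrected`; nonzero tables are never altered.  With the correction disabled,
a zero `a` cell yields an undefined-signal marker rather than an error.

**BCPNN information component.** The default estimator is the shrinkage
form: with expected count `E = (a+b)(a+c)/N`,

```
IC    = log2((a + 0.5) / (E + 0.5))
IC025 = IC − 3.3·(a + 0.5)^(−1/2) − 2·(a + 0.5)^(−3/2)
```

The added 0.5 shrinks sparse cells toward independence and the credibility
bound is deliberately conservative for small `a` (at `a = 3` the penalty
alone is about 2.1 bits).  The original closed-form posterior
expectation/variance under the standard Beta–Dirichlet priors is available
via `bcpnn_ic(..., variant = "exact")` for users who want the classical
formulation; the shrinkage form is the default because it has become the
common implementation when no prior hyperparameters are published for a
study.

**Dual-threshold flag.** A term is a positive signal only when it passes
both methods simultaneously: at least `min_cases = 3` records, ROR 95% CI
lower bound > 1, and IC025 > 0.  These thresholds are standard
pharmacovigilance practice and are configuration-overridable; the package
treats them as a documented assumption, not a tuned quantity.  Requiring
both statistics materially reduces false positives: under a null generator
the IC025 bound alone keeps the flagged fraction of eligible terms well
below 5% (the test suite measures this over 200 simulations).

**Sensitivity analyses.** Two re-screens mirror common practice: a
*monotherapy* screen that drops target reports listing any other medication
(removing concomitant-drug confounding), and *comparator* screens that
repeat the whole analysis with same-indication drugs (ivacaftor,
tezacaftor/ivacaftor) as the target.  Signals flagged for every comparator
as well are interpreted as disease-linked rather than drug-specific.

## Clinical priority scoring and signal origin

Each flagged PT is scored 0–2 on four criteria: reporting rate (share of
all target-drug PT records; > 10% → 2, 1–10% → 1), magnitude of the ROR CI
lower bound (> 5 → 2, 2–5 → 1), reported case-fatality rate (> 50% → 2,
25–50% → 1) and clinical relevance (Designated Medical Event list → 2,
Important Medical Event list → 1).  Published banding of this kind leaves
the edges ambiguous ("2–5" vs "1–2"); the package resolves every boundary
as upper-inclusive for the middle band, which makes the scoring a total,
deterministic function that the test suite checks against an independent
lookup over all 81 band combinations.  Totals of 0–2, 3–5 and 6–8 map to
low, medium and high priority.  The DME/IME and label term lists are
user-supplied files; no list content ships with the package.

Signal origin is classified per flagged term: `expected` when the term is
on the drug label, `disease_expected` when it is flagged for **all**
comparator drugs (pointing at the underlying disease), `unexpected`
otherwise.  A term absent from a comparator's screen counts as not flagged
there.

## Stratified (modified-ROR) subgroup analysis

Within the target drug's reports, each term's 2×2 table contrasts two
strata (males/females, 50–100 kg vs < 50 kg, QD vs BID dosing, fatal vs
non-fatal).  This is not an epidemiological odds ratio but a comparative
disproportionality measure.  The ROR code path is shared with the primary
screen; inference combines a chi-square test (no continuity correction by
default, matching common volcano-plot practice at these counts; Yates
correction is a flag) with Benjamini–Hochberg adjustment across the terms
of one stratifier.  Adjusting within each stratum-variable screen (rather
than globally across all stratifiers) was an open choice; per-screen
adjustment keeps each volcano plot self-contained.  The direction rule:
CI lower bound > 1 with adjusted p < 0.05 flags group 1, upper bound < 1
flags group 2.

## Logistic risk-factor regression

For an outcome PT (depression by default), reports are coded 1 when they
mention the term.  The analysis is complete-case over six covariates (age
group, sex, reporter type, country, dosing frequency, monotherapy) with
reference levels 18–65 years, female, health-professional, United States,
BID and non-monotherapy.  Each covariate is fitted alone; those with Wald
p < 0.05 enter the multivariate model.  Fitting is maximum likelihood by
iteratively reweighted least squares (50 iterations).  Complete separation
is detected (diverging coefficients with fitted probabilities pinned at
0/1) and reported per covariate as a non-estimable row rather than silently
accepted or penalized — no Firth correction is applied, by design.

## Time-to-onset analysis

TTO is the interval in days from the earliest valid full therapy start date
of the target drug to the event date.  Only complete 8-digit dates qualify;
partial (`YYYYMM`, `YYYY`) and missing dates are excluded with per-reason
counts, as are non-positive intervals (the Weibull support is positive, so
same-day onsets are excluded and documented as such) and intervals beyond
9,125 days — a 25-year implausibility cap, which is the package's explicit
reading of "implausible date entries".  One sample per report is the
default unit (per-record analysis is available), since onset is a property
of the (patient, therapy) pair rather than of each coded reaction.

Intervals are summarized in 30-day bins with an open `>360` bin, and per
SOC by median and IQR (midpoint convention for even counts); a report
contributes to every SOC its PTs map to.

The Weibull fit maximizes the likelihood via Newton iteration on the
profile score for the shape (the scale is closed-form given the shape),
with a bracketing fallback; confidence intervals come from the observed
information on the log-parameter scale, exponentiated, which respects
positivity.  The shape CI drives the failure classification: upper bound
< 1 → *early failure* (decreasing hazard), lower bound > 1 → *wear-out*
(increasing hazard), otherwise *random* (roughly constant hazard).
Subgroups are compared with log-rank tests computed on fully observed
times — FAERS samples exist only because the event occurred, so there is no
censoring model — plus Wilcoxon rank-sum tests (exact for small untied
samples, tie- and continuity-corrected normal approximation otherwise) and
Dunn's pairwise rank tests with BH adjustment for the dose groups.

## The synthetic FAERS generator

Because real FAERS snapshots are multi-gigabyte downloads, the package
ships a generator that emits quarterly files in exactly the ingestion
format, with full ground truth.  Its defaults encode the reporting
conditions of a CF-modulator safety study:

* one target drug (10% of reports), two same-indication comparators (6%
  each) and a background drug catalog; concomitant drugs drawn
  independently per report with Pulmozyme-led frequencies;
* 38 PTs across 12 SOCs with background reporting probabilities between
  0.2% and 8%; planted drug–event associations as **odds multipliers**
  (`odds' = θ·p/(1−p)`), so a planted pair's expected ROR equals its θ
  exactly and unplanted pairs have expected ROR 1 — the quantity under
  test is the ROR, so the planting is parameterized in its units;
* label-type associations for the target only (e.g. pulmonary
  exacerbation θ = 60, cough θ = 5), disease-type associations shared by
  all three modulators (hospitalisation θ = 8), and unexpected
  target-only associations (depression θ = 2.5 with a male log-odds shift
  of log 0.224 so the regression module has a recoverable sex effect);
* heavy missingness mirroring spontaneous reporting: weight missing in
  82% of reports, age 41%, dosing frequency 27%, with a female-leaning
  sex ratio, consumer-heavy reporter mix and US-dominant countries;
* onset intervals Weibull with shape 0.79 and scale 400 days (decreasing
  hazard, median ≈ 250 days); therapy start uniform over the study
  window, event = start + onset, FDA receipt = event + geometric lag
  (mean ≈ 30 days); about half of start dates and a third of event dates
  are missing and 8% partial, leaving roughly a quarter of reports with a
  valid TTO pair;
* 8% duplicate case versions (same CASEID, later FDA_DT) and 1% deleted
  cases, exercising the deduplication chain end to end.

Identical seeds give byte-identical files.  The default study size is
20,000 reports — roughly 2,000 target-drug reports — which keeps a full
pipeline run to a few seconds while leaving planted moderate-strength
signals comfortably detectable.

Two honest caveats about what passing tests on this generator shows.
First, drug–event and drug–drug correlation structure in real FAERS is far
richer (co-prescription clusters, stimulated reporting waves, duplicate
records that differ in content, free-text drug names); the generator draws
concomitants independently and writes clean table structure, so ingestion
robustness to truly messy files is only partially exercised.  Second, when
many strong associations are planted on one drug, the *record-level*
empirical ROR of each pair falls below its planted θ: the extra planted
records inflate the `b` cell.  This is a real property of record-based
disproportionality, not a generator artifact — single-signal
configurations recover θ directly, and the validation suite uses both
designs deliberately.

## Numerical and reproducibility choices

* All randomness flows from a single integer seed; pipeline reruns with
  the same configuration and seed are byte-identical.  For that reason the
  run manifest records a configuration hash and package version but no
  wall-clock timestamp.
* Result tables are written with numerics rounded to 4 decimals for
  diffability; returned objects keep full precision.
* Validation problem sizes: the oracle-equivalence check uses 20 datasets
  of 2,150–5,000 reports with 50 PTs; null calibration uses 200
  simulations of 2,000 reports; planted-signal power uses 100 replicates
  of 20,000 reports; Weibull recovery uses 100 replicates of n = 1,592 at
  shape 0.79; regression recovery uses 100 replicates of n = 3,440.  These
  sizes were chosen to match the corresponding strata of the motivating
  study design while keeping the whole suite fast on a single CPU.

## Known limitations

* Only the post-2014 FAERS layout is supported, and there is no download
  client — users supply the quarterly files.
* PRR, EBGM/MGPS and other disproportionality estimators are out of scope;
  the package implements exactly the ROR + BCPNN pair.
* Disproportionality measures reporting, not incidence; nothing here
  estimates risk in the exposed population, and the per-SOC and subgroup
  outputs inherit all the selection and notoriety biases of spontaneous
  reporting.
* The logistic module offers no penalized fallback for separated designs,
  and the TTO module has no interval-censoring machinery — both by design.
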