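# faersignal

Pharmacovigilance signal detection and time-to-onset analysis for FDA
Adverse Event Reporting System (FAERS) spontaneous reports, built around the
post-marketing safety assessment of the cystic-fibrosis CFTR-modulator
combination lumacaftor/ivacaftor (Orkambi) and configurable for any target
drug.

Spontaneous-report databases cannot measure incidence, but they can reveal
*disproportionality*: drug–event pairs reported more often than the database
background predicts. `faersignal` takes raw FAERS quarterly files (or a
bundled synthetic emulator with planted ground truth) through the complete
study workflow used in modern pharmacovigilance papers:

1. **Ingestion & deduplication** — parse the "$"-delimited DEMO / DRUG /
   REAC / INDI / THER / OUTC tables; per CASEID keep the report version with
   the most recent FDA_DT (ties: highest PRIMARYID); drop deleted cases;
   select reports naming the target drug as primary suspect via exact
   normalized synonym matching.
2. **Disproportionality screening** — for every preferred term (PT) and
   system organ class (SOC), a 2×2 table of PT records yields the reporting
   odds ratio with Wald CI,

   `ROR = ad/bc`,  `CI = exp(log ROR ± 1.96·√(1/a+1/b+1/c+1/d))`,

   and the BCPNN information component with shrinkage credibility bound,

   `IC = log2((a+½)/(E+½))`, `E = (a+b)(a+c)/N`,
   `IC025 = IC − 3.3(a+½)^{−1/2} − 2(a+½)^{−3/2}`.

   A term is a positive signal only when `a ≥ 3`, ROR CI lower bound > 1
   **and** IC025 > 0. Monotherapy and same-indication comparator
   (ivacaftor, tezacaftor/ivacaftor) sensitivity screens re-run the whole
   analysis.
3. **Clinical priority & origin** — each flagged PT scores 0–2 points on
   reporting rate, ROR lower bound, case-fatality rate and DME/IME
   relevance (total 0–8 → low/medium/high priority), and is classified as
   expected (on label), disease-expected (flagged for all comparators) or
   unexpected.
4. **Stratified modified-ROR screens** — sex, weight, dosing-frequency and
   fatality subgroup 2×2 tables with chi-square tests and
   Benjamini–Hochberg adjustment (volcano-plot tables).
5. **Logistic risk-factor regression** — univariate screen then
   multivariate IRLS fit for an outcome PT (depression by default) over
   age, sex, reporter, country, frequency and monotherapy, complete-case.
6. **Time-to-onset** — days from earliest valid therapy start to event,
   30-day bins, per-SOC medians/IQRs, a Weibull maximum-likelihood fit
   whose shape CI classifies the hazard (early / random / wear-out
   failure), and log-rank / Wilcoxon / Dunn subgroup comparisons.

A synthetic FAERS generator (`sim_config()`, `generate_faers_dataset()`)
emits quarter files with known planted association strengths, duplicates,
deletions, missingness and Weibull onset times, so every stage is testable
without external data. See the methods vignette
(`vignettes/faers-signal-detection.Rmd`) for the full model description.

## Worked example

Run the bundled synthetic study (20,000 reports, ~2,000 for the target
drug) end to end:

```r
library(faersignal)
res <- run_faers_analysis(run_config(seed = 1), out_dir = "orkambi_run")

res$cases
#> faers_cases: 19800 reports, 27743 PT records, 12 SOCs
#>   target-drug reports: 2025

sp <- res$screens$primary_pt
head(sp[sp$flagged, c("term", "n", "ror", "ror_low", "ic", "ic025")], 4)
#>                                                  term   n   ror ror_low    ic ic025
#> 1                                               Cough 467  2.38    2.13 0.921 0.768
#> 2                                     Hospitalisation 416  2.25    2.00 0.870 0.708
#> 3                                            Dyspnoea 357  2.35    2.07 0.923 0.749
#> 4 Infective pulmonary exacerbation of cystic fibrosis 251 40.51   29.06 2.614 2.406

res$priority[c(1, 2, 4), c("term", "n", "total", "category", "origin")]
#>                                                  term   n total category           origin
#> 1                                               Cough 467     3   medium         expected
#> 2                                     Hospitalisation 416     2      low disease_expected
#> 4 Infective pulmonary exacerbation of cystic fibrosis 251     3   medium         expected

res$tto$weibull
#> Weibull fit (n = 483): shape 0.811 (0.756-0.870), scale 392.9 d (349.9-441.2)
#> failure class: early
```

Reading this output: the dual-threshold screen flags the planted
associations (e.g. pulmonary exacerbation, ROR ≈ 41 with IC025 ≈ 2.4 — both
bounds far above their thresholds); hospitalisation is flagged for the
comparator drugs too and is therefore classified disease-expected rather
than drug-specific; and the fitted Weibull shape of 0.81 with CI entirely
below 1 classifies onset as early failure — adverse-event risk is highest in
the first months of therapy and declines thereafter (median onset 247 days,
IQR 78–592). `orkambi_run/` holds every result table as TSV plus
`manifest.json` with the filter-chain counts; rerunning with the same seed
reproduces the outputs byte for byte.

To analyse real FAERS data, point the config at a directory of quarterly
files and supply a PT→SOC mapping:

```r
cfg <- run_config(input = list(dir = "faers/", quarters = c("23Q1", "23Q2")),
                  pt_soc = read_pt_soc_map("pt2soc.tsv"))
run_faers_analysis(cfg, "orkambi_real")
```

A thin CLI (`inst/scripts/faersignal.R`) exposes the same entry points as
`run-all` and `simulate` subcommands.

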