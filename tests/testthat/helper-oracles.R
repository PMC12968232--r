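## Independent oracles and tiny fixture builders shared across tests.
## These deliberately avoid the package's own code paths wherever they are
## used to check one.

## Brute-force disproportionality recount: explicit per-term row loop over
## the record table, plus direct evaluation of the ROR / IC formulas.
oracle_screen <- function(records, target_ids, level = "pt") {
  vals <- records[[level]]
  is_t <- records$primaryid %in% target_ids
  terms <- sort(unique(vals[is_t]))
  rows <- lapply(terms, function(tm) {
    a <- 0L; b <- 0L; cc <- 0L; d <- 0L
    for (i in seq_along(vals)) {
      hit <- vals[i] == tm
      if (is_t[i] && hit) a <- a + 1L
      else if (is_t[i]) b <- b + 1L
      else if (hit) cc <- cc + 1L
      else d <- d + 1L
    }
    ror <- (a * d) / (b * cc)
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    e <- (a + b) * (a + cc) / (a + b + cc + d)
    ic <- log2((a + 0.5) / (e + 0.5))
    data.frame(term = tm, a = a, b = b, c = cc, d = d, ror = ror,
               ror_low = exp(log(ror) - qnorm(0.975) * se),
               ror_high = exp(log(ror) + qnorm(0.975) * se),
               ic = ic,
               ic025 = ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Hand risk-set computation of the two-group log-rank statistic on fully
## observed event times.
oracle_logrank2 <- function(a, b) {
  time <- c(a, b)
  grp <- rep(1:2, c(length(a), length(b)))
  o_a <- 0; e_a <- 0; v <- 0
  for (t in sort(unique(time))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp == 1)
    d <- sum(time == t)
    d_a <- sum(time == t & grp == 1)
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1) {
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
  }
  (o_a - e_a)^2 / v
}

## Small case container built directly (bypasses ingestion) for unit tests.
toy_cases <- function(reports, records, drugs = NULL, outcomes = NULL) {
  defaults <- data.frame(
    primaryid = reports$primaryid,
    caseid = reports$primaryid,
    age_yr = NA_real_, sex = NA_character_, weight_kg = NA_real_,
    reporter = NA_character_, country = NA_character_, year = NA_integer_,
    quarter = NA_character_, event_date = as.Date(NA),
    event_precision = "missing", start_date = as.Date(NA),
    start_precision = "missing", frequency = NA_character_,
    dose = NA_character_, indication = NA_character_, n_pts = 1L,
    fatal = FALSE, monotherapy = TRUE, is_target = FALSE,
    stringsAsFactors = FALSE
  )
  for (nm in setdiff(names(reports), "primaryid")) {
    defaults[[nm]] <- reports[[nm]]
  }
  if (!"soc" %in% names(records)) records$soc <- "UNMAPPED"
  if (is.null(drugs)) {
    drugs <- data.frame(primaryid = character(0), drug_seq = character(0),
                        role_cod = character(0), drugname = character(0),
                        drugname_norm = character(0), is_target = logical(0),
                        stringsAsFactors = FALSE)
  }
  if (is.null(outcomes)) {
    outcomes <- data.frame(primaryid = character(0),
                           outc_cod = character(0), stringsAsFactors = FALSE)
  }
  faers_cases(defaults, records, drugs, outcomes)
}

## Minimal screening container straight from simulate_reports() output,
## skipping the file round trip (used by the large calibration tests).
cases_from_sim <- function(sim) {
  tr <- sim$truth$reports
  reports <- data.frame(primaryid = tr$primaryid, caseid = tr$caseid,
                        sex = tr$sex, fatal = tr$fatal,
                        monotherapy = tr$monotherapy,
                        stringsAsFactors = FALSE)
  rec <- unique(sim$tables$reac[, c("primaryid", "pt")])
  rec <- rec[rec$primaryid %in% reports$primaryid, , drop = FALSE]
  rec$soc <- "UNMAPPED"
  toy_cases(reports, rec)
}

sim_target_ids <- function(sim, drug = "ORKAMBI") {
  sim$truth$reports$primaryid[sim$truth$reports$ps_drug == drug]
}

## fast single-quarter config for tests that do not need the full catalog
small_sim_config <- function(n_reports = 1500, ...) {
  sim_config(n_reports = n_reports, ...)
}
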