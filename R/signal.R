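## Disproportionality statistics on 2x2 contingency tables.  The counting
## unit throughout is the PT record — one row per (report, distinct PT) — so
## a report with several distinct reactions contributes one record per
## reaction and duplicate PTs within a report collapse to one record.

#' Build a 2x2 contingency table for a drug-event pair
#'
#' Cells partition all PT records: `a` = target-drug records of the term,
#' `b` = other target-drug records, `c` = the term under other drugs, `d` =
#' everything else.
#'
#' @param records PT-record table (`primaryid`, `pt`, `soc`), deduplicated.
#' @param target_ids primaryids of target-drug reports.
#' @param term the PT (or SOC) of interest.
#' @param level `"pt"` or `"soc"`: which column of `records` defines the
#'   term.
#' @return object of class `faers_2x2`: list with `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(records, target_ids, term,
                              level = c("pt", "soc")) {
  level <- match.arg(level)
  if (nrow(records) == 0L) stop("empty PT-record table")
  vals <- records[[level]]
  is_t <- records$primaryid %in% target_ids
  a <- sum(is_t & vals == term)
  b <- sum(is_t) - a
  cc <- sum(vals == term) - a
  d <- nrow(records) - a - b - cc
  structure(list(a = a, b = b, c = cc, d = d, n = nrow(records)),
            class = "faers_2x2")
}

#' @export
print.faers_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target event", "other events")))
  print(m)
  invisible(x)
}

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' `ROR = (a d)/(b c)` with the interval
#' `exp(log ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`.  When any cell is zero
#' the Haldane correction adds 0.5 to all four cells and the result is marked
#' `corrected`; with `correction = "none"` a zero `a` cell yields an
#' undefined-signal marker (`NA` estimates) rather than an error.
#'
#' @param a,b,c,d cell counts (vectors allowed, recycled together).
#' @param conf confidence level (default 0.95).
#' @param correction `"haldane"` (default) or `"none"`.
#' @return data frame with columns `ror`, `ror_low`, `ror_high`, `corrected`.
#' @export
ror_estimate <- function(a, b, c, d, conf = 0.95,
                         correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  z <- qnorm(1 - (1 - conf) / 2)
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  corrected <- zero & correction == "haldane"
  aa <- a + 0.5 * corrected; bb <- b + 0.5 * corrected
  cc <- c + 0.5 * corrected; dd <- d + 0.5 * corrected
  ror <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  out <- data.frame(ror = ror, ror_low = exp(log(ror) - z * se),
                    ror_high = exp(log(ror) + z * se),
                    corrected = corrected)
  undef <- zero & correction == "none"
  out[undef, c("ror", "ror_low", "ror_high")] <- NA_real_
  out
}

#' BCPNN information component with lower credibility bound
#'
#' Default shrinkage estimator: with expected count `E = (a+b)(a+c)/N`,
#' `IC = log2((a + 0.5)/(E + 0.5))` and
#' `IC025 = IC - 3.3 (a+0.5)^{-1/2} - 2 (a+0.5)^{-3/2}`, a credible-interval
#' approximation whose added 0.5 shrinks sparse cells toward independence.
#' `variant = "exact"` instead uses the original closed-form posterior
#' expectation and variance of the information component under the standard
#' Beta/Dirichlet priors, with `IC025 = E(IC) - 1.96 sd(IC)`.
#'
#' @param a,b,c,d cell counts (vectors allowed, recycled together).
#' @param variant `"shrinkage"` (default) or `"exact"`.
#' @return data frame with columns `ic` and `ic025` (bits).
#' @export
bcpnn_ic <- function(a, b, c, d, variant = c("shrinkage", "exact")) {
  variant <- match.arg(variant)
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  n <- a + b + c + d
  if (any(n <= 0)) stop("total count must be positive")
  if (variant == "shrinkage") {
    e <- (a + b) * (a + c) / n
    ic <- log2((a + 0.5) / (e + 0.5))
    ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  } else {
    ## closed-form posterior moments (gamma11 = alpha1 = beta1 = 1,
    ## alpha = beta = 2)
    a1 <- 1; b1 <- 1; g11 <- 1; al <- 2; be <- 2
    g <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
    eic <- log2((a + g11) * (n + al) * (n + be) /
                  ((n + g) * (a + b + a1) * (a + c + b1)))
    vic <- ((n - a + g - g11) / ((a + g11) * (1 + n + g)) +
              (n - a - b + al - a1) / ((a + b + a1) * (1 + n + al)) +
              (n - a - c + be - b1) / ((a + c + b1) * (1 + n + be))) /
      log(2)^2
    ic <- eic
    ic025 <- eic - 1.96 * sqrt(vic)
  }
  data.frame(ic = ic, ic025 = ic025)
}

#' Dual-threshold positive-signal rule
#'
#' A term is flagged as a positive signal only when it meets the frequentist
#' and the Bayesian criterion simultaneously: at least `min_cases` reports,
#' ROR 95% CI lower bound above 1, and IC025 above 0.
#'
#' @param n_cases number of target drug-event records (`a`).
#' @param ror_low ROR CI lower bound.
#' @param ic025 IC 2.5% bound.
#' @param min_cases minimum case count (default 3).
#' @return logical vector.
#' @export
flag_signal <- function(n_cases, ror_low, ic025, min_cases = 3) {
  !is.na(ror_low) & !is.na(ic025) &
    n_cases >= min_cases & ror_low > 1 & ic025 > 0
}

#' Screen every term for disproportionate reporting
#'
#' Builds the 2x2 table of each PT (or SOC) with at least one target-drug
#' record and evaluates ROR and BCPNN IC with the dual-threshold flag.
#'
#' @param cases a `faers_cases` object covering the whole database.
#' @param target_ids primaryids of the target-drug reports.
#' @param level `"pt"` or `"soc"`.
#' @param analysis_tag label recorded in the output (e.g. `"primary"`,
#'   `"monotherapy"`, `"comparator:KALYDECO"`).
#' @param min_cases,conf,correction,bcpnn_variant passed to the component
#'   estimators.
#' @return data frame sorted by `n` descending with columns `term`, `level`,
#'   `n`, `a`, `b`, `c`, `d`, `ror`, `ror_low`, `ror_high`, `ic`, `ic025`,
#'   `corrected`, `flagged`, `analysis_tag`.
#' @export
screen_signals <- function(cases, target_ids, level = c("pt", "soc"),
                           analysis_tag = "primary", min_cases = 3,
                           conf = 0.95, correction = "haldane",
                           bcpnn_variant = "shrinkage") {
  level <- match.arg(level)
  rec <- cases$records
  if (nrow(rec) == 0L) stop("empty PT-record table")
  if (length(target_ids) == 0L) stop("no target reports to screen")
  vals <- rec[[level]]
  is_t <- rec$primaryid %in% target_ids
  n_total <- nrow(rec)
  n_target <- sum(is_t)
  a_tab <- table(vals[is_t])
  terms <- names(a_tab)
  tot_tab <- table(vals)[terms]
  a <- as.numeric(a_tab)
  b <- n_target - a
  cc <- as.numeric(tot_tab) - a
  d <- n_total - n_target - cc
  ror <- ror_estimate(a, b, cc, d, conf = conf, correction = correction)
  ic <- bcpnn_ic(a, b, cc, d, variant = bcpnn_variant)
  out <- data.frame(term = terms, level = level, n = as.integer(a),
                    a = as.integer(a), b = as.integer(b), c = as.integer(cc),
                    d = as.integer(d), stringsAsFactors = FALSE)
  out <- cbind(out, ror, ic)
  out$flagged <- flag_signal(out$n, out$ror_low, out$ic025, min_cases)
  out$analysis_tag <- analysis_tag
  out <- out[order(-out$n, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict to monotherapy reports (concomitant-medication sensitivity)
#'
#' Removes target-drug reports that list any non-target medication, leaving
#' the background database untouched, so the screen can be re-run free of
#' concomitant-medication confounding.
#'
#' @param cases a `faers_cases` object.
#' @param target_ids primaryids of target-drug reports.
#' @return list with `cases` (filtered) and `target_ids` (monotherapy
#'   subset).
#' @export
restrict_monotherapy <- function(cases, target_ids) {
  rep_df <- cases$reports
  mono <- rep_df$primaryid[rep_df$monotherapy]
  keep_target <- intersect(target_ids, mono)
  drop <- setdiff(target_ids, keep_target)
  kept <- subset_cases(cases, setdiff(rep_df$primaryid, drop))
  list(cases = kept, target_ids = keep_target)
}

#' Re-screen with a comparator drug as target
#'
#' Re-runs report selection and screening with a same-indication comparator
#' (e.g. ivacaftor) in place of the study drug, used to judge whether a
#' signal tracks the disease rather than the drug.
#'
#' @param cases a `faers_cases` object.
#' @param comparator_synonyms synonym list for the comparator.
#' @param name label for the comparator (used in `analysis_tag`).
#' @param role drug role (default `"PS"`).
#' @param ... passed to [screen_signals()].
#' @return a signal table as from [screen_signals()]; zero rows (with a
#'   warning) when the comparator is absent from the data.
#' @export
comparator_screen <- function(cases, comparator_synonyms, name, role = "PS",
                              ...) {
  ids <- select_drug_reports(cases$drugs, comparator_synonyms, role = role)
  if (length(ids) == 0L) {
    warning("comparator ", name, " absent from data; empty result")
    out <- screen_signals(cases,
                          cases$reports$primaryid[1L], ...)[0L, , drop = FALSE]
    return(out)
  }
  screen_signals(cases, ids,
                 analysis_tag = paste0("comparator:", name), ...)
}
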