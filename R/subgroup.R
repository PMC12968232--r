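## Modified-ROR subgroup (volcano) analysis: within the target drug's
## reports, each term's 2x2 table contrasts two strata (e.g. males vs
## females): a = term records in group 1, b = other records in group 1,
## c = term records in group 2, d = other records in group 2.

## derive the stratum label per report for the supported stratifiers
stratum_values <- function(reports, stratum) {
  switch(stratum,
    sex = reports$sex,
    weight = cut(reports$weight_kg, c(0, 50, 100, Inf),
                 labels = c("<50", "50-100", ">100"), right = FALSE),
    age = cut(reports$age_yr, c(0, 2, 6, 12, 18, 66, Inf),
              labels = c("<2", "2-5", "6-11", "12-17", "18-65", ">65"),
              right = FALSE),
    frequency = reports$frequency,
    dose = reports$dose,
    fatal = ifelse(reports$fatal, "fatal", "non-fatal"),
    {
      if (!stratum %in% names(reports)) {
        stop("unknown stratum variable: ", stratum)
      }
      reports[[stratum]]
    }
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (a thin wrapper over
#' [stats::p.adjust()]); adjusted values are monotone after sorting and
#' capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Direction call for a subgroup signal
#'
#' A ROR CI lower bound above 1 with adjusted p below `alpha` marks a risk
#' signal in group 1; an upper bound below 1 with adjusted p below `alpha`
#' marks group 2; anything else is no call.
#'
#' @param ror_low,ror_high CI bounds (vectors).
#' @param p_adj adjusted p-values.
#' @param alpha significance level (default 0.05).
#' @return character vector: `"group1"`, `"group2"` or `"none"`.
#' @export
flag_direction <- function(ror_low, ror_high, p_adj, alpha = 0.05) {
  ifelse(!is.na(ror_low) & ror_low > 1 & p_adj < alpha, "group1",
         ifelse(!is.na(ror_high) & ror_high < 1 & p_adj < alpha, "group2",
                "none"))
}

#' Stratified modified-ROR screen
#'
#' For every PT with at least `min_cases` records in the two strata
#' combined, computes the subgroup ROR with Wald CI, a chi-square test
#' without continuity correction (Yates correction available via
#' `correct_chi`), Benjamini-Hochberg adjustment across the screen's terms,
#' and the direction call.  Records from reports with a missing stratum
#' value are excluded and counted in the `n_excluded_missing` attribute.
#'
#' @param cases a `faers_cases` object.
#' @param target_ids primaryids of target-drug reports.
#' @param stratum stratifier name: `"sex"`, `"weight"`, `"age"`,
#'   `"frequency"`, `"dose"`, `"fatal"`, or any column of `cases$reports`.
#' @param group1,group2 the two stratum labels to contrast.
#' @param min_cases minimum `a + c` for a term to be tested (default 3).
#' @param alpha significance level for the direction call.
#' @param correct_chi apply Yates continuity correction (default `FALSE`).
#' @param p_adjust `"BH"` (default) or `"bonferroni"`.
#' @return data frame with one row per tested term: the 2x2 cells, `ror`
#'   with CI, `log2_ror`, `chi2`, `p`, `p_adj`, `direction`.
#' @export
subgroup_screen <- function(cases, target_ids, stratum, group1, group2,
                            min_cases = 3, alpha = 0.05,
                            correct_chi = FALSE, p_adjust = "BH") {
  rep_df <- cases$reports[cases$reports$primaryid %in% target_ids, ,
                          drop = FALSE]
  sv <- as.character(stratum_values(rep_df, stratum))
  missing_strat <- is.na(sv) | !(sv %in% c(group1, group2))
  g1_ids <- rep_df$primaryid[!missing_strat & sv == group1]
  g2_ids <- rep_df$primaryid[!missing_strat & sv == group2]
  rec <- cases$records
  rec <- rec[rec$primaryid %in% c(g1_ids, g2_ids), , drop = FALSE]
  in1 <- rec$primaryid %in% g1_ids
  terms <- sort(unique(rec$pt))
  n1 <- sum(in1); n2 <- sum(!in1)
  a <- as.numeric(table(factor(rec$pt[in1], levels = terms)))
  ac <- as.numeric(table(factor(rec$pt, levels = terms)))
  keep <- ac >= min_cases
  terms <- terms[keep]; a <- a[keep]
  cc <- ac[keep] - a
  b <- n1 - a
  d <- n2 - cc
  ror <- ror_estimate(a, b, cc, d)
  chi <- vapply(seq_along(terms), function(i) {
    tab <- matrix(c(a[i], cc[i], b[i], d[i]), 2)
    ct <- suppressWarnings(chisq.test(tab, correct = correct_chi))
    c(unname(ct$statistic), ct$p.value)
  }, numeric(2))
  p <- if (length(terms)) chi[2L, ] else numeric(0)
  p_adj <- if (identical(p_adjust, "BH")) {
    benjamini_hochberg(p)
  } else {
    p.adjust(p, method = p_adjust)
  }
  out <- data.frame(term = terms, stratum = stratum, group1 = group1,
                    group2 = group2, a = as.integer(a), b = as.integer(b),
                    c = as.integer(cc), d = as.integer(d),
                    stringsAsFactors = FALSE)
  out <- cbind(out, ror)
  out$log2_ror <- log2(out$ror)
  out$chi2 <- if (length(terms)) chi[1L, ] else numeric(0)
  out$p <- p
  out$p_adj <- p_adj
  out$direction <- flag_direction(out$ror_low, out$ror_high, out$p_adj,
                                  alpha)
  out <- out[order(out$p_adj, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded_missing") <- sum(missing_strat)
  out
}
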