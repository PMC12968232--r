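## Clinical priority scoring and signal-origin classification for flagged
## disproportionality signals.

#' Score the clinical priority of a signal
#'
#' Four criteria, each worth 0-2 points: reporting rate (share of all target
#' drug PT records), magnitude of the ROR 95% CI lower bound, reported case
#' fatality rate, and clinical relevance (membership of the Designated /
#' Important Medical Events lists).  Band edges are upper-inclusive for the
#' middle band: rate >10% scores 2, 1-10% scores 1; ROR lower bound >5
#' scores 2, 2-5 scores 1; fatality >50% scores 2, 25-50% scores 1; DME
#' scores 2, IME 1.  Totals map to priority `low` (0-2), `medium` (3-5),
#' `high` (6-8).
#'
#' @param n_cases reports of the term (`a` cell); must be positive.
#' @param total_records total target-drug PT records.
#' @param ror_low ROR CI lower bound.
#' @param deaths reports of the term with a death outcome.
#' @param relevance `"DME"`, `"IME"` or `"none"` (vectorized).
#' @return data frame with the echoed inputs, the four point columns,
#'   `total` and `category`.
#' @export
score_priority <- function(n_cases, total_records, ror_low, deaths,
                           relevance = "none") {
  stopifnot(total_records > 0)
  len <- length(n_cases)
  deaths <- rep_len(deaths, len)
  ror_low <- rep_len(ror_low, len)
  relevance <- rep_len(relevance, len)
  if (any(n_cases <= 0)) stop("n_cases must be positive: nothing to score")
  if (any(deaths > n_cases)) stop("deaths cannot exceed n_cases")
  if (!all(relevance %in% c("DME", "IME", "none"))) {
    stop("relevance must be 'DME', 'IME' or 'none'")
  }
  rate <- n_cases / total_records
  cfr <- deaths / n_cases
  band3 <- function(x, hi, lo) ifelse(x > hi, 2L, ifelse(x >= lo, 1L, 0L))
  points_rate <- band3(rate, 0.10, 0.01)
  points_ror <- band3(ror_low, 5, 2)
  points_cfr <- band3(cfr, 0.50, 0.25)
  points_relevance <- ifelse(relevance == "DME", 2L,
                             ifelse(relevance == "IME", 1L, 0L))
  total <- points_rate + points_ror + points_cfr + points_relevance
  category <- cut(total, breaks = c(-1L, 2L, 5L, 8L),
                  labels = c("low", "medium", "high"))
  data.frame(reporting_rate = rate, ror_low = ror_low, cfr = cfr,
             relevance = relevance, points_rate = points_rate,
             points_ror = points_ror, points_cfr = points_cfr,
             points_relevance = points_relevance, total = total,
             category = as.character(category), stringsAsFactors = FALSE)
}

#' Classify the origin of a flagged signal
#'
#' A flagged term is `expected` when it appears in the drug label,
#' `disease_expected` when (not labelled but) flagged in every comparator
#' screen — all same-indication drugs meet the signal threshold, pointing at
#' the disease rather than the drug — and `unexpected` otherwise.  A term
#' missing from a comparator's results counts as not flagged there.
#'
#' @param terms character vector of flagged terms.
#' @param label_terms PTs listed in the drug label.
#' @param comparator_flags named list, one logical vector per comparator,
#'   each named by term (`TRUE` = flagged for that comparator).
#' @return data frame with `term`, `origin`
#'   (`expected`/`disease_expected`/`unexpected`) and `evidence`.
#' @export
classify_signal_origin <- function(terms, label_terms,
                                   comparator_flags = list()) {
  in_label <- terms %in% label_terms
  n_comp <- length(comparator_flags)
  if (n_comp > 0L) {
    flag_mat <- vapply(comparator_flags, function(fl) {
      v <- unname(fl[terms])
      v[is.na(v)] <- FALSE
      v
    }, logical(length(terms)))
    flag_mat <- matrix(flag_mat, nrow = length(terms))
    all_comp <- rowSums(flag_mat) == n_comp
  } else {
    all_comp <- rep(FALSE, length(terms))
  }
  origin <- ifelse(in_label, "expected",
                   ifelse(all_comp, "disease_expected", "unexpected"))
  evidence <- ifelse(in_label, "drug label",
                     ifelse(all_comp,
                            paste("flagged in all comparators:",
                                  paste(names(comparator_flags),
                                        collapse = ", ")),
                            "not labelled; not flagged in all comparators"))
  data.frame(term = terms, origin = origin, evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Score and classify all flagged signals of a primary screen
#'
#' Joins the primary signal table with death counts, the relevance lists and
#' the comparator screens into one priority table.
#'
#' @param signals primary PT-level signal table from [screen_signals()].
#' @param cases the `faers_cases` object (for death outcomes per term).
#' @param target_ids primaryids of target-drug reports.
#' @param label_terms,dme_terms,ime_terms user-supplied PT lists.
#' @param comparator_results named list of comparator signal tables.
#' @return data frame, one row per flagged term, with counts, points,
#'   `total`, `category`, `origin`.
#' @export
prioritize_signals <- function(signals, cases, target_ids,
                               label_terms = character(0),
                               dme_terms = character(0),
                               ime_terms = character(0),
                               comparator_results = list()) {
  sig <- signals[signals$flagged, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(term = character(0)))
  }
  total_records <- sig$a[1L] + sig$b[1L]  # a+b is constant across terms
  rec <- cases$records[cases$records$primaryid %in% target_ids, ,
                       drop = FALSE]
  fatal_ids <- cases$reports$primaryid[cases$reports$fatal]
  deaths <- vapply(sig$term, function(tm) {
    sum(unique(rec$primaryid[rec$pt == tm]) %in% fatal_ids)
  }, integer(1))
  relevance <- ifelse(sig$term %in% dme_terms, "DME",
                      ifelse(sig$term %in% ime_terms, "IME", "none"))
  sc <- score_priority(sig$n, total_records, sig$ror_low, deaths, relevance)
  comp_flags <- lapply(comparator_results, function(tab) {
    setNames(tab$flagged, tab$term)
  })
  org <- classify_signal_origin(sig$term, label_terms, comp_flags)
  out <- cbind(data.frame(term = sig$term, n = sig$n, deaths = deaths,
                          stringsAsFactors = FALSE),
               sc[, c("reporting_rate", "ror_low", "cfr", "relevance",
                      "points_rate", "points_ror", "points_cfr",
                      "points_relevance", "total", "category")],
               origin = org$origin)
  rownames(out) <- NULL
  out
}
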