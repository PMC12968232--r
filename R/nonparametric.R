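## Nonparametric subgroup comparisons for onset times.  FAERS onset samples
## are fully observed events (a spontaneous report exists because the event
## happened), so the log-rank statistic is computed without censoring.

#' k-group log-rank test on uncensored event times
#'
#' @param groups list of two or more non-empty numeric vectors of event
#'   times (all observed).
#' @return list with `chi2`, `df` (= k - 1) and `p`.
#' @export
logrank_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) stop("all groups must be non-empty")
  time <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  sd <- survdiff(Surv(time, rep(1, length(time))) ~ grp)
  df <- length(groups) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = pchisq(unname(sd$chisq), df, lower.tail = FALSE))
}

#' Wilcoxon rank-sum test
#'
#' Exact two-sided p when the smaller sample has at most 8 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with `statistic` (rank-sum W of `x`), `p` and `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Dunn's pairwise rank comparisons
#'
#' Post-hoc z tests on pooled mid-ranks after an omnibus comparison of
#' three or more groups, with the usual tie correction and
#' Benjamini-Hochberg adjustment across pairs.  Groups with fewer than two
#' observations are excluded with a warning.
#'
#' @param groups named list of three or more numeric vectors.
#' @param p_adjust adjustment method across pairs (default `"BH"`).
#' @return data frame `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_pairwise <- function(groups, p_adjust = "BH") {
  stopifnot(is.list(groups), length(groups) >= 3L)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  small <- lengths(groups) < 2L
  if (any(small)) {
    warning("excluding groups with fewer than 2 observations: ",
            paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
  }
  stopifnot(length(groups) >= 2L)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  n <- length(x)
  rk <- rank(x)                      # mid-ranks
  tie_sizes <- table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n - 1))
  mean_rank <- tapply(rk, g, mean)
  ni <- lengths(groups)[names(mean_rank)]
  pairs <- utils::combn(names(mean_rank), 2)
  z <- apply(pairs, 2, function(pr) {
    sdij <- sqrt((n * (n + 1) / 12 - tie_term) *
                   (1 / ni[pr[1]] + 1 / ni[pr[2]]))
    (mean_rank[pr[1]] - mean_rank[pr[2]]) / sdij
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = unname(z),
             p = unname(p),
             p_adj = unname(p.adjust(p, method = p_adjust)),
             stringsAsFactors = FALSE)
}
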