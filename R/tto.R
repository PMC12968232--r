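## Time-to-onset (TTO): days from therapy initiation to event occurrence,
## computed only from complete 8-digit date pairs, summarized in 30-day
## bins and per-SOC medians/IQRs, and modelled with a Weibull law whose
## shape parameter classifies the hazard as early / random / wear-out.

#' Compute time-to-onset samples
#'
#' `days = event_date - earliest target-drug therapy start`.  Reports are
#' excluded (with per-reason counts in the `exclusions` attribute) when
#' either date is missing or only partial, when the interval is
#' non-positive (same-day or event-before-start entries are implausible for
#' onset), or when it exceeds `cap_days` (default 9,125 d = 25 years).
#'
#' @param cases a `faers_cases` object.
#' @param target_ids primaryids to restrict to (default: all reports).
#' @param ime_terms optional PT list defining the IME stratum flag.
#' @param cap_days implausibility cap in days.
#' @return data frame, one row per valid report: `primaryid`, `days`, and
#'   stratum labels (`sex`, `age_group`, `weight_group`, `frequency`,
#'   `dose`, `fatal`, `ime`); attribute `exclusions` holds named counts.
#' @export
compute_tto <- function(cases, target_ids = NULL, ime_terms = NULL,
                        cap_days = 9125) {
  r <- cases$reports
  if (!is.null(target_ids)) {
    r <- r[r$primaryid %in% target_ids, , drop = FALSE]
  }
  days <- as.numeric(r$event_date - r$start_date)
  reason <- rep(NA_character_, nrow(r))
  reason[r$start_precision == "partial"] <- "partial_start"
  reason[r$start_precision %in% c("missing", "invalid")] <- "missing_start"
  ev_bad <- is.na(reason)
  reason[ev_bad & r$event_precision == "partial"] <- "partial_event"
  reason[ev_bad & r$event_precision %in% c("missing", "invalid")] <-
    "missing_event"
  ok_dates <- is.na(reason)
  reason[ok_dates & days <= 0] <- "nonpositive"
  reason[ok_dates & days > cap_days] <- "implausible"
  valid <- is.na(reason)

  rv <- r[valid, , drop = FALSE]
  ime <- if (is.null(ime_terms)) {
    rep(NA, nrow(rv))
  } else {
    rec <- cases$records
    rv$primaryid %in% rec$primaryid[rec$pt %in% ime_terms]
  }
  out <- data.frame(
    primaryid = rv$primaryid,
    days = as.integer(days[valid]),
    sex = rv$sex,
    age_group = as.character(cut(rv$age_yr, c(0, 2, 6, 12, 18, 66, Inf),
                                 labels = c("<2", "2-5", "6-11", "12-17",
                                            "18-65", ">65"), right = FALSE)),
    weight_group = as.character(cut(rv$weight_kg, c(0, 50, 100, Inf),
                                    labels = c("<50", "50-100", ">100"),
                                    right = FALSE)),
    frequency = rv$frequency,
    dose = rv$dose,
    fatal = rv$fatal,
    ime = ime,
    stringsAsFactors = FALSE
  )
  attr(out, "exclusions") <- c(table(reason))
  attr(out, "n_input") <- nrow(r)
  out
}

#' Bin onset days into 30-day intervals
#'
#' Intervals `1-30`, `31-60`, ..., `331-360` and `>360`.
#'
#' @param days positive integer vector.
#' @return character vector of interval labels.
#' @export
bin_tto <- function(days) {
  stopifnot(all(days >= 1))
  labels <- paste(seq(1, 331, 30), seq(30, 360, 30), sep = "-")
  idx <- pmin(ceiling(days / 30), 13)
  c(labels, ">360")[idx]
}

#' Tabulate binned onset intervals
#'
#' @param days positive integer vector of onset days.
#' @return data frame `interval`, `n`, `percent` (over all samples), in
#'   chronological order — the plot-ready butterfly table.
#' @export
tto_bin_table <- function(days) {
  labels <- c(paste(seq(1, 331, 30), seq(30, 360, 30), sep = "-"), ">360")
  n <- as.integer(table(factor(bin_tto(days), levels = labels)))
  data.frame(interval = labels, n = n, percent = 100 * n / length(days),
             stringsAsFactors = FALSE)
}

weibull_negloglik <- function(logpar, x) {
  k <- exp(logpar[1L]); lam <- exp(logpar[2L])
  -sum(log(k / lam) + (k - 1) * log(x / lam) - (x / lam)^k)
}

#' Fit a Weibull distribution to onset intervals
#'
#' Maximum likelihood via Newton iteration on the profile score for the
#' shape (the scale has a closed form given the shape); 95% confidence
#' intervals come from the observed information on the log-parameter scale,
#' exponentiated back.  The shape's CI drives the failure-type
#' classification (see [classify_failure()]).
#'
#' @param x positive onset intervals (days); at least 10 values, not all
#'   identical.
#' @param conf confidence level (default 0.95).
#' @return object of class `weibull_fit`: `shape`, `scale`, `shape_ci`,
#'   `scale_ci`, `loglik`, `n`, `failure_class`.
#' @export
weibull_fit <- function(x, conf = 0.95) {
  x <- as.numeric(x)
  stopifnot(all(is.finite(x)), all(x > 0))
  if (length(x) < 10L) stop("need at least 10 onset values")
  if (length(unique(x)) < 2L) stop("degenerate sample: all values identical")
  lx <- log(x)
  mlx <- mean(lx)
  ## profile score g(k) = sum(x^k log x)/sum(x^k) - 1/k - mean(log x)
  g <- function(k) {
    xk <- x^k
    sum(xk * lx) / sum(xk) - 1 / k - mlx
  }
  k <- 1.2 / stats::sd(lx)      # moment-style start
  converged <- FALSE
  for (it in 1:50) {
    xk <- x^k
    s0 <- sum(xk); s1 <- sum(xk * lx); s2 <- sum(xk * lx^2)
    gk <- s1 / s0 - 1 / k - mlx
    dgk <- (s2 * s0 - s1^2) / s0^2 + 1 / k^2
    step <- gk / dgk
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-12 * max(1, k)) {
      k <- k_new
      converged <- TRUE
      break
    }
    k <- k_new
  }
  if (!converged && abs(g(k)) > 1e-6) {
    ## fall back to bracketing before declaring failure
    br <- try(uniroot(g, c(1e-3, 1e3), tol = 1e-12), silent = TRUE)
    if (inherits(br, "try-error")) {
      stop("Weibull shape iteration failed to converge; last shape = ",
           signif(k, 6), ", score = ", signif(g(k), 6))
    }
    k <- br$root
  }
  lam <- mean(x^k)^(1 / k)
  lp <- c(log(k), log(lam))
  ll <- -weibull_negloglik(lp, x)
  h <- optimHess(lp, weibull_negloglik, x = x)
  vc <- solve(h)
  se <- sqrt(diag(vc))
  z <- qnorm(1 - (1 - conf) / 2)
  shape_ci <- exp(lp[1L] + c(-1, 1) * z * se[1L])
  scale_ci <- exp(lp[2L] + c(-1, 1) * z * se[2L])
  fit <- structure(list(shape = k, scale = lam, shape_ci = shape_ci,
                        scale_ci = scale_ci, se_log = se, loglik = ll,
                        n = length(x), conf = conf),
                   class = "weibull_fit")
  fit$failure_class <- classify_failure(fit)
  fit
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "Weibull fit (n = %d): shape %.3f (%.3f-%.3f), scale %.1f d (%.1f-%.1f)\n",
    x$n, x$shape, x$shape_ci[1], x$shape_ci[2], x$scale, x$scale_ci[1],
    x$scale_ci[2]))
  cat("failure class:", x$failure_class, "\n")
  invisible(x)
}

#' Classify the hazard pattern from the Weibull shape CI
#'
#' `early` failure when the shape CI upper bound is below 1 (decreasing
#' hazard: events concentrate early in therapy), `wearout` when the lower
#' bound exceeds 1 (increasing hazard), `random` when the CI contains 1
#' (roughly constant hazard).
#'
#' @param fit a `weibull_fit`, or a length-2 numeric CI.
#' @return `"early"`, `"random"` or `"wearout"`.
#' @export
classify_failure <- function(fit) {
  ci <- if (inherits(fit, "weibull_fit")) fit$shape_ci else as.numeric(fit)
  stopifnot(length(ci) == 2L, all(ci > 0), ci[1L] <= ci[2L])
  if (ci[2L] < 1) "early" else if (ci[1L] > 1) "wearout" else "random"
}

#' Per-SOC time-to-onset summary
#'
#' A sample contributes to every SOC its report's PTs map to; medians use
#' the midpoint convention for even counts, quartiles the default
#' [stats::quantile()] type.  SOCs with no samples are omitted.
#'
#' @param tto TTO sample table from [compute_tto()].
#' @param cases the `faers_cases` object providing the PT record SOCs.
#' @return data frame `soc`, `n`, `median`, `q1`, `q3`, sorted by `n`
#'   descending.
#' @export
soc_tto_summary <- function(tto, cases) {
  rec <- unique(cases$records[cases$records$primaryid %in% tto$primaryid,
                              c("primaryid", "soc")])
  rec$days <- tto$days[match(rec$primaryid, tto$primaryid)]
  if (nrow(rec) == 0L) {
    return(data.frame(soc = character(0), n = integer(0),
                      median = numeric(0), q1 = numeric(0),
                      q3 = numeric(0)))
  }
  out <- do.call(rbind, lapply(split(rec$days, rec$soc), function(dd) {
    data.frame(n = length(dd), median = median(dd),
               q1 = unname(quantile(dd, 0.25)),
               q3 = unname(quantile(dd, 0.75)))
  }))
  out <- data.frame(soc = rownames(out), out, stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$soc), , drop = FALSE]
  rownames(out) <- NULL
  out
}
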