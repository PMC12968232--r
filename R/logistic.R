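## Logistic regression for reporting-risk factors (e.g. which report
## characteristics predict that a report mentions depression).

#' Fit a logistic regression by maximum likelihood
#'
#' Binomial GLM fitted by iteratively reweighted least squares
#' ([stats::glm.fit()], 50 iterations), with Wald odds-ratio confidence
#' intervals `exp(coef +/- z SE)`.  Non-convergence raises an error with the
#' coefficient trace; complete separation (diverging coefficients together
#' with fitted probabilities pinned at 0/1) raises an explicit error rather
#' than returning a silently unstable fit.
#'
#' @param x design matrix including an intercept column.
#' @param y binary outcome vector (0/1), both levels present.
#' @param conf confidence level (default 0.95).
#' @return object of class `logistic_fit`: list with `coef`, `se`, `or`,
#'   `or_low`, `or_high`, `p`, `loglik`, `converged`, `n`.
#' @export
fit_logistic <- function(x, y, conf = 0.95) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L) stop("degenerate outcome: only one level")
  if (nrow(x) < ncol(x)) stop("fewer observations than parameters")
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  fit <- suppressWarnings(
    glm.fit(x, y, family = binomial(),
            control = glm.control(maxit = 50))
  )
  cf <- fit$coefficients
  if (!fit$converged) {
    stop("logistic fit did not converge in 50 iterations; coefficients: ",
         paste(signif(cf, 4), collapse = ", "))
  }
  mu <- fit$fitted.values
  pinned <- mu < 1e-8 | mu > 1 - 1e-8
  if (any(abs(cf) > 15) && any(pinned)) {
    stop("complete or quasi-complete separation detected ",
         "(diverging coefficients with fitted probabilities at 0/1)")
  }
  p <- length(cf)
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(diag(covmat))
  z <- qnorm(1 - (1 - conf) / 2)
  wald <- cf / se
  loglik <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  structure(list(coef = cf, se = se, or = exp(cf),
                 or_low = exp(cf - z * se), or_high = exp(cf + z * se),
                 p = 2 * pnorm(-abs(wald)), loglik = loglik,
                 converged = fit$converged, n = nrow(x)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: n = %d, logLik = %.2f\n", x$n, x$loglik))
  print(data.frame(coef = round(x$coef, 4), or = round(x$or, 3),
                   or_low = round(x$or_low, 3),
                   or_high = round(x$or_high, 3),
                   p = signif(x$p, 3)))
  invisible(x)
}

## default covariate set: reference levels mirror the depression risk-factor
## model (female, health-professional, US, BID, 18-65, non-monotherapy)
default_regression_covariates <- function() {
  list(
    age = list(values = function(r) {
      ifelse(is.na(r$age_yr), NA,
             ifelse(r$age_yr < 18, "<18",
                    ifelse(r$age_yr <= 65, "18-65", NA)))
    }, reference = "18-65"),
    sex = list(values = function(r) {
      ifelse(r$sex %in% c("F", "M"),
             ifelse(r$sex == "M", "Male", "Female"), NA)
    }, reference = "Female"),
    reporter = list(values = function(r) {
      ifelse(is.na(r$reporter), NA,
             ifelse(r$reporter == "CN", "Consumer", "Health professional"))
    }, reference = "Health professional"),
    country = list(values = function(r) {
      ifelse(is.na(r$country), NA,
             ifelse(r$country == "US", "United States", "Others"))
    }, reference = "United States"),
    frequency = list(values = function(r) r$frequency, reference = "BID"),
    monotherapy = list(values = function(r) {
      ifelse(r$monotherapy, "Yes", "No")
    }, reference = "No")
  )
}

#' Univariate then multivariate logistic risk-factor workflow
#'
#' The outcome is 1 when a target-drug report mentions `outcome_pt`.
#' Complete-case analysis: reports missing any candidate covariate are
#' dropped (count reported in the result).  Each covariate is first fitted
#' alone; those with Wald `p < alpha_enter` enter the multivariate model.
#' Covariates left with a single level after filtering are dropped with a
#' warning.
#'
#' @param cases a `faers_cases` object.
#' @param target_ids primaryids of target-drug reports.
#' @param outcome_pt the PT defining the outcome (must occur in the data).
#' @param covariates named list of covariate definitions (`values`
#'   function + `reference` level); defaults mirror the depression model.
#' @param alpha_enter univariate inclusion threshold (default 0.05).
#' @return list with `n_used`, `n_dropped`, `outcome_n`, `univariate` (data
#'   frame: covariate, level, reference, n, or, ci, p), `multivariate` (a
#'   `logistic_fit` or `NULL`), `entered` (covariates in the multivariate
#'   model).
#' @export
regression_workflow <- function(cases, target_ids, outcome_pt,
                                covariates = default_regression_covariates(),
                                alpha_enter = 0.05) {
  rec <- cases$records
  if (!outcome_pt %in% rec$pt) {
    stop("outcome PT not present in the data: ", outcome_pt)
  }
  r <- cases$reports[cases$reports$primaryid %in% target_ids, , drop = FALSE]
  vals <- lapply(covariates, function(cv) as.character(cv$values(r)))
  keep <- Reduce(`&`, lapply(vals, function(v) !is.na(v) & v != ""))
  n_dropped <- sum(!keep)
  r <- r[keep, , drop = FALSE]
  vals <- lapply(vals, function(v) v[keep])
  y <- as.numeric(r$primaryid %in% rec$primaryid[rec$pt == outcome_pt])
  if (sum(y) == 0L || sum(y) == length(y)) {
    stop("outcome is constant among complete-case target reports")
  }

  one_hot <- function(v, ref) {
    lev <- setdiff(sort(unique(v)), ref)
    m <- vapply(lev, function(l) as.numeric(v == l),
                numeric(length(v)))
    m <- matrix(m, ncol = length(lev),
                dimnames = list(NULL, lev))
    m
  }

  uni <- list()
  usable <- character(0)
  for (nm in names(covariates)) {
    v <- vals[[nm]]
    ref <- covariates[[nm]]$reference
    if (length(unique(v)) < 2L) {
      warning("covariate '", nm, "' has a single level after filtering; ",
              "dropped")
      next
    }
    m <- one_hot(v, ref)
    fit <- tryCatch(fit_logistic(cbind(`(Intercept)` = 1, m), y),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      ## separation or non-convergence is reported per covariate (NA
      ## estimates), never resolved silently, and excluded downstream
      warning("covariate '", nm, "' not estimable: ",
              conditionMessage(fit))
      uni[[nm]] <- data.frame(
        covariate = nm, level = colnames(m), reference = ref,
        n = as.integer(table(v)[colnames(m)]),
        or = NA_real_, or_low = NA_real_, or_high = NA_real_, p = NA_real_,
        stringsAsFactors = FALSE
      )
      next
    }
    idx <- seq_len(ncol(m)) + 1L
    uni[[nm]] <- data.frame(
      covariate = nm, level = colnames(m), reference = ref,
      n = as.integer(table(v)[colnames(m)]),
      or = fit$or[idx], or_low = fit$or_low[idx], or_high = fit$or_high[idx],
      p = fit$p[idx], stringsAsFactors = FALSE
    )
    usable <- c(usable, nm)
  }
  univariate <- do.call(rbind, uni)
  rownames(univariate) <- NULL

  entered <- usable[vapply(usable,
                           function(nm) any(uni[[nm]]$p < alpha_enter),
                           logical(1))]
  multivariate <- NULL
  if (length(entered)) {
    mm <- do.call(cbind, lapply(entered, function(nm) {
      m <- one_hot(vals[[nm]], covariates[[nm]]$reference)
      colnames(m) <- paste(nm, colnames(m), sep = ":")
      m
    }))
    multivariate <- fit_logistic(cbind(`(Intercept)` = 1, mm), y)
  } else {
    message("no covariate passed the univariate screen; ",
            "multivariate model skipped")
  }
  list(n_used = length(y), n_dropped = n_dropped, outcome_n = sum(y),
       univariate = univariate, multivariate = multivariate,
       entered = entered)
}
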