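test_that("Benjamini-Hochberg adjustment matches the step-up hand computation", {
  expect_equal(benjamini_hochberg(0.02), 0.02)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(numeric(0)), numeric(0))
  set.seed(3)
  p <- runif(40)
  expect_true(all(benjamini_hochberg(p) >= p))
})

test_that("direction calls follow the CI-bound plus adjusted-p rule", {
  ## chest-discomfort style signal: CI fully below 1, significant -> group 2
  expect_equal(flag_direction(0.14, 0.50, 0.001), "group2")
  expect_equal(flag_direction(0.8, 1.3, 0.001), "none")   # CI spans 1
  expect_equal(flag_direction(1.2, 2.0, 0.2), "none")     # fails alpha
  expect_equal(flag_direction(1.2, 2.0, 0.01), "group1")
  expect_equal(flag_direction(c(1.2, 0.5), c(2, 0.9), c(0.01, 0.01)),
               c("group1", "group2"))
})

test_that("the subgroup screen shares the ROR code path and matches chisq.test", {
  set.seed(9)
  n <- 600
  rep_df <- data.frame(primaryid = as.character(seq_len(n)),
                       sex = sample(c("M", "F", NA), n, TRUE,
                                    prob = c(0.45, 0.45, 0.1)),
                       stringsAsFactors = FALSE)
  ## plant a female-enriched term
  p_term <- ifelse(rep_df$sex %in% "F", 0.25, 0.05)
  rows <- list(data.frame(primaryid = rep_df$primaryid, pt = "Background",
                          stringsAsFactors = FALSE))
  hit <- runif(n) < p_term
  rows[[2]] <- data.frame(primaryid = rep_df$primaryid[hit],
                          pt = "PlantedFem", stringsAsFactors = FALSE)
  rec <- do.call(rbind, rows)
  rec$soc <- "S"
  cases <- toy_cases(rep_df, rec)
  out <- subgroup_screen(cases, rep_df$primaryid, "sex", "M", "F")
  pl <- out[out$term == "PlantedFem", ]
  expect_equal(pl$direction, "group2")
  ## shared code path with ror_estimate
  expect_equal(pl[, c("ror", "ror_low", "ror_high")],
               ror_estimate(pl$a, pl$b, pl$c, pl$d)[, c("ror", "ror_low",
                                                        "ror_high")],
               ignore_attr = TRUE)
  ## chi-square equals the stock test without continuity correction
  ct <- suppressWarnings(
    chisq.test(matrix(c(pl$a, pl$c, pl$b, pl$d), 2), correct = FALSE))
  expect_equal(pl$chi2, unname(ct$statistic))
  expect_equal(pl$p, ct$p.value)
  expect_true(all(out$p_adj >= out$p))
  ## records under reports with missing stratum are excluded and counted
  expect_equal(attr(out, "n_excluded_missing"), sum(is.na(rep_df$sex)))
})

test_that("a hand-computed subgroup table gives ROR 0.211", {
  rep_df <- data.frame(primaryid = as.character(1:200),
                       grp = rep(c("g1", "g2"), each = 100),
                       stringsAsFactors = FALSE)
  term <- c(rep(c("T", "O"), c(5, 95)), rep(c("T", "O"), c(20, 80)))
  rec <- data.frame(primaryid = rep_df$primaryid, pt = term, soc = "S",
                    stringsAsFactors = FALSE)
  cases <- toy_cases(rep_df, rec)
  out <- subgroup_screen(cases, rep_df$primaryid, "grp", "g1", "g2")
  tt <- out[out$term == "T", ]
  expect_equal(unlist(tt[c("a", "b", "c", "d")]),
               c(a = 5, b = 95, c = 20, d = 80))
  expect_equal(tt$ror, (5 * 80) / (95 * 20), tolerance = 1e-12)
  expect_equal(round(tt$ror, 3), 0.211)
})

test_that("equal proportions in both strata give ROR 1 and no direction", {
  rep_df <- data.frame(primaryid = as.character(1:200),
                       grp = rep(c("g1", "g2"), each = 100),
                       stringsAsFactors = FALSE)
  term <- rep(rep(c("E", "O"), c(10, 90)), 2)
  rec <- data.frame(primaryid = rep_df$primaryid, pt = term, soc = "S",
                    stringsAsFactors = FALSE)
  cases <- toy_cases(rep_df, rec)
  out <- subgroup_screen(cases, rep_df$primaryid, "grp", "g1", "g2")
  ee <- out[out$term == "E", ]
  expect_equal(ee$ror, 1)
  expect_equal(ee$direction, "none")
})

test_that("the saturated logistic fit reproduces ln(ad/bc)", {
  ## outcome x covariate counts (10, 90; 5, 95)
  x1 <- c(rep(1, 100), rep(0, 100))
  y <- c(rep(1, 10), rep(0, 90), rep(1, 5), rep(0, 95))
  fit <- fit_logistic(cbind(1, x1), y)
  expect_equal(unname(fit$coef[2]), log((10 * 95) / (90 * 5)),
               tolerance = 1e-6)
  expect_equal(unname(fit$or[2]), 2.111, tolerance = 1e-3)
  ## Wald CI structure
  expect_true(fit$or_low[2] < fit$or[2] && fit$or[2] < fit$or_high[2])
})

test_that("degenerate and separated logistic designs raise explicit errors", {
  x <- cbind(1, c(rep(0, 10), rep(1, 10)))
  expect_error(fit_logistic(x, rep(0, 20)), "one level")
  expect_error(fit_logistic(matrix(1, 2, 3), c(0, 1)), "fewer observations")
  ## complete separation: covariate perfectly predicts outcome
  xx <- cbind(1, c(rep(0, 20), rep(1, 20)))
  yy <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_logistic(xx, yy), "separation")
})

test_that("regression workflow screens univariately, then fits jointly", {
  set.seed(77)
  n <- 3000
  sex <- sample(c("F", "M"), n, TRUE)
  age <- runif(n, 5, 60)
  rep_df <- data.frame(
    primaryid = as.character(seq_len(n)), sex = sex, age_yr = age,
    reporter = sample(c("CN", "MD"), n, TRUE),
    country = sample(c("US", "FR"), n, TRUE, prob = c(0.9, 0.1)),
    frequency = sample(c("BID", "QD"), n, TRUE, prob = c(0.95, 0.05)),
    monotherapy = sample(c(TRUE, FALSE), n, TRUE),
    stringsAsFactors = FALSE
  )
  ## only sex truly drives the outcome
  p <- plogis(-2.6 - 1.49 * (sex == "M"))
  hit <- runif(n) < p
  rec <- data.frame(primaryid = rep_df$primaryid,
                    pt = ifelse(hit, "Depression", "Other"), soc = "S",
                    stringsAsFactors = FALSE)
  cases <- toy_cases(rep_df, rec)
  wf <- regression_workflow(cases, rep_df$primaryid, "Depression")
  expect_equal(wf$n_used, n)   # no missing covariates here
  expect_true("sex" %in% wf$entered)
  sex_row <- wf$univariate[wf$univariate$covariate == "sex", ]
  expect_lt(sex_row$or, 0.5)
  expect_lt(sex_row$p, 0.001)
  mv <- wf$multivariate
  expect_s3_class(mv, "logistic_fit")
  expect_lt(abs(mv$coef[grep("Male", names(mv$coef))] + 1.49), 0.6)
  ## outcome absent -> error
  expect_error(regression_workflow(cases, rep_df$primaryid, "NoSuchPT"),
               "not present")
  ## single-level covariate is dropped with a warning
  rep_df2 <- rep_df
  rep_df2$frequency <- "BID"
  cases2 <- toy_cases(rep_df2, rec)
  expect_warning(regression_workflow(cases2, rep_df2$primaryid,
                                     "Depression"),
                 "single level")
})
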