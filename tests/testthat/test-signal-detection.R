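test_that("the 2x2 cells partition the record table", {
  rec <- data.frame(primaryid = c("1", "1", "2", "2"),
                    pt = c("p", "q", "p", "q"), soc = "S",
                    stringsAsFactors = FALSE)
  t1 <- build_contingency(rec, "1", "p")
  expect_equal(unlist(t1[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))
  expect_error(build_contingency(rec[0, ], "1", "p"), "empty")
})

test_that("ROR point estimate and Wald interval match hand arithmetic", {
  r1 <- ror_estimate(10, 10, 10, 10)
  expect_equal(r1$ror, 1)
  expect_equal(log(r1$ror_high), -log(r1$ror_low))  # symmetric on log scale

  r2 <- ror_estimate(20, 80, 100, 800)
  expect_equal(r2$ror, 2.000, tolerance = 1e-12)
  expect_equal(r2$ror_low, exp(log(2) - qnorm(0.975) * sqrt(0.07375)),
               tolerance = 1e-12)
  expect_equal(round(c(r2$ror_low, r2$ror_high), 2), c(1.17, 3.41))
  expect_false(r2$corrected)
})

test_that("zero cells get the Haldane correction or an undefined marker", {
  rc <- ror_estimate(0, 10, 10, 100)
  expect_true(rc$corrected)
  expect_equal(rc$ror, (0.5 * 100.5) / (10.5 * 10.5))
  rn <- ror_estimate(0, 10, 10, 100, correction = "none")
  expect_true(is.na(rn$ror))
  expect_false(rn$corrected)
})

test_that("the reciprocal and monotonicity invariants hold for the ROR", {
  set.seed(1)
  for (i in 1:25) {
    cells <- sample(1:200, 4, replace = TRUE)
    fwd <- ror_estimate(cells[1], cells[2], cells[3], cells[4])
    swp <- ror_estimate(cells[3], cells[4], cells[1], cells[2])
    expect_equal(fwd$ror, 1 / swp$ror, tolerance = 1e-12)
  }
  base <- ror_estimate(5:30, 50, 60, 500)
  expect_true(all(diff(base$ror) > 0))
  ics <- bcpnn_ic(5:30, 50, 60, 500)
  expect_true(all(diff(ics$ic) > 0))
})

test_that("the shrinkage information component matches the stated formulas", {
  u <- bcpnn_ic(10, 10, 10, 10)
  expect_equal(u$ic, 0)            # uniform table: observed equals expected
  v <- bcpnn_ic(20, 80, 100, 800)  # N = 1000, a+b = 100, a+c = 120, E = 12
  expect_equal(v$ic, log2(20.5 / 12.5), tolerance = 1e-12)
  expect_equal(v$ic025,
               log2(20.5 / 12.5) - 3.3 / sqrt(20.5) - 2 / 20.5^1.5,
               tolerance = 1e-12)
  expect_equal(round(v$ic, 3), 0.714)
  expect_equal(round(v$ic025, 3), -0.037)
  ## ic025 < ic always (positive subtracted terms)
  set.seed(2)
  ab <- matrix(sample(1:500, 80, replace = TRUE), ncol = 4)
  w <- bcpnn_ic(ab[, 1], ab[, 2], ab[, 3], ab[, 4])
  expect_true(all(w$ic025 < w$ic))
  ## exact-variance variant: shrunk toward 0, bound below the point value
  ex <- bcpnn_ic(20, 80, 100, 800, variant = "exact")
  expect_lt(ex$ic025, ex$ic)
  expect_lt(abs(ex$ic - v$ic), 0.2)
})

test_that("the dual-threshold rule requires count, ROR bound and IC bound", {
  expect_true(flag_signal(81, 1.37, 0.45))
  expect_false(flag_signal(81, 0.99, 0.5))
  expect_false(flag_signal(2, 1.37, 0.45))    # below min_cases
  expect_true(flag_signal(2, 1.37, 0.45, min_cases = 2))
  expect_false(flag_signal(10, 1.37, -0.01))
})

test_that("screen_signals equals a brute-force per-term recount", {
  cfg <- small_sim_config(n_reports = 900, duplicate_fraction = 0,
                          deleted_fraction = 0)
  sim <- simulate_reports(cfg, seed = 31)
  cases <- cases_from_sim(sim)
  tgt <- sim_target_ids(sim)
  got <- screen_signals(cases, tgt, level = "pt")
  want <- oracle_screen(cases$records, tgt)
  got <- got[match(want$term, got$term), ]
  expect_equal(got$a, want$a)
  expect_equal(got$b, want$b)
  expect_equal(got$c, want$c)
  expect_equal(got$d, want$d)
  ok <- !got$corrected
  expect_equal(got$ror[ok], want$ror[ok], tolerance = 1e-9)
  expect_equal(got$ror_low[ok], want$ror_low[ok], tolerance = 1e-9)
  expect_equal(got$ic, want$ic, tolerance = 1e-9)
  expect_equal(got$ic025, want$ic025, tolerance = 1e-9)
  ## cell conservation for every term
  expect_true(all(got$a + got$b + got$c + got$d == nrow(cases$records)))
  ## sorted by case count
  full <- screen_signals(cases, tgt, level = "pt")
  expect_true(all(diff(full$n) <= 0))
})

test_that("SOC-level screening counts PT records grouped by organ class", {
  rec <- data.frame(primaryid = c("1", "1", "2", "3", "3"),
                    pt = c("p", "q", "p", "r", "q"),
                    soc = c("A", "A", "A", "B", "A"),
                    stringsAsFactors = FALSE)
  rep_df <- data.frame(primaryid = c("1", "2", "3"))
  cases <- toy_cases(rep_df, rec)
  tab <- screen_signals(cases, "1", level = "soc", min_cases = 1)
  expect_lte(nrow(tab), 2L)
  ## report 1 has two PTs in SOC A: both records count
  expect_equal(tab$a[tab$term == "A"], 2L)
  t2 <- build_contingency(rec, "1", "A", level = "soc")
  expect_equal(t2$a, 2L)
  expect_equal(t2$n, 5L)
})

test_that("monotherapy restriction drops co-medicated target reports only", {
  drugs <- data.frame(
    primaryid = c("1", "2", "2", "3"),
    drug_seq = "1", role_cod = "PS",
    drugname = c("ORKAMBI", "ORKAMBI", "PULMOZYME", "OTHER"),
    stringsAsFactors = FALSE
  )
  drugs$drugname_norm <- normalize_drug_name(drugs$drugname)
  drugs$is_target <- drugs$drugname_norm == "ORKAMBI"
  rep_df <- data.frame(primaryid = c("1", "2", "3"),
                       monotherapy = c(TRUE, FALSE, TRUE))
  rec <- data.frame(primaryid = c("1", "2", "3"), pt = "p", soc = "S")
  cases <- toy_cases(rep_df, rec, drugs = drugs)
  mono <- restrict_monotherapy(cases, c("1", "2"))
  expect_equal(mono$target_ids, "1")
  expect_setequal(mono$cases$reports$primaryid, c("1", "3"))
})

test_that("comparator screens rediscover shared signals and miss target-only ones", {
  cfg <- sim_config(n_reports = 12000)
  sim <- simulate_reports(cfg, seed = 44)
  cases <- cases_from_sim(sim)
  ## comparator equal to the target reproduces the primary screen
  tgt <- sim_target_ids(sim)
  prim <- screen_signals(cases, tgt)
  drugs <- data.frame(primaryid = sim$truth$reports$primaryid,
                      drug_seq = "1", role_cod = "PS",
                      drugname = sim$truth$reports$ps_drug,
                      stringsAsFactors = FALSE)
  drugs$drugname_norm <- normalize_drug_name(drugs$drugname)
  drugs$is_target <- drugs$drugname_norm == "ORKAMBI"
  cases$drugs <- drugs
  same <- comparator_screen(cases, "ORKAMBI", "self")
  expect_equal(same[order(same$term), c("a", "b", "c", "d", "ror", "ic025")],
               prim[order(prim$term), c("a", "b", "c", "d", "ror", "ic025")])
  ## the shared disease-linked signal flags for a comparator too
  kaly <- comparator_screen(cases, "KALYDECO", "KALYDECO")
  expect_true(kaly$flagged[kaly$term == "Pulmonary function test decreased"])
  ## the target-only unexpected signal does not
  expect_false(isTRUE(kaly$flagged[kaly$term == "Mood altered"]))
  ## absent comparator: empty result with warning
  expect_warning(res <- comparator_screen(cases, "NOSUCHDRUG", "x"),
                 "absent")
  expect_equal(nrow(res), 0L)
})
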