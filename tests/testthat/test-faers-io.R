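test_that("FAERS date parsing distinguishes full, partial, missing, invalid", {
  d <- parse_faers_date(c("20150801", "201508", "2015", "", "20151340",
                          "notadate", "20160229", "20150229"))
  expect_equal(d$precision,
               c("day", "month", "year", "missing", "invalid", "invalid",
                 "day", "invalid"))  # 2016 is a leap year, 2015 is not
  expect_equal(d$date[1], as.Date("2015-08-01"))
  expect_true(all(is.na(d$date[-c(1, 7)])))
})

test_that("dollar-delimited tables parse with header, trailing delimiter and 0 rows", {
  tmp <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$fda_dt",
               "1001$100$20160101",
               "1002$101$20160102"), file.path(tmp, "t.txt"))
  df <- faersignal:::read_dollar_table(file.path(tmp, "t.txt"))
  expect_equal(nrow(df), 2L)        # lines minus header
  expect_equal(df$primaryid, c("1001", "1002"))

  ## trailing "$" and trailing empty fields are tolerated
  writeLines(c("a$b$c$", "1$2$3$", "4$5$", "x$y$z$w$v"),
             file.path(tmp, "t2.txt"))
  df2 <- faersignal:::read_dollar_table(file.path(tmp, "t2.txt"))
  expect_equal(nrow(df2), 2L)
  expect_equal(df2$c, c("3", ""))
  expect_equal(attr(df2, "malformed"), 1L)  # the 5-field row

  writeLines("a$b", file.path(tmp, "t3.txt"))
  df3 <- faersignal:::read_dollar_table(file.path(tmp, "t3.txt"))
  expect_equal(nrow(df3), 0L)
})

test_that("reading a quarter fails with the missing table named", {
  tmp <- withr::local_tempdir()
  expect_error(read_faers_quarter(tmp, "16Q1"), "DEMO")
})

test_that("deduplication keeps the most recent FDA_DT, then highest PRIMARYID", {
  demo <- data.frame(
    primaryid = c("1001", "1002", "2001", "2002", "3001"),
    caseid = c("100", "100", "200", "200", "300"),
    fda_dt = c("20160101", "20170101", "20200101", "20200101", "20190301"),
    stringsAsFactors = FALSE
  )
  kept <- deduplicate_cases(demo)
  expect_setequal(kept, c("1002", "2002", "3001"))

  ## unparseable FDA_DT sorts as oldest
  demo2 <- data.frame(primaryid = c("11", "12"), caseid = c("9", "9"),
                      fda_dt = c("", "20100101"))
  expect_equal(deduplicate_cases(demo2), "12")

  expect_error(deduplicate_cases(
    data.frame(primaryid = c("1", "1"), caseid = c("a", "b"),
               fda_dt = c("20200101", "20200102"))),
    "duplicate primaryid")
})

test_that("deduplication is idempotent and bounded by distinct caseids", {
  set.seed(42)
  n <- 400
  demo <- data.frame(
    primaryid = as.character(sample(1e6, n)),
    caseid = as.character(sample(150, n, replace = TRUE)),
    fda_dt = format(as.Date("2016-01-01") + sample(0:2000, n, TRUE),
                    "%Y%m%d"),
    stringsAsFactors = FALSE
  )
  kept <- deduplicate_cases(demo)
  expect_lte(length(kept), length(unique(demo$caseid)))
  expect_equal(length(kept), length(unique(demo$caseid)))
  again <- deduplicate_cases(demo[demo$primaryid %in% kept, ])
  expect_setequal(again, kept)

  ## no repeated caseid: everything retained
  demo_u <- demo[!duplicated(demo$caseid), ]
  expect_setequal(deduplicate_cases(demo_u), demo_u$primaryid)
})

test_that("deleted-case removal is a caseid set difference", {
  demo <- data.frame(primaryid = c("1001", "1002"), caseid = c("100", "101"),
                     fda_dt = "20200101")
  kept <- c("1001", "1002")
  expect_equal(remove_deleted_cases(kept, demo, character(0)), kept)
  expect_equal(remove_deleted_cases(kept, demo, "101"), "1001")
})

test_that("drug report selection is exact-match on normalized names and role", {
  drug <- data.frame(
    primaryid = c("1", "2", "3", "4", "5"),
    drugname = c("Orkambi", "ORKAMBI", "LUMACAFTOR/IVACAFTOR", "KALYDECO",
                 "IVACAFTOR"),
    role_cod = c("PS", "C", "PS", "PS", "PS"),
    stringsAsFactors = FALSE
  )
  syn <- c("ORKAMBI", "LUMACAFTOR/IVACAFTOR")
  expect_setequal(select_drug_reports(drug, syn), c("1", "3"))
  ## role C excluded under role = PS; comparator synonyms select only theirs
  expect_setequal(select_drug_reports(drug, c("KALYDECO", "IVACAFTOR")),
                  c("4", "5"))
  ## exact matching: IVACAFTOR does not catch the combination product
  expect_setequal(select_drug_reports(drug, "IVACAFTOR"), "5")
  expect_error(select_drug_reports(drug, character(0)), "empty")
})

test_that("case assembly normalizes units and attributes one SOC per PT record", {
  tmp <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$wt$wt_cod$occp_cod$reporter_country",
               "1$10$20200101$20191801$24$MON$F$110$LBS$CN$US",
               "2$20$20200101$20190601$30$YR$M$70$KG$MD$US",
               "3$30$20200101$$5$DEC$F$$$CN$GB"),
             file.path(tmp, "DEMO19Q1.txt"))
  writeLines(c("primaryid$drug_seq$role_cod$drugname$dose_amt$dose_freq",
               "1$1$PS$Orkambi$200/125 MG$BID",
               "2$1$PS$ORKAMBI$$QD",
               "2$2$C$PULMOZYME$$",
               "3$1$PS$OTHERDRUG$$"),
             file.path(tmp, "DRUG19Q1.txt"))
  writeLines(c("primaryid$pt", "1$Cough", "1$Dyspnoea", "1$Cough",
               "2$Cough", "3$Rash"), file.path(tmp, "REAC19Q1.txt"))
  writeLines(c("primaryid$indi_pt", "1$CYSTIC FIBROSIS"),
             file.path(tmp, "INDI19Q1.txt"))
  writeLines(c("primaryid$dsg_drug_seq$start_dt$end_dt",
               "1$1$20190201$", "1$1$20190105$", "2$1$201905$"),
             file.path(tmp, "THER19Q1.txt"))
  writeLines(c("primaryid$outc_cod", "1$HO", "2$DE", "2$HO"),
             file.path(tmp, "OUTC19Q1.txt"))
  tb <- read_faers_quarter(tmp, "19Q1")
  cases <- assemble_cases(tb, c("1", "2", "3"), c("ORKAMBI"),
                          pt_soc = data.frame(pt = c("Cough", "Dyspnoea"),
                                              soc = c("Resp", "Resp")))
  r <- cases$reports
  expect_equal(r$age_yr[r$primaryid == "1"], 2.0)            # 24 months
  expect_equal(r$age_yr[r$primaryid == "3"], 50)             # 5 decades
  expect_equal(round(r$weight_kg[r$primaryid == "1"], 1), 49.9)  # 110 lbs
  expect_equal(r$weight_kg[r$primaryid == "2"], 70)
  ## duplicate PT collapses: report 1 has 2 records despite 3 REAC rows
  expect_equal(sum(cases$records$primaryid == "1"), 2L)
  expect_setequal(cases$records$soc[cases$records$primaryid == "1"], "Resp")
  expect_equal(cases$records$soc[cases$records$pt == "Rash"], "UNMAPPED")
  ## earliest valid full start date wins; partial start is not a date
  expect_equal(r$start_date[r$primaryid == "1"], as.Date("2019-01-05"))
  expect_equal(r$start_precision[r$primaryid == "2"], "partial")
  ## invalid event date flagged, monotherapy/target flags correct
  expect_equal(r$event_precision[r$primaryid == "1"], "invalid")
  expect_true(r$monotherapy[r$primaryid == "1"])
  expect_false(r$monotherapy[r$primaryid == "2"])
  expect_setequal(r$primaryid[r$is_target], c("1", "2"))
  expect_true(r$fatal[r$primaryid == "2"])
  expect_equal(select_drug_reports(cases$drugs, "ORKAMBI"), c("1", "2"))
})

test_that("synthetic quarter round-trips through ingestion with exact truth counts", {
  tmp <- withr::local_tempdir()
  cfg <- small_sim_config(n_reports = 800, duplicate_fraction = 0.1,
                          deleted_fraction = 0.02)
  truth <- generate_faers_dataset(cfg, tmp, seed = 303)
  tb <- read_faers_quarter(tmp, "16Q1")
  expect_equal(sum(attr(tb, "malformed")), 0L)
  expect_equal(nrow(tb$demo), truth$counts$n_demo_rows)

  kept <- deduplicate_cases(tb$demo)
  expect_equal(length(kept), truth$counts$n_reports)
  ## every duplicated case resolves to its later (duplicate) version
  expect_true(all(truth$duplicates$dup_primaryid %in% kept))
  expect_false(any(truth$duplicates$old_primaryid %in% kept))

  kept2 <- remove_deleted_cases(kept, tb$demo, tb$deleted_caseids)
  expect_equal(length(kept), length(kept2) + truth$counts$n_deleted)

  cases <- assemble_cases(tb, kept2, default_synonyms("orkambi"),
                          pt_soc = read_pt_soc_map(file.path(tmp,
                                                             "pt2soc.tsv")))
  keep_truth <- !truth$reports$deleted
  expect_equal(nrow(cases$reports), sum(keep_truth))
  expect_equal(nrow(cases$records),
               sum(truth$reports$n_pts[keep_truth]))
  ## exactly one SOC per record, none unmapped under the generator's map
  expect_false(any(cases$records$soc == "UNMAPPED"))
  ## demographics survive the round trip (weight within rounding); retained
  ## ids of duplicated cases are the duplicate versions, so map by caseid
  tr <- truth$reports[match(cases$reports$caseid,
                            truth$reports$caseid), ]
  got_sex <- cases$reports$sex
  expect_true(all(got_sex == tr$sex | is.na(got_sex)))
  w <- cases$reports$weight_kg
  expect_true(all(abs(w - tr$weight_kg)[!is.na(w)] < 0.3))
})
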