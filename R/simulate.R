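## Synthetic FAERS generator.  Emits quarterly files in exactly the format
## the ingestion layer reads, together with the ground truth that was planted
## (association strengths, duplicates, deletions, onset days), so that every
## downstream stage can be validated without external data.

default_drug_catalog <- function() {
  bg <- c("IBUPROFEN", "AZITHROMYCIN", "OMEPRAZOLE", "SALBUTAMOL",
          "PREDNISONE", "AMOXICILLIN", "PARACETAMOL", "METFORMIN",
          "LISINOPRIL", "SERTRALINE", "INSULIN GLARGINE", "CEFTAZIDIME")
  data.frame(
    name = c("ORKAMBI", "KALYDECO", "SYMDEKO", bg),
    prob = c(0.10, 0.06, 0.06, rep(0.78 / length(bg), length(bg))),
    stringsAsFactors = FALSE
  )
}

default_concomitant_catalog <- function() {
  data.frame(
    name = c("PULMOZYME", "CREON", "SODIUM CHLORIDE", "AZITHROMYCIN",
             "CAYSTON", "ZENPEP", "TOBRAMYCIN", "OMEPRAZOLE", "PROAIR HFA",
             "VITAMIN D3"),
    prob = c(0.30, 0.20, 0.11, 0.10, 0.09, 0.08, 0.07, 0.06, 0.06, 0.06),
    stringsAsFactors = FALSE
  )
}

default_pt_catalog <- function() {
  soc_inf <- "Infections and infestations"
  soc_resp <- "Respiratory, thoracic and mediastinal disorders"
  soc_gi <- "Gastrointestinal disorders"
  soc_psy <- "Psychiatric disorders"
  soc_inv <- "Investigations"
  soc_met <- "Metabolism and nutrition disorders"
  soc_skin <- "Skin and subcutaneous tissue disorders"
  soc_gen <- "General disorders and administration site conditions"
  soc_surg <- "Surgical and medical procedures"
  soc_nerv <- "Nervous system disorders"
  soc_msk <- "Musculoskeletal and connective tissue disorders"
  soc_vasc <- "Vascular disorders"
  df <- rbind(
    c("Infective pulmonary exacerbation of cystic fibrosis", soc_inf, 0.002),
    c("Pneumonia", soc_inf, 0.02),
    c("Nasopharyngitis", soc_inf, 0.02),
    c("Rhinitis", soc_inf, 0.01),
    c("Infection", soc_inf, 0.02),
    c("Sinusitis", soc_inf, 0.01),
    c("Dyspnoea", soc_resp, 0.04),
    c("Cough", soc_resp, 0.05),
    c("Haemoptysis", soc_resp, 0.008),
    c("Chest discomfort", soc_resp, 0.015),
    c("Nausea", soc_gi, 0.06),
    c("Vomiting", soc_gi, 0.04),
    c("Diarrhoea", soc_gi, 0.05),
    c("Abdominal pain", soc_gi, 0.03),
    c("Constipation", soc_gi, 0.02),
    c("Flatulence", soc_gi, 0.01),
    c("Depression", soc_psy, 0.02),
    c("Anxiety", soc_psy, 0.02),
    c("Suicidal ideation", soc_psy, 0.008),
    c("Aggression", soc_psy, 0.006),
    c("Mood altered", soc_psy, 0.005),
    c("Insomnia", soc_psy, 0.02),
    c("Pulmonary function test decreased", soc_inv, 0.003),
    c("Weight decreased", soc_inv, 0.02),
    c("Blood creatine phosphokinase increased", soc_inv, 0.006),
    c("Decreased appetite", soc_met, 0.02),
    c("Hypoglycaemia", soc_met, 0.008),
    c("Rash", soc_skin, 0.03),
    c("Pruritus", soc_skin, 0.02),
    c("Malaise", soc_gen, 0.04),
    c("Fatigue", soc_gen, 0.05),
    c("Pyrexia", soc_gen, 0.03),
    c("Drug ineffective", soc_gen, 0.08),
    c("Hospitalisation", soc_surg, 0.03),
    c("Headache", soc_nerv, 0.06),
    c("Dizziness", soc_nerv, 0.04),
    c("Rhabdomyolysis", soc_msk, 0.004),
    c("Hypertension", soc_vasc, 0.02)
  )
  data.frame(pt = df[, 1], soc = df[, 2], p = as.numeric(df[, 3]),
             stringsAsFactors = FALSE)
}

default_planted_signals <- function() {
  t <- "ORKAMBI"
  comps <- c("KALYDECO", "SYMDEKO")
  plant <- function(drug, pt, theta) {
    data.frame(drug = drug, pt = pt, theta = theta, stringsAsFactors = FALSE)
  }
  rbind(
    ## label (expected) associations, target only
    plant(t, "Infective pulmonary exacerbation of cystic fibrosis", 60),
    plant(t, "Dyspnoea", 4),
    plant(t, "Cough", 5),
    plant(t, "Rhinitis", 4),
    plant(t, "Pneumonia", 3),
    plant(t, "Haemoptysis", 3),
    ## disease-linked associations shared by all three CFTR modulators
    plant(c(t, comps), "Hospitalisation", 8),
    plant(c(t, comps), "Pulmonary function test decreased", 20),
    plant(c(t, comps), "Sinusitis", 5),
    plant(c(t, comps), "Weight decreased", 2.5),
    ## unexpected associations, target only
    plant(t, "Depression", 2.5),
    plant(t, "Suicidal ideation", 2.5),
    plant(t, "Hypoglycaemia", 2.5),
    plant(t, "Flatulence", 4),
    plant(t, "Mood altered", 4),
    plant(t, "Rhabdomyolysis", 3)
  )
}

#' Simulation configuration for the synthetic FAERS generator
#'
#' Defaults emulate the reporting structure of a CF-modulator safety study:
#' one target drug (ORKAMBI) and two same-indication comparators among a
#' background drug catalog, planted drug-event associations expressed as odds
#' multipliers (so the expected reporting odds ratio of a planted pair equals
#' its `theta` and unplanted pairs have expected ROR 1), heavy demographic
#' missingness (weight missing in >80% of reports, frequency in ~27%),
#' duplicate case versions with later FDA_DT, deleted-case lists, and
#' therapy/event date pairs whose intervals follow a Weibull law with shape
#' 0.79 (decreasing hazard).
#'
#' @param n_reports number of underlying reports (before duplication).
#' @param quarter quarter tag for the emitted files (default `"16Q1"`).
#' @param drug_catalog data frame `name`/`prob`: primary-suspect drug and its
#'   marginal probability.
#' @param concomitant_catalog data frame `name`/`prob`: each concomitant drug
#'   is drawn independently per report.
#' @param pt_catalog data frame `pt`/`soc`/`p`: event terms with background
#'   reporting probabilities.
#' @param planted_signals data frame `drug`/`pt`/`theta`: odds multipliers,
#'   `theta > 0`.
#' @param covariate_effects named list: per PT, named numeric vector of
#'   log-odds shifts; supported names `male` (applied when sex is M).
#' @param duplicate_fraction fraction of cases receiving an extra version
#'   with a later FDA_DT.
#' @param deleted_fraction fraction of cases listed in the deleted-case file.
#' @param missing_rates named list of per-field missingness probabilities
#'   (`age`, `sex`, `weight`, `frequency`, `dose`, `indication`, `start_dt`,
#'   `event_dt`).
#' @param partial_date_fraction probability that a recorded (non-missing)
#'   therapy start or event date is written as a partial `YYYYMM` value.
#' @param tto_shape,tto_scale default Weibull onset parameters (days).
#' @param tto_models optional data frame `drug`/`pt`/`shape`/`scale`
#'   overriding the onset law for reports of that pair.
#' @param demographics named list: `sex_female`, `age_group_probs`,
#'   `weight_meanlog`, `weight_sdlog`, `reporter_probs`, `country_probs`.
#' @param fatal_fraction probability a report carries outcome code DE.
#' @param hosp_fraction probability a report carries outcome code HO.
#' @param start_window two dates bounding therapy start.
#' @param seed optional integer seed stored in the config.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_reports = 20000L,
                       quarter = "16Q1",
                       drug_catalog = default_drug_catalog(),
                       concomitant_catalog = default_concomitant_catalog(),
                       pt_catalog = default_pt_catalog(),
                       planted_signals = default_planted_signals(),
                       covariate_effects = list(
                         Depression = c(male = log(0.224))
                       ),
                       duplicate_fraction = 0.08,
                       deleted_fraction = 0.01,
                       missing_rates = list(age = 0.41, sex = 0.08,
                                            weight = 0.82, frequency = 0.27,
                                            dose = 0.45, indication = 0.02,
                                            start_dt = 0.50, event_dt = 0.35),
                       partial_date_fraction = 0.08,
                       tto_shape = 0.79,
                       tto_scale = 400,
                       tto_models = NULL,
                       demographics = list(
                         sex_female = 0.52,
                         age_group_probs = c("<2" = 0.03, "2-5" = 0.10,
                                             "6-11" = 0.17, "12-17" = 0.23,
                                             "18-65" = 0.45, ">65" = 0.02),
                         weight_meanlog = log(45), weight_sdlog = 0.35,
                         reporter_probs = c(CN = 0.45, OT = 0.23, PH = 0.20,
                                            MD = 0.11, HP = 0.01),
                         country_probs = c(US = 0.892, GB = 0.031, FR = 0.014,
                                           OTHER = 0.063)
                       ),
                       fatal_fraction = 0.018,
                       hosp_fraction = 0.50,
                       start_window = c("2016-01-01", "2023-06-30"),
                       seed = NULL) {
  stopifnot(n_reports >= 1, nrow(drug_catalog) >= 1, nrow(pt_catalog) >= 1,
            all(drug_catalog$prob >= 0), sum(drug_catalog$prob) > 0,
            all(pt_catalog$p > 0), all(pt_catalog$p < 1),
            duplicate_fraction >= 0, duplicate_fraction <= 1,
            deleted_fraction >= 0, deleted_fraction <= 1,
            partial_date_fraction >= 0, partial_date_fraction <= 1,
            tto_shape > 0, tto_scale > 0,
            fatal_fraction >= 0, fatal_fraction <= 1)
  if (!is.null(planted_signals) && nrow(planted_signals)) {
    stopifnot(all(planted_signals$theta > 0),
              all(planted_signals$drug %in% drug_catalog$name),
              all(planted_signals$pt %in% pt_catalog$pt))
  }
  stopifnot(all(unlist(missing_rates) >= 0), all(unlist(missing_rates) <= 1))
  structure(as.list(environment()), class = "sim_config")
}

fmt_ymd <- function(d) format(d, "%Y%m%d")

## write a date vector with configured quality: full / partial YYYYMM / ""
date_with_quality <- function(d, p_missing, p_partial) {
  n <- length(d)
  u <- runif(n)
  out <- fmt_ymd(d)
  out[u < p_missing] <- ""
  part <- u >= p_missing & u < p_missing + p_partial
  out[part] <- substr(out[part], 1L, 6L)
  out
}

#' Simulate one quarter of FAERS reports in memory
#'
#' Draws the full report set described by a [sim_config()]: primary-suspect
#' drug, demographics, event terms (planted pairs get odds
#' `theta * p/(1-p)` on the background probability `p`, so their expected ROR
#' is `theta`), concomitant drugs, outcome codes, therapy/event/FDA dates
#' consistent with the sampled Weibull onset intervals, duplicate versions
#' and a deleted-case list.  Identical seeds give identical output.
#'
#' @param config a `sim_config`.
#' @param seed integer seed (overrides `config$seed`).
#' @return list with `tables` (the six all-character FAERS tables),
#'   `deleted_caseids`, and `truth` (see [planted_truth()] plus per-report
#'   rows, record tally and duplicate bookkeeping).
#' @export
simulate_reports <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(config$n_reports)
  dem <- config$demographics
  pts <- config$pt_catalog
  J <- nrow(pts)

  ps <- sample(config$drug_catalog$name, n, replace = TRUE,
               prob = config$drug_catalog$prob)

  sex <- ifelse(runif(n) < dem$sex_female, "F", "M")
  agp <- sample(names(dem$age_group_probs), n, replace = TRUE,
                prob = dem$age_group_probs)
  age_lo <- c("<2" = 0.1, "2-5" = 2, "6-11" = 6, "12-17" = 12,
              "18-65" = 18, ">65" = 66)
  age_hi <- c("<2" = 2, "2-5" = 6, "6-11" = 12, "12-17" = 18,
              "18-65" = 65, ">65" = 85)
  age <- age_lo[agp] + runif(n) * (age_hi[agp] - age_lo[agp])
  weight <- rlnorm(n, dem$weight_meanlog, dem$weight_sdlog)
  reporter <- sample(names(dem$reporter_probs), n, replace = TRUE,
                     prob = dem$reporter_probs)
  country <- sample(names(dem$country_probs), n, replace = TRUE,
                    prob = dem$country_probs)

  ## per-report event probabilities: background, then odds-multiplier
  ## planting per (PS drug, PT), then covariate effects on the logit
  P <- matrix(rep(pts$p, each = n), nrow = n, ncol = J)
  plant <- config$planted_signals
  if (!is.null(plant) && nrow(plant)) {
    for (k in seq_len(nrow(plant))) {
      j <- match(plant$pt[k], pts$pt)
      rows <- ps == plant$drug[k]
      odds <- plant$theta[k] * pts$p[j] / (1 - pts$p[j])
      P[rows, j] <- odds / (1 + odds)
    }
  }
  for (pt_name in names(config$covariate_effects %||% list())) {
    j <- match(pt_name, pts$pt)
    if (is.na(j)) next
    eff <- config$covariate_effects[[pt_name]]
    shift <- numeric(n)
    if (!is.na(eff["male"])) shift <- shift + eff[["male"]] * (sex == "M")
    P[, j] <- plogis(qlogis(P[, j]) + shift)
  }
  hits <- matrix(runif(n * J), n, J) < P
  empty <- which(rowSums(hits) == 0L)
  if (length(empty)) {
    ## every report must carry at least one reaction; the forced draw uses
    ## the report's own (planted) probabilities so association strengths
    ## survive the conditioning
    forced <- vapply(empty, function(i) {
      sample.int(J, 1L, prob = P[i, ])
    }, integer(1))
    hits[cbind(empty, forced)] <- TRUE
  }
  rec_idx <- which(hits, arr.ind = TRUE)
  rec_idx <- rec_idx[order(rec_idx[, 1L], rec_idx[, 2L]), , drop = FALSE]

  ## concomitant drugs, independent draws
  conc <- config$concomitant_catalog
  Cm <- matrix(runif(n * nrow(conc)), n, nrow(conc)) <
    matrix(rep(conc$prob, each = n), n)
  monotherapy <- rowSums(Cm) == 0L

  fatal <- runif(n) < config$fatal_fraction
  hosp <- runif(n) < config$hosp_fraction

  ## dates: therapy start uniform over the window; event = start + onset;
  ## FDA receipt = event + geometric reporting lag (mean ~30 d)
  w0 <- as.Date(config$start_window[1])
  w1 <- as.Date(config$start_window[2])
  start <- w0 + floor(runif(n) * (as.numeric(w1 - w0) + 1))
  shape <- rep(config$tto_shape, n)
  scale <- rep(config$tto_scale, n)
  tm <- config$tto_models
  if (!is.null(tm) && nrow(tm)) {
    for (k in seq_len(nrow(tm))) {
      j <- match(tm$pt[k], pts$pt)
      rows <- ps == tm$drug[k] & hits[, j]
      shape[rows] <- tm$shape[k]
      scale[rows] <- tm$scale[k]
    }
  }
  onset <- pmax(1L, as.integer(ceiling(rweibull(n, shape, scale))))
  event <- start + onset
  fda <- event + rgeom(n, 1 / 31) + 1L

  primaryid <- as.character(100000000L + seq_len(n))
  caseid <- as.character(20000000L + seq_len(n))

  mr <- config$missing_rates
  age_present <- runif(n) >= (mr$age %||% 0)
  age_cod <- ifelse(age < 2, "MON", "YR")
  age_str <- ifelse(age_present,
                    ifelse(age_cod == "MON",
                           as.character(round(age * 12)),
                           as.character(round(age, 1))), "")
  age_cod[!age_present] <- ""
  wt_present <- runif(n) >= (mr$weight %||% 0)
  wt_lbs <- runif(n) < 0.2
  wt_str <- ifelse(wt_present,
                   ifelse(wt_lbs,
                          as.character(round(weight / LBS_PER_KG, 1)),
                          as.character(round(weight, 1))), "")
  wt_cod <- ifelse(wt_present, ifelse(wt_lbs, "LBS", "KG"), "")
  sex_str <- ifelse(runif(n) < (mr$sex %||% 0), "", sex)
  freq <- ifelse(runif(n) < 0.96, "BID", "QD")
  freq_str <- ifelse(runif(n) < (mr$frequency %||% 0), "", freq)
  dose_pool <- c("200/125 MG", "400/250 MG", "100/125 MG", "150/188 MG",
                 "OTHER")
  dose <- sample(dose_pool, n, replace = TRUE,
                 prob = c(0.40, 0.26, 0.20, 0.09, 0.05))
  dose_str <- ifelse(runif(n) < (mr$dose %||% 0), "", dose)
  indi_str <- ifelse(runif(n) < (mr$indication %||% 0), "",
                     ifelse(runif(n) < 0.976, "CYSTIC FIBROSIS",
                            "BRONCHIECTASIS"))

  start_str <- date_with_quality(start, mr$start_dt %||% 0,
                                 config$partial_date_fraction)
  event_str <- date_with_quality(event, mr$event_dt %||% 0,
                                 config$partial_date_fraction)

  ## spelling variation for the target-name field exercises normalization
  variants <- rbind(ps, tolower(ps), paste0(" ", ps, " "))
  ps_written <- variants[cbind(sample.int(3L, n, replace = TRUE),
                               seq_len(n))]

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid, fda_dt = fmt_ymd(fda),
    event_dt = event_str, age = age_str, age_cod = age_cod, sex = sex_str,
    wt = wt_str, wt_cod = wt_cod, occp_cod = reporter,
    reporter_country = country, stringsAsFactors = FALSE
  )
  drug <- data.frame(
    primaryid = primaryid, drug_seq = "1", role_cod = "PS",
    drugname = ps_written, dose_amt = dose_str, dose_freq = freq_str,
    stringsAsFactors = FALSE
  )
  ci <- which(Cm, arr.ind = TRUE)
  if (nrow(ci)) {
    ci <- ci[order(ci[, 1L], ci[, 2L]), , drop = FALSE]
    seq_off <- sequence(tabulate(ci[, 1L], nbins = n))
    drug <- rbind(drug, data.frame(
      primaryid = primaryid[ci[, 1L]],
      drug_seq = as.character(1L + seq_off),
      role_cod = "C", drugname = conc$name[ci[, 2L]],
      dose_amt = "", dose_freq = "", stringsAsFactors = FALSE
    ))
  }
  drug <- drug[order(as.numeric(drug$primaryid),
                     as.numeric(drug$drug_seq)), , drop = FALSE]
  reac <- data.frame(primaryid = primaryid[rec_idx[, 1L]],
                     pt = pts$pt[rec_idx[, 2L]], stringsAsFactors = FALSE)
  indi <- data.frame(primaryid = primaryid, indi_pt = indi_str,
                     stringsAsFactors = FALSE)
  indi <- indi[indi$indi_pt != "", , drop = FALSE]
  ther <- data.frame(primaryid = primaryid, dsg_drug_seq = "1",
                     start_dt = start_str, end_dt = "",
                     stringsAsFactors = FALSE)
  outc <- rbind(
    data.frame(primaryid = primaryid[fatal], outc_cod = "DE",
               stringsAsFactors = FALSE),
    data.frame(primaryid = primaryid[hosp], outc_cod = "HO",
               stringsAsFactors = FALSE),
    data.frame(primaryid = primaryid[!fatal & !hosp], outc_cod = "OT",
               stringsAsFactors = FALSE)
  )
  outc <- outc[order(as.numeric(outc$primaryid), outc$outc_cod), ,
               drop = FALSE]

  ## duplicate case versions: same CASEID, new PRIMARYID, strictly later
  ## FDA_DT, full copies of the satellite rows
  n_dup <- round(config$duplicate_fraction * n)
  dup_of <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
  duplicates <- data.frame(caseid = character(0), old_primaryid = character(0),
                           dup_primaryid = character(0),
                           stringsAsFactors = FALSE)
  if (n_dup > 0) {
    dup_pid <- as.character(100000000L + n + seq_len(n_dup))
    d2 <- demo[dup_of, , drop = FALSE]
    d2$primaryid <- dup_pid
    d2$fda_dt <- fmt_ymd(as.Date(demo$fda_dt[dup_of], "%Y%m%d") +
                           sample(30:400, n_dup, replace = TRUE))
    demo <- rbind(demo, d2)
    copy_rows <- function(df) {
      m <- df[df$primaryid %in% primaryid[dup_of], , drop = FALSE]
      m$primaryid <- dup_pid[match(m$primaryid, primaryid[dup_of])]
      m
    }
    drug <- rbind(drug, copy_rows(drug))
    reac <- rbind(reac, copy_rows(reac))
    indi <- rbind(indi, copy_rows(indi))
    ther <- rbind(ther, copy_rows(ther))
    outc <- rbind(outc, copy_rows(outc))
    duplicates <- data.frame(caseid = caseid[dup_of],
                             old_primaryid = primaryid[dup_of],
                             dup_primaryid = dup_pid,
                             stringsAsFactors = FALSE)
  }

  n_del <- round(config$deleted_fraction * n)
  deleted_caseids <- if (n_del > 0) {
    sort(sample(caseid, n_del))
  } else {
    character(0)
  }

  truth_reports <- data.frame(
    primaryid = primaryid, caseid = caseid, ps_drug = ps, sex = sex,
    age_yr = age, age_group = agp, weight_kg = weight, reporter = reporter,
    country = country, frequency = freq, dose = dose, fatal = fatal,
    hosp = hosp, monotherapy = monotherapy, onset_days = onset,
    start_recorded = start_str != "" & nchar(start_str) == 8L,
    event_recorded = event_str != "" & nchar(event_str) == 8L,
    n_pts = as.integer(rowSums(hits)), deleted = caseid %in% deleted_caseids,
    stringsAsFactors = FALSE
  )
  truth <- list(
    reports = truth_reports,
    records = reac[seq_len(nrow(rec_idx)), , drop = FALSE],
    expected_ror = planted_truth(config)$expected_ror,
    duplicates = duplicates,
    deleted_caseids = deleted_caseids,
    counts = list(n_reports = n, n_records = nrow(rec_idx),
                  n_demo_rows = nrow(demo), n_duplicates = n_dup,
                  n_deleted = sum(truth_reports$deleted))
  )
  list(tables = list(demo = demo, drug = drug, reac = reac, indi = indi,
                     ther = ther, outc = outc),
       deleted_caseids = deleted_caseids, truth = truth)
}

#' Ground truth planted by a simulation configuration
#'
#' @param config a `sim_config`.
#' @return list with `expected_ror` (data frame `drug`/`pt`/`expected_ror`;
#'   pairs not listed have expected ROR 1 by construction) and `tto` (the
#'   onset model parameters).
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  plant <- config$planted_signals
  er <- if (is.null(plant) || nrow(plant) == 0L) {
    data.frame(drug = character(0), pt = character(0),
               expected_ror = numeric(0), stringsAsFactors = FALSE)
  } else {
    data.frame(drug = plant$drug, pt = plant$pt, expected_ror = plant$theta,
               stringsAsFactors = FALSE)
  }
  list(expected_ror = er,
       tto = list(shape = config$tto_shape, scale = config$tto_scale,
                  models = config$tto_models))
}

#' Write a simulated quarter to disk in FAERS format
#'
#' Emits the six "$"-delimited tables plus the deleted-case list and a
#' `pt2soc.tsv` mapping file, all readable by [read_faers_quarter()] and
#' [read_pt_soc_map()].  Output is byte-identical for identical seeds.
#'
#' @param config a `sim_config`.
#' @param dir output directory (created if needed).
#' @param seed integer seed (overrides `config$seed`).
#' @return invisibly, the `truth` component of [simulate_reports()] with the
#'   output directory attached as attribute `dir`.
#' @export
generate_faers_dataset <- function(config, dir, seed = NULL) {
  sim <- simulate_reports(config, seed = seed)
  tag <- quarter_tag(config$quarter)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in names(sim$tables)) {
    write.table(sim$tables[[tab]],
                file.path(dir, paste0(toupper(tab), tag, ".txt")),
                sep = "$", quote = FALSE, row.names = FALSE, na = "")
  }
  writeLines(sim$deleted_caseids,
             file.path(dir, paste0("DELETED", tag, ".txt")))
  write.table(config$pt_catalog[, c("pt", "soc")],
              file.path(dir, "pt2soc.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  attr(truth, "dir") <- dir
  invisible(truth)
}
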