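## End-to-end study orchestration: ingest (real or synthetic), deduplicate,
## select, screen, prioritize, stratify, regress, time-to-onset — emitting
## deterministic TSV result tables and a JSON run manifest whose filter-chain
## counts mirror the study flowchart.

#' Default synonym lists for the CFTR-modulator drugs
#'
#' Exact-match (normalized) synonym sets covering generic and brand
#' spellings.
#'
#' @param drug `"orkambi"`, `"kalydeco"` or `"symdeko"`.
#' @return character vector of synonyms.
#' @export
default_synonyms <- function(drug = c("orkambi", "kalydeco", "symdeko")) {
  switch(match.arg(drug),
    orkambi = c("ORKAMBI", "LUMACAFTOR/IVACAFTOR", "LUMACAFTOR-IVACAFTOR",
                "VX-809 VX-770"),
    kalydeco = c("KALYDECO", "IVACAFTOR", "VX-770"),
    symdeko = c("SYMDEKO", "TEZACAFTOR/IVACAFTOR",
                "TEZACAFTOR/IVACAFTOR/IVACAFTOR")
  )
}

## term lists matching the default synthetic catalog: which planted PTs are
## on the label and which belong to the DME / IME relevance lists
default_label_terms <- function() {
  c("Infective pulmonary exacerbation of cystic fibrosis", "Dyspnoea",
    "Cough", "Rhinitis", "Pneumonia", "Haemoptysis")
}
default_dme_terms <- function() {
  c("Suicidal ideation", "Rhabdomyolysis")
}
default_ime_terms <- function() {
  c("Depression", "Pneumonia", "Hypoglycaemia", "Pneumothorax",
    "Pancreatitis", "Respiratory failure")
}

#' Build a run configuration
#'
#' @param input either a [sim_config()] (synthetic mode) or a list
#'   `list(dir = ..., quarters = c(...))` pointing at FAERS quarterly files.
#' @param target_synonyms synonym list for the study drug.
#' @param comparators named list of comparator synonym lists.
#' @param label_terms,dme_terms,ime_terms PT lists for origin classification
#'   and relevance scoring.
#' @param pt_soc data frame mapping `pt` to `soc`, or `NULL` (synthetic mode
#'   uses the generator's catalog).
#' @param indication_filter optional indication term: when set, target
#'   reports are restricted to that indication before analysis (off by
#'   default).
#' @param min_cases,alpha,conf thresholds for screening and subgroup calls.
#' @param outcome_pt outcome term for the logistic risk-factor model.
#' @param seed integer seed governing all randomness of a synthetic run.
#' @return object of class `faers_run_config`.
#' @export
run_config <- function(input = sim_config(),
                       target_synonyms = default_synonyms("orkambi"),
                       comparators = list(
                         KALYDECO = default_synonyms("kalydeco"),
                         SYMDEKO = default_synonyms("symdeko")
                       ),
                       label_terms = default_label_terms(),
                       dme_terms = default_dme_terms(),
                       ime_terms = default_ime_terms(),
                       pt_soc = NULL,
                       indication_filter = NULL,
                       min_cases = 3,
                       alpha = 0.05,
                       conf = 0.95,
                       outcome_pt = "Depression",
                       seed = 1L) {
  stopifnot(length(target_synonyms) >= 1, min_cases >= 1,
            alpha > 0, alpha < 1, conf > 0, conf < 1)
  structure(as.list(environment()), class = "faers_run_config")
}

#' Run the full analysis
#'
#' Executes every stage in dependency order — ingest, deduplicate, remove
#' deleted cases, select target reports, assemble cases, primary PT/SOC
#' screens, monotherapy and comparator sensitivity screens, priority scoring
#' with origin classification, stratified subgroup screens, logistic
#' risk-factor regression, and time-to-onset analysis — and writes every
#' stage's output as TSV plus a JSON manifest.  Any stage error aborts with
#' the stage name.  A rerun with the same config and seed produces
#' byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param seed overrides `config$seed`.
#' @return invisibly, a list of all result objects plus `manifest` and
#'   `out_dir`.
#' @export
run_faers_analysis <- function(config, out_dir, seed = NULL) {
  stopifnot(inherits(config, "faers_run_config"))
  seed <- as.integer(seed %||% config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## -- ingest ---------------------------------------------------------
  synthetic <- inherits(config$input, "sim_config")
  tables <- stop_stage("ingest", {
    if (synthetic) {
      data_dir <- file.path(tempdir(), sprintf("faersim_%d", seed))
      unlink(data_dir, recursive = TRUE)
      truth <- generate_faers_dataset(config$input, data_dir, seed = seed)
      tb <- read_faers_quarter(data_dir, config$input$quarter)
      attr(tb, "truth") <- truth
      tb
    } else {
      qs <- lapply(config$input$quarters, function(q) {
        read_faers_quarter(config$input$dir, q)
      })
      bind_faers_quarters(qs)
    }
  })
  pt_soc <- config$pt_soc
  if (is.null(pt_soc) && synthetic) {
    pt_soc <- config$input$pt_catalog[, c("pt", "soc")]
  }

  ## -- deduplicate / deleted / assemble --------------------------------
  n_raw <- nrow(tables$demo)
  retained <- stop_stage("deduplicate", deduplicate_cases(tables$demo))
  n_dedup <- length(retained)
  retained <- stop_stage("remove_deleted", {
    remove_deleted_cases(retained, tables$demo, tables$deleted_caseids)
  })
  n_after_deleted <- length(retained)
  cases <- stop_stage("assemble", {
    assemble_cases(tables, retained, config$target_synonyms,
                   pt_soc = pt_soc)
  })
  target_ids <- stop_stage("select", {
    ids <- select_drug_reports(cases$drugs, config$target_synonyms)
    if (!is.null(config$indication_filter)) {
      keep <- cases$reports$primaryid[
        !is.na(cases$reports$indication) &
          cases$reports$indication == config$indication_filter]
      ids <- intersect(ids, keep)
    }
    ids
  })
  if (length(target_ids) == 0L) stop("stage 'select' failed: no target reports")
  n_target <- length(target_ids)
  n_target_records <- sum(cases$records$primaryid %in% target_ids)

  ## -- signal screens ---------------------------------------------------
  screens <- stop_stage("screen", {
    primary_pt <- screen_signals(cases, target_ids, level = "pt",
                                 analysis_tag = "primary",
                                 min_cases = config$min_cases,
                                 conf = config$conf)
    primary_soc <- screen_signals(cases, target_ids, level = "soc",
                                  analysis_tag = "primary",
                                  min_cases = config$min_cases,
                                  conf = config$conf)
    mono <- restrict_monotherapy(cases, target_ids)
    mono_tab <- if (length(mono$target_ids)) {
      screen_signals(mono$cases, mono$target_ids, level = "pt",
                     analysis_tag = "monotherapy",
                     min_cases = config$min_cases, conf = config$conf)
    } else {
      primary_pt[0L, , drop = FALSE]
    }
    comp <- lapply(names(config$comparators), function(nm) {
      comparator_screen(cases, config$comparators[[nm]], nm,
                        min_cases = config$min_cases, conf = config$conf)
    })
    names(comp) <- names(config$comparators)
    list(primary_pt = primary_pt, primary_soc = primary_soc,
         monotherapy = mono_tab, n_monotherapy = length(mono$target_ids),
         comparators = comp)
  })

  ## -- prioritization ---------------------------------------------------
  priority <- stop_stage("prioritize", {
    prioritize_signals(screens$primary_pt, cases, target_ids,
                       label_terms = config$label_terms,
                       dme_terms = config$dme_terms,
                       ime_terms = config$ime_terms,
                       comparator_results = screens$comparators)
  })

  ## -- stratified subgroup screens --------------------------------------
  subgroup_defs <- list(
    sex = c("M", "F"),
    weight = c("50-100", "<50"),
    frequency = c("QD", "BID"),
    fatal = c("fatal", "non-fatal")
  )
  subgroups <- stop_stage("stratify", {
    lapply(names(subgroup_defs), function(sv) {
      gg <- subgroup_defs[[sv]]
      subgroup_screen(cases, target_ids, sv, gg[1L], gg[2L],
                      min_cases = config$min_cases, alpha = config$alpha)
    })
  })
  names(subgroups) <- names(subgroup_defs)

  ## -- logistic regression ----------------------------------------------
  regression <- stop_stage("regress", {
    tryCatch(
      regression_workflow(cases, target_ids, config$outcome_pt),
      error = function(e) {
        ## an outcome too sparse to model is reported, not fatal
        list(error = conditionMessage(e))
      }
    )
  })

  ## -- time-to-onset -----------------------------------------------------
  tto_res <- stop_stage("tto", {
    tto <- compute_tto(cases, target_ids, ime_terms = config$ime_terms)
    bins <- tto_bin_table(tto$days)
    wb <- if (nrow(tto) >= 10L && length(unique(tto$days)) >= 2L) {
      weibull_fit(tto$days)
    } else {
      NULL
    }
    socsum <- soc_tto_summary(tto, cases)
    grp_tests <- list()
    for (sv in c("sex", "ime", "frequency")) {
      v <- tto[[sv]]
      if (sv == "ime") v <- ifelse(tto$ime, "IME", "non-IME")
      gl <- split(tto$days, v)
      gl <- gl[lengths(gl) > 0L]
      if (length(gl) >= 2L) {
        lr <- logrank_test(gl)
        wx <- if (length(gl) == 2L) {
          wilcoxon_rank_sum(gl[[1L]], gl[[2L]])
        } else {
          NULL
        }
        grp_tests[[sv]] <- data.frame(
          stratum = sv, test = c("logrank", "wilcoxon"),
          statistic = c(lr$chi2, if (is.null(wx)) NA else wx$statistic),
          p = c(lr$p, if (is.null(wx)) NA else wx$p),
          stringsAsFactors = FALSE)
      }
    }
    dose_groups <- split(tto$days, tto$dose)
    dose_groups <- dose_groups[lengths(dose_groups) >= 2L]
    dunn <- if (length(dose_groups) >= 3L) {
      dunn_pairwise(dose_groups)
    } else {
      NULL
    }
    list(samples = tto, bins = bins, weibull = wb, soc_summary = socsum,
         tests = do.call(rbind, grp_tests), dunn = dunn)
  })

  ## -- descriptives ------------------------------------------------------
  descriptives <- stop_stage("describe", descriptive_tables(cases, target_ids))
  concomitant <- stop_stage("concomitant", {
    concomitant_top(cases, target_ids, k = 10,
                    target_synonyms = config$target_synonyms)
  })

  ## -- write outputs -----------------------------------------------------
  w <- function(df, name) write_result_tsv(df, file.path(out_dir, name))
  rep_out <- cases$reports
  rep_out$event_date <- as.character(rep_out$event_date)
  rep_out$start_date <- as.character(rep_out$start_date)
  w(rep_out, "cases.tsv")
  w(cases$records, "pt_records.tsv")
  w(screens$primary_pt, "signals_pt.tsv")
  w(screens$primary_soc, "signals_soc.tsv")
  w(screens$monotherapy, "signals_monotherapy.tsv")
  for (nm in names(screens$comparators)) {
    w(screens$comparators[[nm]], sprintf("signals_comparator_%s.tsv", nm))
  }
  w(priority, "priority.tsv")
  for (nm in names(subgroups)) {
    w(subgroups[[nm]], sprintf("subgroup_%s.tsv", nm))
  }
  if (is.null(regression$error)) {
    w(regression$univariate, "regression_univariate.tsv")
    if (!is.null(regression$multivariate)) {
      mv <- regression$multivariate
      w(data.frame(term = names(mv$coef), coef = mv$coef, or = mv$or,
                   or_low = mv$or_low, or_high = mv$or_high, p = mv$p,
                   stringsAsFactors = FALSE),
        "regression_multivariate.tsv")
    }
  }
  w(tto_res$samples, "tto_samples.tsv")
  w(tto_res$bins, "tto_bins.tsv")
  w(tto_res$soc_summary, "tto_soc_summary.tsv")
  if (!is.null(tto_res$tests)) w(tto_res$tests, "tto_tests.tsv")
  if (!is.null(tto_res$dunn)) w(tto_res$dunn, "tto_dunn_dose.tsv")
  if (!is.null(tto_res$weibull)) {
    wb <- tto_res$weibull
    w(data.frame(shape = wb$shape, shape_low = wb$shape_ci[1L],
                 shape_high = wb$shape_ci[2L], scale = wb$scale,
                 scale_low = wb$scale_ci[1L], scale_high = wb$scale_ci[2L],
                 n = wb$n, failure_class = wb$failure_class,
                 median_days = median(tto_res$samples$days),
                 q1_days = unname(quantile(tto_res$samples$days, 0.25)),
                 q3_days = unname(quantile(tto_res$samples$days, 0.75))),
      "tto_weibull.tsv")
  }
  w(descriptives, "descriptives.tsv")
  w(concomitant, "concomitant_top.tsv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("faersignal")),
    seed = seed,
    input_mode = if (synthetic) "synthetic" else "faers",
    config_hash = config_hash(config),
    counts = list(
      raw_demo_rows = n_raw,
      after_dedup = n_dedup,
      after_deleted_removed = n_after_deleted,
      assembled_reports = nrow(cases$reports),
      no_reaction_excluded = cases$meta$n_no_reac,
      target_reports = n_target,
      target_pt_records = n_target_records,
      monotherapy_target_reports = screens$n_monotherapy,
      tto_valid_reports = nrow(tto_res$samples)
    ),
    tto_exclusions = as.list(attr(tto_res$samples, "exclusions")),
    flagged_pt_signals = sum(screens$primary_pt$flagged),
    flagged_soc_signals = sum(screens$primary_soc$flagged)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cases = cases, target_ids = target_ids, screens = screens,
                 priority = priority, subgroups = subgroups,
                 regression = regression, tto = tto_res,
                 descriptives = descriptives, concomitant = concomitant,
                 manifest = manifest, out_dir = out_dir,
                 truth = attr(tables, "truth")))
}

## stable hash of the configuration (ignores functions' environments)
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[setdiff(names(config), "covariate_effects")]),
             tf)
  unname(tools::md5sum(tf))
}

#' Descriptive tabulations of the target drug's reports
#'
#' Counts and percentages (over all target reports) per category for report
#' year, reporter type, age group, sex, weight group, indication, dosing
#' frequency, dose, outcome codes and country, always including an explicit
#' `Missing` row.  A report counts once per distinct outcome code in the
#' outcome tabulation.
#'
#' @param cases a `faers_cases` object.
#' @param target_ids primaryids to describe.
#' @return data frame `variable`, `level`, `n`, `percent`.
#' @export
descriptive_tables <- function(cases, target_ids) {
  r <- cases$reports[cases$reports$primaryid %in% target_ids, , drop = FALSE]
  n_rep <- nrow(r)
  tab1 <- function(variable, v) {
    v <- as.character(v)
    v[is.na(v) | v == ""] <- "Missing"
    tt <- table(v)
    data.frame(variable = variable, level = names(tt),
               n = as.integer(tt), percent = 100 * as.integer(tt) / n_rep,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    tab1("year", r$year),
    tab1("reporter", r$reporter),
    tab1("age_group", as.character(cut(r$age_yr,
                                       c(0, 2, 6, 12, 18, 66, Inf),
                                       labels = c("<2", "2-5", "6-11",
                                                  "12-17", "18-65", ">65"),
                                       right = FALSE))),
    tab1("sex", r$sex),
    tab1("weight_group", as.character(cut(r$weight_kg, c(0, 50, 100, Inf),
                                          labels = c("<50", "50-100",
                                                     ">100"),
                                          right = FALSE))),
    tab1("indication", r$indication),
    tab1("frequency", r$frequency),
    tab1("dose", r$dose)
  )
  oc <- cases$outcomes[cases$outcomes$primaryid %in% target_ids, ,
                       drop = FALSE]
  tt <- table(oc$outc_cod)
  out <- rbind(out, data.frame(variable = "outcome", level = names(tt),
                               n = as.integer(tt),
                               percent = 100 * as.integer(tt) / n_rep,
                               stringsAsFactors = FALSE))
  out <- rbind(out, tab1("country", r$country))
  rownames(out) <- NULL
  out
}

#' Most frequently co-reported drugs
#'
#' Counts target-drug reports (not drug rows: a drug listed twice in one
#' report counts once) naming each normalized non-target drug, and returns
#' the top `k` with ties broken alphabetically.
#'
#' @param cases a `faers_cases` object.
#' @param target_ids primaryids of target-drug reports.
#' @param k number of drugs to return (`k >= 1`).
#' @param target_synonyms synonyms identifying (and excluding) the target
#'   drug itself.
#' @return data frame `drug`, `n_reports`.
#' @export
concomitant_top <- function(cases, target_ids, k = 10,
                            target_synonyms = character(0)) {
  if (k < 1) stop("k must be at least 1")
  d <- cases$drugs[cases$drugs$primaryid %in% target_ids, , drop = FALSE]
  syn <- normalize_drug_name(target_synonyms)
  d <- d[!(d$drugname_norm %in% syn), , drop = FALSE]
  d <- unique(d[, c("primaryid", "drugname_norm")])
  tt <- table(d$drugname_norm)
  out <- data.frame(drug = names(tt), n_reports = as.integer(tt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_reports, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  head(out, k)
}
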