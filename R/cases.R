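## Assembled case records: the central in-memory container downstream of
## ingestion.  A `faers_cases` object holds, for every retained report in the
## database (target drug and background alike):
##   reports  - one row per report: demographics (units normalized), dates,
##              target-drug exposure, dosing, outcome summary, monotherapy flag
##   records  - one row per (report, distinct PT), each attributed to one SOC
##   drugs    - retained drug rows with normalized names and a target flag
##   outcomes - one row per (report, distinct outcome code)

age_unit_factor <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.14,
                     DY = 1 / 365.25, HR = 1 / 8766)
LBS_PER_KG <- 0.453592

#' Construct a faers_cases object
#'
#' Low-level constructor used by [assemble_cases()] and by simulation helpers
#' that build case sets directly.  Performs structural validation only.
#'
#' @param reports data frame, one row per report; must contain `primaryid`.
#' @param records data frame, one row per (report, distinct PT); must contain
#'   `primaryid`, `pt`, `soc`.
#' @param drugs data frame of drug rows (`primaryid`, `drugname_norm`,
#'   `role_cod`, `is_target`); may be empty.
#' @param outcomes data frame of outcome rows (`primaryid`, `outc_cod`); may
#'   be empty.
#' @param meta list of bookkeeping counts.
#' @return object of class `faers_cases`.
#' @export
faers_cases <- function(reports, records,
                        drugs = data.frame(primaryid = character(0),
                                           drugname_norm = character(0),
                                           role_cod = character(0),
                                           is_target = logical(0)),
                        outcomes = data.frame(primaryid = character(0),
                                              outc_cod = character(0)),
                        meta = list()) {
  stopifnot(is.data.frame(reports), "primaryid" %in% names(reports),
            is.data.frame(records),
            all(c("primaryid", "pt", "soc") %in% names(records)))
  if (anyDuplicated(reports$primaryid)) {
    stop("reports must have unique primaryid")
  }
  if (!all(records$primaryid %in% reports$primaryid)) {
    stop("records refer to unknown reports")
  }
  structure(list(reports = reports, records = records, drugs = drugs,
                 outcomes = outcomes, meta = meta),
            class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("faers_cases: %d reports, %d PT records, %d SOCs\n",
              nrow(x$reports), nrow(x$records),
              length(unique(x$records$soc))))
  if (!is.null(x$reports$is_target)) {
    cat(sprintf("  target-drug reports: %d\n", sum(x$reports$is_target)))
  }
  invisible(x)
}

#' Subset a faers_cases object to a set of reports
#'
#' @param cases a `faers_cases` object.
#' @param ids primaryids to keep.
#' @return filtered `faers_cases`.
#' @export
subset_cases <- function(cases, ids) {
  keep <- function(df) df[df$primaryid %in% ids, , drop = FALSE]
  faers_cases(keep(cases$reports), keep(cases$records), keep(cases$drugs),
              keep(cases$outcomes), cases$meta)
}

#' Assemble per-report case records
#'
#' Integrates the parsed quarterly tables into one [faers_cases()] container
#' for the retained (deduplicated, deletion-filtered) reports.  Ages are
#' converted to years (DEC x10, MON /12, WK /52.14, DY /365.25, HR /8766),
#' weights to kilograms (LBS x 0.453592); non-positive values become missing.
#' Each report's earliest valid full therapy start date among target-drug
#' rows is kept for time-to-onset work, and duplicate PTs within a report
#' collapse to a single PT record.  Reports without any reaction row are
#' excluded and counted in `meta$n_no_reac`.
#'
#' @param tables a `faers_tables` object from [read_faers_quarter()].
#' @param retained character vector of retained `primaryid`s.
#' @param target_synonyms synonym list identifying the target drug.
#' @param pt_soc data frame mapping `pt` to `soc` (unmapped PTs get
#'   `"UNMAPPED"`), or `NULL`.
#' @param role role code defining target exposure (default `"PS"`).
#' @return a `faers_cases` object covering all retained reports, with
#'   `reports$is_target` marking reports where the target drug holds the
#'   requested role.
#' @export
assemble_cases <- function(tables, retained, target_synonyms, pt_soc = NULL,
                           role = "PS") {
  demo <- tables$demo[as.character(tables$demo$primaryid) %in% retained, ,
                      drop = FALSE]
  demo$primaryid <- as.character(demo$primaryid)

  reac <- tables$reac
  reac$primaryid <- as.character(reac$primaryid)
  reac <- reac[reac$primaryid %in% demo$primaryid & trimws(reac$pt) != "", ,
               drop = FALSE]
  has_reac <- demo$primaryid %in% reac$primaryid
  n_no_reac <- sum(!has_reac)
  demo <- demo[has_reac, , drop = FALSE]
  ids <- demo$primaryid

  records <- unique(data.frame(primaryid = reac$primaryid,
                               pt = trimws(reac$pt),
                               stringsAsFactors = FALSE))
  records$soc <- map_pt_to_soc(records$pt, pt_soc)

  drug <- tables$drug[as.character(tables$drug$primaryid) %in% ids, ,
                      drop = FALSE]
  drug$primaryid <- as.character(drug$primaryid)
  drug$drugname_norm <- normalize_drug_name(drug$drugname)
  syn <- normalize_drug_name(target_synonyms)
  drug$is_target <- drug$drugname_norm %in% syn &
    toupper(trimws(drug$role_cod)) == role

  ## demographics with unit normalization
  age_val <- suppressWarnings(as.numeric(demo$age))
  cod <- toupper(trimws(demo$age_cod %||% rep("", nrow(demo))))
  cod[cod == ""] <- "YR"
  fac <- age_unit_factor[cod]
  fac[is.na(fac)] <- NA_real_
  age_yr <- age_val * fac
  age_yr[!is.na(age_yr) & age_yr < 0] <- NA_real_

  wt_val <- suppressWarnings(as.numeric(demo$wt))
  wt_cod <- toupper(trimws(demo$wt_cod %||% rep("", nrow(demo))))
  weight_kg <- ifelse(wt_cod == "LBS", wt_val * LBS_PER_KG, wt_val)
  weight_kg[!is.na(weight_kg) & weight_kg <= 0] <- NA_real_

  sex <- toupper(trimws(demo$sex %||% rep("", nrow(demo))))
  sex[!(sex %in% c("F", "M"))] <- NA_character_

  reporter <- toupper(trimws(demo$occp_cod %||% rep("", nrow(demo))))
  reporter[reporter == ""] <- NA_character_
  country <- trimws(demo$reporter_country %||% rep("", nrow(demo)))
  country[country == ""] <- NA_character_

  fda <- parse_faers_date(demo$fda_dt)
  year <- ifelse(fda$precision %in% c("day", "month", "year"),
                 as.integer(substr(fda$raw, 1L, 4L)), NA_integer_)
  evt <- parse_faers_date(demo$event_dt %||% rep("", nrow(demo)))

  ## earliest valid full start date among target-drug therapy rows
  ther <- tables$ther
  ther$primaryid <- as.character(ther$primaryid)
  tkey <- paste(drug$primaryid[drug$is_target],
                trimws(drug$drug_seq[drug$is_target]))
  tther <- ther[paste(ther$primaryid, trimws(ther$dsg_drug_seq)) %in% tkey, ,
                drop = FALSE]
  sd <- parse_faers_date(tther$start_dt)
  start_date <- rep(as.Date(NA), length(ids))
  start_precision <- rep("missing", length(ids))
  if (nrow(tther)) {
    ## best precision seen per report, for exclusion accounting
    prec_rank <- c(day = 3L, month = 2L, year = 1L, invalid = 0L,
                   missing = 0L)
    agg_best <- tapply(prec_rank[sd$precision], tther$primaryid, max)
    idx <- match(names(agg_best), ids)
    start_precision[idx[!is.na(idx)]] <-
      c("missing", "partial", "partial", "day")[agg_best[!is.na(idx)] + 1L]
    ok <- sd$precision == "day"
    if (any(ok)) {
      mins <- tapply(as.numeric(sd$date[ok]), tther$primaryid[ok], min)
      idx <- match(names(mins), ids)
      start_date[idx[!is.na(idx)]] <-
        as.Date(as.numeric(mins[!is.na(idx)]), origin = "1970-01-01")
    }
  }

  outc <- tables$outc
  outc$primaryid <- as.character(outc$primaryid)
  outc <- unique(outc[outc$primaryid %in% ids &
                        trimws(outc$outc_cod) != "",
                      c("primaryid", "outc_cod")])
  outc$outc_cod <- toupper(trimws(outc$outc_cod))
  fatal <- ids %in% outc$primaryid[outc$outc_cod == "DE"]

  indi <- tables$indi
  indi$primaryid <- as.character(indi$primaryid)
  indi <- indi[indi$primaryid %in% ids & trimws(indi$indi_pt) != "", ,
               drop = FALSE]
  indication <- trimws(indi$indi_pt)[match(ids, indi$primaryid)]

  ## dosing fields from the first target drug row per report
  tg <- drug[drug$is_target, , drop = FALSE]
  first <- !duplicated(tg$primaryid)
  frequency <- toupper(trimws(tg$dose_freq[first]))[match(ids,
                                                          tg$primaryid[first])]
  frequency[!is.na(frequency) & frequency == ""] <- NA_character_
  dose <- trimws(tg$dose_amt[first])[match(ids, tg$primaryid[first])]
  dose[!is.na(dose) & dose == ""] <- NA_character_

  n_pts <- as.integer(table(records$primaryid)[ids])
  other_drug <- tapply(!(drug$drugname_norm %in% syn), drug$primaryid, any)
  monotherapy <- !as.logical(other_drug[ids])
  monotherapy[is.na(monotherapy)] <- TRUE
  is_target <- ids %in% drug$primaryid[drug$is_target]

  reports <- data.frame(
    primaryid = ids,
    caseid = as.character(demo$caseid),
    age_yr = age_yr,
    sex = sex,
    weight_kg = weight_kg,
    reporter = reporter,
    country = country,
    year = year,
    quarter = demo$report_quarter %||% rep(NA_character_, length(ids)),
    event_date = evt$date,
    event_precision = ifelse(evt$precision %in% c("month", "year"),
                             "partial", evt$precision),
    start_date = start_date,
    start_precision = start_precision,
    frequency = frequency,
    dose = dose,
    indication = indication,
    n_pts = n_pts,
    fatal = fatal,
    monotherapy = monotherapy,
    is_target = is_target,
    stringsAsFactors = FALSE
  )
  faers_cases(reports, records,
              drugs = drug[, c("primaryid", "drug_seq", "role_cod",
                               "drugname", "drugname_norm", "is_target")],
              outcomes = outc,
              meta = list(n_no_reac = n_no_reac,
                          n_retained_input = length(retained)))
}
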