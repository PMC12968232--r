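#' Deduplicate FAERS case versions
#'
#' A FAERS case (CASEID) can appear as several report versions (PRIMARYID)
#' across quarters.  Following the FDA-recommended rule, the version with the
#' most recent FDA_DT is retained per CASEID; ties on FDA_DT are broken by
#' keeping the highest PRIMARYID.  FDA_DT values that are not 8-digit dates
#' sort as oldest, so a parseable version always wins over an unparseable one.
#'
#' @param demo DEMO table (data frame with `primaryid`, `caseid`, `fda_dt`).
#' @return character vector of retained `primaryid`s (one per caseid).
#' @export
deduplicate_cases <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  pid <- as.character(demo$primaryid)
  if (anyNA(pid) || any(pid == "")) stop("empty primaryid in DEMO")
  if (anyDuplicated(pid)) {
    stop("duplicate primaryid within DEMO input; keys must be unique")
  }
  fda <- as.character(demo$fda_dt)
  fda_key <- suppressWarnings(as.numeric(ifelse(grepl("^[0-9]{8}$", fda),
                                                fda, NA)))
  fda_key[is.na(fda_key)] <- -Inf      # unparseable sorts as oldest
  pid_key <- suppressWarnings(as.numeric(pid))
  if (anyNA(pid_key)) pid_key <- xtfrm(pid)  # non-numeric ids: lexicographic
  ord <- order(as.character(demo$caseid), fda_key, pid_key)
  keep <- !duplicated(as.character(demo$caseid)[ord], fromLast = TRUE)
  sort(pid[ord][keep])
}

#' Remove reports whose case appears in a deleted-case list
#'
#' From 2019Q4 onward FAERS quarters ship lists of case numbers the FDA has
#' withdrawn; retained reports whose CASEID appears there are excluded.  An
#' empty deleted list (earlier quarters) leaves the input unchanged.
#'
#' @param retained character vector of retained `primaryid`s.
#' @param demo DEMO table mapping `primaryid` to `caseid`.
#' @param deleted_caseids character vector of deleted CASEIDs (may be empty).
#' @return filtered character vector of `primaryid`s.
#' @export
remove_deleted_cases <- function(retained, demo, deleted_caseids) {
  if (length(deleted_caseids) == 0L) return(retained)
  caseid <- as.character(demo$caseid)[match(retained,
                                            as.character(demo$primaryid))]
  retained[!(caseid %in% as.character(deleted_caseids))]
}

#' Select reports naming a drug of interest in a given role
#'
#' Matching is exact on normalized names (see [normalize_drug_name()])
#' against a synonym list covering generic and brand spellings, restricted to
#' the requested FAERS role code (default `"PS"`, primary suspect).
#'
#' @param drug DRUG table (data frame with `primaryid`, `drugname`,
#'   `role_cod`).
#' @param synonyms character vector of drug name synonyms (non-empty).
#' @param role FAERS role code: one of `"PS"`, `"SS"`, `"C"`, `"I"`.
#' @return character vector of unique matching `primaryid`s.
#' @export
select_drug_reports <- function(drug, synonyms, role = "PS") {
  if (length(synonyms) == 0L) stop("synonym set must not be empty")
  role <- match.arg(role, c("PS", "SS", "C", "I"))
  syn <- normalize_drug_name(synonyms)
  hit <- normalize_drug_name(drug$drugname) %in% syn &
    toupper(trimws(drug$role_cod)) == role
  sort(unique(as.character(drug$primaryid)[hit]))
}
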