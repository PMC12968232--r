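## FAERS quarterly ASCII ingestion: "$"-delimited tables, first line a header.
## Only the post-2014 layout is supported.

faers_table_names <- c("demo", "drug", "reac", "indi", "ther", "outc")

faers_required_cols <- list(
  demo = c("primaryid", "caseid", "fda_dt"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  indi = c("primaryid", "indi_pt"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt"),
  outc = c("primaryid", "outc_cod")
)

## Read one "$"-delimited table.  Tolerates a trailing delimiter; rows whose
## field count still disagrees with the header are counted as malformed and
## dropped, never fatal.  Non-UTF-8 bytes fall back to latin1 with
## replacement, and the replacement count is recorded.
read_dollar_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  bad <- !validUTF8(lines)
  n_repaired <- sum(bad)
  if (n_repaired > 0) {
    lines[bad] <- iconv(lines[bad], from = "latin1", to = "UTF-8", sub = "?")
  }
  parts <- strsplit(lines, "$", fixed = TRUE)
  header <- tolower(trimws(parts[[1]]))
  header <- header[header != ""]
  nh <- length(header)
  body <- parts[-1]
  ## trailing "$" produces one extra empty field; strsplit also drops
  ## trailing empty fields entirely, so short rows are padded with ""
  body <- lapply(body, function(p) {
    if (length(p) == nh + 1L && p[length(p)] == "") p <- p[-length(p)]
    if (length(p) < nh) p <- c(p, rep("", nh - length(p)))
    p
  })
  lens <- lengths(body)
  malformed <- sum(lens != nh)
  body <- body[lens == nh]
  if (length(body)) {
    m <- matrix(unlist(body, use.names = FALSE), ncol = nh, byrow = TRUE)
  } else {
    m <- matrix(character(0), ncol = nh)
  }
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- header
  attr(df, "malformed") <- malformed
  attr(df, "repaired_encoding") <- n_repaired
  df
}

## "2016q1", "2016Q1" and "16Q1" all resolve to the file tag "16Q1"
quarter_tag <- function(quarter) {
  q <- toupper(trimws(quarter))
  if (grepl("^[0-9]{4}Q[1-4]$", q)) q <- substr(q, 3L, 6L)
  if (!grepl("^[0-9]{2}Q[1-4]$", q)) {
    stop("cannot interpret quarter identifier: ", quarter)
  }
  q
}

#' Read one FAERS quarter from disk
#'
#' Expects the seven-table quarterly layout as "$"-delimited ASCII files named
#' `DEMO16Q1.txt`, `DRUG16Q1.txt`, `REAC16Q1.txt`, `INDI16Q1.txt`,
#' `THER16Q1.txt`, `OUTC16Q1.txt` (the RPSR table is not used by any analysis
#' here and is ignored if present), plus an optional deleted-case list
#' `DELETED16Q1.txt` with one CASEID per line (deleted-case files exist only
#' from 2019Q4 onward).
#'
#' @param dir directory holding the quarter's files.
#' @param quarter quarter identifier, e.g. `"2016q1"` or `"16Q1"`.
#' @return An object of class `faers_tables`: a list with the six parsed
#'   tables (all-character data frames with lower-case column names), a
#'   `deleted_caseids` character vector, and attributes `quarter` and
#'   `malformed` (per-table dropped-row counts).
#' @export
read_faers_quarter <- function(dir, quarter) {
  tag <- quarter_tag(quarter)
  out <- list()
  malformed <- integer(0)
  for (tab in faers_table_names) {
    fname <- file.path(dir, paste0(toupper(tab), tag, ".txt"))
    if (!file.exists(fname)) {
      stop(sprintf("missing FAERS table file for %s: %s",
                   toupper(tab), fname))
    }
    df <- read_dollar_table(fname)
    need <- faers_required_cols[[tab]]
    if (!all(need %in% names(df))) {
      stop(sprintf("%s table lacks required columns: %s", toupper(tab),
                   paste(setdiff(need, names(df)), collapse = ", ")))
    }
    malformed[tab] <- attr(df, "malformed")
    df$report_quarter <- rep(tag, nrow(df))
    out[[tab]] <- df
  }
  del_file <- file.path(dir, paste0("DELETED", tag, ".txt"))
  out$deleted_caseids <- if (file.exists(del_file)) {
    unique(trimws(readLines(del_file, warn = FALSE)))
  } else {
    character(0)
  }
  out$deleted_caseids <- out$deleted_caseids[out$deleted_caseids != ""]
  structure(out, class = "faers_tables", quarter = tag, malformed = malformed)
}

## Stack several quarters into one table set (deleted lists are unioned).
bind_faers_quarters <- function(quarters) {
  stopifnot(length(quarters) >= 1L)
  if (length(quarters) == 1L) return(quarters[[1L]])
  out <- lapply(faers_table_names, function(tab) {
    do.call(rbind, lapply(quarters, `[[`, tab))
  })
  names(out) <- faers_table_names
  out$deleted_caseids <- unique(unlist(lapply(quarters, `[[`,
                                              "deleted_caseids")))
  structure(out, class = "faers_tables",
            quarter = vapply(quarters, attr, "", "quarter"))
}

#' Read a newline-delimited term list
#'
#' Used for drug synonym lists and for label / DME / IME preferred-term lists.
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return character vector of unique trimmed terms.
#' @export
read_term_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[x != "" & !startsWith(x, "#")])
}

#' Read a PT to SOC mapping table
#'
#' A two-column tab-separated file with header `pt<TAB>soc`, supplied by the
#' user (the MedDRA dictionary is licensed and is never bundled).
#'
#' @param path file path.
#' @return data frame with columns `pt` and `soc`.
#' @export
read_pt_soc_map <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "", stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("pt", "soc") %in% names(df))) {
    stop("PT->SOC mapping must have columns 'pt' and 'soc'")
  }
  df[, c("pt", "soc")]
}

#' Map preferred terms to system organ classes
#'
#' Terms absent from the mapping keep the sentinel class `"UNMAPPED"` so that
#' every PT record is attributed to exactly one SOC.
#'
#' @param pts character vector of PTs.
#' @param map data frame as returned by [read_pt_soc_map()], or `NULL`.
#' @return character vector of SOCs, same length as `pts`.
#' @export
map_pt_to_soc <- function(pts, map = NULL) {
  if (is.null(map) || nrow(map) == 0L) {
    return(rep("UNMAPPED", length(pts)))
  }
  soc <- map$soc[match(pts, map$pt)]
  soc[is.na(soc)] <- "UNMAPPED"
  soc
}
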