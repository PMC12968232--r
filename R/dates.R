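#' Parse raw FAERS date strings
#'
#' FAERS date fields are written as `YYYYMMDD` when complete, but partial
#' (`YYYYMM`, `YYYY`), empty, and frankly impossible values (month 13, day 40)
#' all occur.  Partial dates are usable for year tabulations but not for
#' time-to-onset computation; impossible values are flagged invalid.
#'
#' @param x character vector of raw date strings.
#' @return A data frame with one row per input: `raw` (the trimmed input),
#'   `precision` (`"day"`, `"month"`, `"year"`, `"missing"`, or `"invalid"`),
#'   and `date` (a `Date`, non-`NA` only when `precision == "day"`).
#' @export
#' @examples
#' parse_faers_date(c("20150801", "201508", "2015", "", "20151340"))
parse_faers_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- trimws(x)
  n <- length(x)
  precision <- rep("invalid", n)
  precision[x == ""] <- "missing"
  date <- rep(as.Date(NA), n)
  digits <- grepl("^[0-9]+$", x)

  full <- which(digits & nchar(x) == 8L)
  if (length(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    yr <- as.integer(substr(x[full], 1L, 4L))
    ok <- !is.na(d) & yr >= 1900L & yr <= 2100L
    precision[full[ok]] <- "day"
    date[full[ok]] <- d[ok]
  }
  mo6 <- which(digits & nchar(x) == 6L)
  if (length(mo6)) {
    yr <- as.integer(substr(x[mo6], 1L, 4L))
    mo <- as.integer(substr(x[mo6], 5L, 6L))
    ok <- yr >= 1900L & yr <= 2100L & mo >= 1L & mo <= 12L
    precision[mo6[ok]] <- "month"
  }
  yr4 <- which(digits & nchar(x) == 4L)
  if (length(yr4)) {
    yr <- as.integer(x[yr4])
    precision[yr4[yr >= 1900L & yr <= 2100L]] <- "year"
  }
  data.frame(raw = x, precision = precision, date = date,
             stringsAsFactors = FALSE)
}
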