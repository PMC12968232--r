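`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a drug name for matching
#'
#' Uppercases, trims, and collapses runs of whitespace and punctuation (other
#' than "/") to a single space, so that e.g. `" Orkambi "` and `"ORKAMBI"`
#' compare equal.  Matching against synonym lists is exact on the normalized
#' string, never substring, so `"IVACAFTOR"` does not match combination
#' products such as `"LUMACAFTOR/IVACAFTOR"`.
#'
#' @param x character vector of raw drug names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_drug_name(c(" Orkambi ", "lumacaftor / ivacaftor"))
normalize_drug_name <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("[^A-Z0-9/]+", " ", x)
  x <- gsub(" */ *", "/", x)
  trimws(gsub(" +", " ", x))
}

## deterministic TSV writer used for all pipeline outputs (numerics to 4 dp)
write_result_tsv <- function(df, path, digits = 4) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, digits))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

stop_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}
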