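#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace so that symbol-keyed joins
#' across sources (GWAS tables, curated lists, interaction tables) behave as
#' set operations. Applied before any merge or graph construction.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
#' @examples
#' normalizeSymbols(c(" tp53 ", "Braf"))
normalizeSymbols <- function(x) {
  toupper(trimws(as.character(x)))
}

## internal TSV helpers: all pipeline tables are plain tab-separated text
.readTsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

## split a ';'-joined field into a character vector; empty -> character(0)
.splitField <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  out <- trimws(strsplit(as.character(x), ";", fixed = TRUE)[[1]])
  out[nzchar(out)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
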