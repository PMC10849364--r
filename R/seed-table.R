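#' Read a plain gene list
#'
#' One symbol per line; blank lines and '#' comments are ignored; symbols are
#' normalized (uppercased, trimmed). Duplicates within one list collapse with
#' a warning, since curated lists are keyed by symbol.
#'
#' @param path file path.
#' @return character vector of unique symbols.
#' @export
readGeneList <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  syms <- normalizeSymbols(lines[nzchar(trimws(lines))])
  if (anyDuplicated(syms)) {
    warning(sprintf("%d duplicated symbol(s) collapsed in %s",
                    sum(duplicated(syms)), path))
    syms <- unique(syms)
  }
  syms
}

#' Merge GWAS, familial and somatic gene lists into a seed table
#'
#' The three provenance lists are unioned into the unique risk-gene table;
#' each gene keeps a flag per source list it appears in. CDKN2A-style loci
#' encoding several proteins are naturally a single node because the table is
#' keyed by gene symbol.
#'
#' @param gwas,familial,somatic character vectors of gene symbols (possibly
#'   overlapping; normalized internally; within-list duplicates collapse with
#'   a warning).
#' @return a [SeedTable-class].
#' @export
#' @examples
#' st <- mergeSeedLists(c("MITF", "TERT"), c("MITF", "CDKN2A"), c("BRAF"))
#' seedComposition(st)
mergeSeedLists <- function(gwas, familial, somatic) {
  norm1 <- function(x, what) {
    x <- normalizeSymbols(x)
    x <- x[nzchar(x)]
    if (anyDuplicated(x)) {
      warning(sprintf("%d duplicated symbol(s) collapsed in %s list",
                      sum(duplicated(x)), what))
      x <- unique(x)
    }
    x
  }
  gwas <- norm1(gwas, "GWAS")
  familial <- norm1(familial, "familial")
  somatic <- norm1(somatic, "somatic")
  if (length(gwas) + length(familial) + length(somatic) == 0)
    stop("no seed genes: all three input lists are empty", call. = FALSE)
  syms <- sort(unique(c(gwas, familial, somatic)))
  tb <- data.frame(symbol = syms,
                   gwas = syms %in% gwas,
                   familial = syms %in% familial,
                   somatic = syms %in% somatic,
                   stringsAsFactors = FALSE)
  new("SeedTable", table = tb)
}

#' Write / read a seed table as TSV
#'
#' The on-disk form has the symbol column plus 0/1 source columns and
#' round-trips losslessly. Reading validates uniqueness and that every row
#' keeps at least one source.
#'
#' @param object a [SeedTable-class].
#' @param path file path.
#' @return \code{writeSeedTable} returns the path invisibly;
#'   \code{readSeedTable} returns a [SeedTable-class].
#' @export
writeSeedTable <- function(object, path) {
  stopifnot(is(object, "SeedTable"))
  tb <- object@table
  out <- data.frame(symbol = tb$symbol,
                    gwas = as.integer(tb$gwas),
                    familial = as.integer(tb$familial),
                    somatic = as.integer(tb$somatic))
  .writeTsv(out, path)
}

#' @rdname writeSeedTable
#' @export
readSeedTable <- function(path) {
  df <- .readTsv(path)
  .assert(all(c("symbol", "gwas", "familial", "somatic") %in% names(df)),
          "seed table file needs symbol, gwas, familial, somatic columns")
  tb <- data.frame(symbol = normalizeSymbols(df$symbol),
                   gwas = df$gwas == 1,
                   familial = df$familial == 1,
                   somatic = df$somatic == 1,
                   stringsAsFactors = FALSE)
  new("SeedTable", table = tb)   # validity rejects dup symbols / empty sources
}
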