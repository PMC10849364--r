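#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

## ---- input checking ---------------------------------------------------

.checkSnps <- function(snps) {
  .assert(all(c("rsid", "chrom", "pos") %in% names(snps)),
          "SNP table needs columns rsid, chrom, pos")
  .assert(!anyDuplicated(snps$rsid), "duplicated rsid in SNP table")
  .assert(all(snps$pos >= 1), "SNP positions must be >= 1")
  snps
}

.checkIntervals <- function(df, what) {
  .assert(all(c("start", "end") %in% names(df)),
          sprintf("%s needs start/end columns", what))
  bad <- df$start > df$end
  if (any(bad))
    stop(sprintf("%s: malformed interval (start > end) in %d row(s)",
                 what, sum(bad)), call. = FALSE)
  .assert(all(df$start >= 1), sprintf("%s: start must be >= 1", what))
  df
}

.grFromDf <- function(df) {
  GenomicRanges::GRanges(as.character(df$chrom),
                         IRanges::IRanges(df$start, df$end))
}

## ---- SNP classification -----------------------------------------------

#' Classify risk SNPs as coding, intronic or intergenic
#'
#' A marker is \code{coding} when it falls inside an exon or 3' UTR of a
#' protein-coding open reading frame, \code{intronic} when it lies inside an
#' ORF span but outside every exon/UTR, and \code{intergenic} otherwise.
#' Coordinates are 1-based and intervals inclusive on both ends.
#'
#' @param snps data.frame with columns \code{rsid}, \code{chrom}, \code{pos}.
#' @param geneModels data.frame with columns \code{symbol}, \code{chrom},
#'   \code{start}, \code{end}, \code{feature} where feature is one of
#'   \code{exon}, \code{intron}, \code{utr3}, \code{span}. Gene spans missing
#'   an explicit \code{span} row are derived as the range of the gene's
#'   features.
#' @return the \code{snps} data.frame with an added \code{category} column and
#'   a \code{host_genes} column (';'-joined symbols of the coding ORFs hosting
#'   a coding SNP; empty otherwise). A SNP inside exons of several overlapping
#'   ORFs is attached to all of them.
#' @export
classifySnps <- function(snps, geneModels) {
  snps <- .checkSnps(snps)
  gm <- .checkIntervals(geneModels, "gene models")
  .assert(all(gm$feature %in% c("exon", "intron", "utr3", "span")),
          "gene model feature must be exon|intron|utr3|span")
  gm$symbol <- normalizeSymbols(gm$symbol)

  snpGr <- GenomicRanges::GRanges(as.character(snps$chrom),
                                  IRanges::IRanges(snps$pos, snps$pos))

  coding <- gm[gm$feature %in% c("exon", "utr3"), , drop = FALSE]
  ## ORF extent: explicit span rows, plus per-symbol feature range
  spanList <- lapply(split(gm, gm$symbol), function(d) {
    data.frame(symbol = d$symbol[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end))
  })
  spans <- do.call(rbind, spanList)

  category <- rep("intergenic", nrow(snps))
  hosts <- rep("", nrow(snps))
  if (nrow(coding) > 0) {
    ov <- GenomicRanges::findOverlaps(snpGr, .grFromDf(coding))
    if (length(ov) > 0) {
      hit <- S4Vectors::queryHits(ov)
      category[unique(hit)] <- "coding"
      hg <- tapply(coding$symbol[S4Vectors::subjectHits(ov)], hit,
                   function(s) paste(sort(unique(s)), collapse = ";"))
      hosts[as.integer(names(hg))] <- as.character(hg)
    }
  }
  if (!is.null(spans) && nrow(spans) > 0) {
    ov <- GenomicRanges::findOverlaps(snpGr, .grFromDf(spans))
    inSpan <- unique(S4Vectors::queryHits(ov))
    category[setdiff(inSpan, which(category == "coding"))] <- "intronic"
  }
  snps$category <- category
  snps$host_genes <- hosts
  snps
}

## ---- locus construction -----------------------------------------------

#' Build physical-distance (PD) loci around risk markers
#'
#' Draws a window of +/- \code{halfWindow} bp (default 250 kb) around each
#' marker, clipped at position 1 on the chromosome start; there is no upper
#' clipping since assembly lengths are not required.
#'
#' @param snps data.frame with \code{rsid}, \code{chrom}, \code{pos}.
#' @param halfWindow half window size in bp.
#' @return data.frame with \code{rsid}, \code{chrom}, \code{start},
#'   \code{end}, \code{method = "PD"}.
#' @export
buildPdLocus <- function(snps, halfWindow = 250000) {
  snps <- .checkSnps(snps)
  .assert(halfWindow >= 0, "halfWindow must be >= 0")
  if (nrow(snps) == 0)
    return(data.frame(rsid = character(), chrom = character(),
                      start = integer(), end = integer(),
                      method = character(), stringsAsFactors = FALSE))
  data.frame(rsid = snps$rsid, chrom = as.character(snps$chrom),
             start = pmax(1, snps$pos - halfWindow),
             end = snps$pos + halfWindow,
             method = "PD", stringsAsFactors = FALSE)
}

#' Build linkage-disequilibrium (LD) loci
#'
#' The LD locus of a marker spans the minimum to maximum position over the
#' marker itself and all its proxies with r^2 >= \code{r2Min} (threshold
#' inclusive). A marker with no row at all in the proxy table is treated as
#' absent from the LD panel and receives no LD locus (presence without
#' passing proxies is encoded by a self row, rsid -> rsid with r^2 = 1).
#' Markers inside \code{hlaRegion} are excluded from LD locus construction
#' (the physical-distance locus still applies to them).
#'
#' @param snps data.frame with \code{rsid}, \code{chrom}, \code{pos}.
#' @param proxies data.frame with \code{rsid}, \code{proxy_rsid}, \code{r2},
#'   \code{proxy_pos}.
#' @param r2Min minimum squared correlation, default 0.8.
#' @param hlaRegion optional list/one-row data.frame with \code{chrom},
#'   \code{start}, \code{end} delimiting the HLA interval.
#' @return data.frame with \code{rsid}, \code{chrom}, \code{start},
#'   \code{end}, \code{method = "LD"}; markers absent from the panel or in
#'   the HLA region are omitted.
#' @export
buildLdLocus <- function(snps, proxies, r2Min = 0.8, hlaRegion = NULL) {
  snps <- .checkSnps(snps)
  .assert(all(c("rsid", "proxy_rsid", "r2", "proxy_pos") %in% names(proxies)),
          "proxy table needs rsid, proxy_rsid, r2, proxy_pos")
  if (nrow(proxies) > 0)
    .assert(all(proxies$r2 >= 0 & proxies$r2 <= 1), "r2 outside [0, 1]")

  inHla <- rep(FALSE, nrow(snps))
  if (!is.null(hlaRegion)) {
    inHla <- as.character(snps$chrom) == as.character(hlaRegion$chrom) &
      snps$pos >= hlaRegion$start & snps$pos <= hlaRegion$end
  }
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    if (inHla[i]) return(NULL)
    pr <- proxies[proxies$rsid == snps$rsid[i], , drop = FALSE]
    if (nrow(pr) == 0) return(NULL)        # marker absent from the LD panel
    keep <- pr$r2 >= r2Min
    posns <- c(snps$pos[i], pr$proxy_pos[keep])
    data.frame(rsid = snps$rsid[i], chrom = as.character(snps$chrom[i]),
               start = min(posns), end = max(posns), method = "LD",
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(rsid = character(), chrom = character(),
                      start = integer(), end = integer(),
                      method = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Map genomic elements to loci
#'
#' Returns the elements whose interval overlaps a locus by at least one base
#' pair (inclusive-inclusive coordinates), per locus, same chromosome only.
#'
#' @param loci data.frame of loci as returned by [buildPdLocus()] /
#'   [buildLdLocus()] (one or more rows).
#' @param elements data.frame with \code{symbol}, \code{name}, \code{chrom},
#'   \code{start}, \code{end}.
#' @return data.frame with columns \code{rsid}, \code{method}, \code{symbol}.
#' @export
mapElementsToLocus <- function(loci, elements) {
  loci <- .checkIntervals(loci, "loci")
  elements <- .checkIntervals(elements, "elements")
  empty <- data.frame(rsid = character(), method = character(),
                      symbol = character(), stringsAsFactors = FALSE)
  if (nrow(loci) == 0 || nrow(elements) == 0) return(empty)
  ## disjoint chromosome sets between loci and elements are routine
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(.grFromDf(loci), .grFromDf(elements)))
  if (length(ov) == 0) return(empty)
  out <- data.frame(rsid = loci$rsid[S4Vectors::queryHits(ov)],
                    method = loci$method[S4Vectors::queryHits(ov)],
                    symbol = normalizeSymbols(
                      elements$symbol[S4Vectors::subjectHits(ov)]),
                    stringsAsFactors = FALSE)
  unique(out)
}

## ---- biotype keyword filter -------------------------------------------

#' Keywords flagging non-protein-coding genomic elements
#'
#' Elements whose name contains one of these (case-insensitive substrings)
#' are dropped when compiling the protein-coding candidate list. The list
#' includes both "Incrna" and "lncrna" spellings so either rendering of the
#' long-noncoding keyword is caught.
#'
#' @return character vector of keywords.
#' @export
defaultExclusionKeywords <- function() {
  c("nan", "none", "pseudogene", "novel", "antisense", "microRNA",
    "IncRNA", "lncRNA", "small nucleolar RNA", "yRNA", "TEC",
    "readthrough", "intergenic", "intronic")
}

#' Filter genomic elements down to protein-coding candidates
#'
#' Removes every element whose \code{name} contains any exclusion keyword
#' (case-insensitive substring match) and any element whose symbol is empty
#' after normalization. Idempotent.
#'
#' @param elements data.frame with \code{symbol} and \code{name} columns.
#' @param keywords keyword vector, default [defaultExclusionKeywords()].
#' @return filtered data.frame.
#' @export
filterCodingElements <- function(elements, keywords = defaultExclusionKeywords()) {
  nm <- tolower(as.character(elements$name))
  drop <- rep(FALSE, nrow(elements))
  for (kw in tolower(keywords)) drop <- drop | grepl(kw, nm, fixed = TRUE)
  out <- elements[!drop, , drop = FALSE]
  out$symbol <- normalizeSymbols(out$symbol)
  out[nzchar(out$symbol), , drop = FALSE]
}

## ---- eQTL join ---------------------------------------------------------

#' Join noncoding markers to their skin eQTL target genes
#'
#' Unions the eQTL target genes over the two skin tissues
#' (\code{skin_sun_exposed}, \code{skin_not_sun_exposed}) per marker. Only
#' noncoding (intronic/intergenic) markers may be passed; coding markers are
#' already resolved to their host gene.
#'
#' @param snps classified SNP data.frame (needs a \code{category} column)
#'   restricted to noncoding categories.
#' @param eqtls data.frame with \code{rsid}, \code{symbol}, \code{tissue}.
#' @return named list, rsid -> character vector of target symbols (possibly
#'   empty).
#' @export
joinEqtl <- function(snps, eqtls) {
  .assert("category" %in% names(snps), "snps must be classified first")
  if (any(snps$category == "coding"))
    stop("joinEqtl: coding markers passed in; restrict to noncoding SNPs",
         call. = FALSE)
  .assert(all(c("rsid", "symbol", "tissue") %in% names(eqtls)),
          "eQTL table needs rsid, symbol, tissue")
  if (nrow(eqtls) > 0)
    .assert(all(eqtls$tissue %in% c("skin_sun_exposed", "skin_not_sun_exposed")),
            "eQTL tissue must be skin_sun_exposed or skin_not_sun_exposed")
  out <- lapply(snps$rsid, function(rs) {
    sort(unique(normalizeSymbols(eqtls$symbol[eqtls$rsid == rs])))
  })
  names(out) <- snps$rsid
  out
}

## ---- full prioritization ----------------------------------------------

#' Prioritize candidate genes from GWAS risk markers
#'
#' The full locus-to-gene workflow: markers are classified
#' (coding/intronic/intergenic); coding markers resolve to their host genes
#' with evidence \code{coding}; for each noncoding marker, candidate genes
#' are collected from the +/-250 kb physical-distance locus, the r^2 >= 0.8
#' LD locus, and skin eQTL associations, after dropping non-protein-coding
#' elements by keyword. Each gene carries its evidence flags and the markers
#' it traces to.
#'
#' @param snps data.frame with \code{rsid}, \code{chrom}, \code{pos}.
#' @param geneModels gene-model table, see [classifySnps()].
#' @param elements genomic-element table, see [mapElementsToLocus()].
#' @param proxies LD proxy table, see [buildLdLocus()].
#' @param eqtls eQTL table, see [joinEqtl()].
#' @param halfWindow PD half window (bp), default 250000.
#' @param r2Min LD threshold, default 0.8.
#' @param hlaRegion optional HLA interval, see [buildLdLocus()].
#' @param keywords element exclusion keywords.
#' @return list with \code{genes} (data.frame: symbol, coding, pd, ld, eqtl
#'   logical flags, source_rsids ';'-joined), \code{snps} (classified marker
#'   table) and \code{composition} (evidence-combination counts, see
#'   [evidenceComposition()]).
#' @export
prioritizeGenes <- function(snps, geneModels, elements, proxies, eqtls,
                            halfWindow = 250000, r2Min = 0.8,
                            hlaRegion = NULL,
                            keywords = defaultExclusionKeywords()) {
  cls <- classifySnps(snps, geneModels)
  noncoding <- cls[cls$category != "coding", , drop = FALSE]
  codingSnps <- cls[cls$category == "coding", , drop = FALSE]
  keepEl <- filterCodingElements(elements, keywords)

  pdHits <- mapElementsToLocus(buildPdLocus(noncoding, halfWindow), keepEl)
  ldHits <- mapElementsToLocus(
    buildLdLocus(noncoding, proxies, r2Min, hlaRegion), keepEl)
  eq <- joinEqtl(noncoding, eqtls)

  ## accumulate per-gene evidence
  ev <- new.env(parent = emptyenv())
  addEv <- function(symbol, flag, rsid) {
    for (i in seq_along(symbol)) {
      s <- symbol[i]
      rec <- get0(s, envir = ev,
                  ifnotfound = list(coding = FALSE, pd = FALSE, ld = FALSE,
                                    eqtl = FALSE, rsids = character(0)))
      rec[[flag]] <- TRUE
      rec$rsids <- union(rec$rsids, rsid[i])
      assign(s, rec, envir = ev)
    }
  }
  if (nrow(codingSnps) > 0) {
    for (i in seq_len(nrow(codingSnps))) {
      hg <- .splitField(codingSnps$host_genes[i])
      addEv(hg, "coding", rep(codingSnps$rsid[i], length(hg)))
    }
  }
  if (nrow(pdHits) > 0) addEv(pdHits$symbol, "pd", pdHits$rsid)
  if (nrow(ldHits) > 0) addEv(ldHits$symbol, "ld", ldHits$rsid)
  for (rs in names(eq)) {
    if (length(eq[[rs]]) > 0) addEv(eq[[rs]], "eqtl", rep(rs, length(eq[[rs]])))
  }

  syms <- sort(ls(ev))
  genes <- do.call(rbind, lapply(syms, function(s) {
    rec <- get(s, envir = ev)
    data.frame(symbol = s, coding = rec$coding, pd = rec$pd, ld = rec$ld,
               eqtl = rec$eqtl,
               source_rsids = paste(sort(rec$rsids), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(genes))
    genes <- data.frame(symbol = character(), coding = logical(),
                        pd = logical(), ld = logical(), eqtl = logical(),
                        source_rsids = character(), stringsAsFactors = FALSE)
  list(genes = genes, snps = cls, composition = evidenceComposition(genes))
}

#' Evidence-combination composition of prioritized genes
#'
#' Counts, among the noncoding-derived (non-coding-evidence) genes, those
#' supported by eQTL together with proximity/LD, by eQTL only, and by
#' proximity/LD only, with percentages over the noncoding-derived total.
#'
#' @param genes the \code{genes} data.frame from [prioritizeGenes()].
#' @return named numeric vector with counts \code{n_coding},
#'   \code{n_prioritized}, \code{eqtl_and_proximity}, \code{eqtl_only},
#'   \code{proximity_only} and the matching \code{pct_*} percentages.
#' @export
evidenceComposition <- function(genes) {
  nc <- genes[!genes$coding, , drop = FALSE]
  prox <- nc$pd | nc$ld
  both <- sum(nc$eqtl & prox)
  eqOnly <- sum(nc$eqtl & !prox)
  proxOnly <- sum(!nc$eqtl & prox)
  n <- nrow(nc)
  pct <- function(k) if (n > 0) 100 * k / n else NA_real_
  c(n_coding = sum(genes$coding), n_prioritized = n,
    eqtl_and_proximity = both, eqtl_only = eqOnly, proximity_only = proxOnly,
    pct_eqtl_and_proximity = pct(both), pct_eqtl_only = pct(eqOnly),
    pct_proximity_only = pct(proxOnly))
}
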