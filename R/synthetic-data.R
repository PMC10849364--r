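#' @importFrom stats rnorm runif setNames
NULL

## run expr with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(expr)
}

#' Synthetic GWAS fixture: SNPs, gene models, elements, LD proxies, eQTLs
#'
#' Generates a marker table and all annotation tables consumed by
#' [prioritizeGenes()], with a fully known design: \code{nCoding} markers
#' planted inside exons of host genes, the remaining markers noncoding
#' (alternating intronic/intergenic) with candidate genes planted into
#' designed evidence classes - PD-only, PD-and-LD, LD-only (via wide LD
#' spans reaching beyond the physical window), eQTL-combined and eQTL-only.
#' One marker sits in a configurable HLA interval (annotated for PD only;
#' its LD span carries a trap gene that a correct pipeline must not
#' prioritize) and one marker is absent from the LD panel. Junk elements
#' carrying every biotype exclusion keyword are planted inside the loci.
#' Default quotas mirror the study conditions: 54 markers, 10 coding, and
#' 135 prioritized genes of which 25 have eQTL plus proximity/LD evidence,
#' 2 eQTL-only and 108 proximity/LD-only.
#'
#' @param seed RNG seed (placement jitter; the design is deterministic).
#' @param nCoding number of coding markers.
#' @param nNarrow,nWide noncoding markers with narrow (+/-50 kb) and wide
#'   (+/-400 kb) LD spans.
#' @param nPdOnly,nBoth,nLdOnly,nEqtlOnly evidence-class gene quotas.
#' @param nEqtlPdOnly,nEqtlBoth,nEqtlLdOnly how many genes of the first
#'   three classes additionally receive eQTL rows.
#' @param withHla,withMissing plant the HLA marker / the marker missing from
#'   the LD panel (both drawn from the narrow markers).
#' @return list with \code{snps}, \code{geneModels}, \code{elements},
#'   \code{proxies}, \code{eqtls}, \code{hlaRegion} and \code{truth} (a list
#'   holding the designed gene table with evidence flags, the expected
#'   composition, junk symbols and the HLA trap gene).
#' @export
simulateSnpFixture <- function(seed = 1L, nCoding = 10, nNarrow = 38,
                               nWide = 6, nPdOnly = 80, nBoth = 47,
                               nLdOnly = 6, nEqtlOnly = 2,
                               nEqtlPdOnly = 13, nEqtlBoth = 10,
                               nEqtlLdOnly = 2,
                               withHla = TRUE, withMissing = TRUE) {
  .assert(nLdOnly <= nWide * 17, "too many LD-only genes for the wide markers")
  .assert(nEqtlPdOnly <= nPdOnly && nEqtlBoth <= nBoth && nEqtlLdOnly <= nLdOnly,
          "eQTL quotas exceed class quotas")
  .withSeed(seed, {
    P <- 1000000L
    snps <- list(); proxies <- list(); elements <- list()
    geneModels <- list(); eqtls <- list(); truthRows <- list()

    ## --- coding markers -------------------------------------------------
    for (i in seq_len(nCoding)) {
      chrom <- sprintf("cod%02d", i)
      rs <- sprintf("rsc%03d", i)
      host <- sprintf("GC%02d", i)
      snps[[length(snps) + 1]] <-
        data.frame(rsid = rs, chrom = chrom, pos = 5000L)
      geneModels[[length(geneModels) + 1]] <- data.frame(
        symbol = host, chrom = chrom,
        start = c(1000L, 1000L, 4000L), end = c(9000L, 1500L, 6000L),
        feature = c("span", "exon", "exon"))
      truthRows[[length(truthRows) + 1]] <- data.frame(
        symbol = host, coding = TRUE, pd = FALSE, ld = FALSE, eqtl = FALSE,
        rsid = rs)
    }

    ## --- noncoding markers ---------------------------------------------
    nNc <- nNarrow + nWide
    ncChrom <- sprintf("c%02d", seq_len(nNc))
    ncRs <- sprintf("rsn%03d", seq_len(nNc))
    kind <- c(rep("narrow", nNarrow), rep("wide", nWide))
    hlaIdx <- if (withHla) nNarrow else 0L          # last narrow marker
    missIdx <- if (withMissing) nNarrow - 1L else 0L
    if (withMissing) ncRs[missIdx] <- "rsmiss"
    for (i in seq_len(nNc)) {
      snps[[length(snps) + 1]] <-
        data.frame(rsid = ncRs[i], chrom = ncChrom[i], pos = P)
      if (i == missIdx) next                         # absent from LD panel
      span <- if (kind[i] == "wide" || i == hlaIdx) 400000L else 50000L
      r2lo <- if (kind[i] == "wide" || i == hlaIdx) 0.8 else 0.85
      proxies[[length(proxies) + 1]] <- data.frame(
        rsid = ncRs[i],
        proxy_rsid = c(ncRs[i], paste0(ncRs[i], c("a", "b"))),
        r2 = c(1, r2lo, 0.9),
        proxy_pos = c(P, P - span, P + span))
      ## sub-threshold proxy that must not widen the span
      proxies[[length(proxies) + 1]] <- data.frame(
        rsid = ncRs[i], proxy_rsid = paste0(ncRs[i], "x"),
        r2 = 0.5, proxy_pos = P + 900000L)
    }
    hlaRegion <- if (withHla)
      list(chrom = ncChrom[hlaIdx], start = P - 1000L, end = P + 1000L)
      else NULL

    addGene <- function(sym, i, start, end, pd, ld) {
      elements[[length(elements) + 1]] <<- data.frame(
        symbol = sym, name = "protein coding gene",
        chrom = ncChrom[i], start = start, end = end)
      truthRows[[length(truthRows) + 1]] <<- data.frame(
        symbol = sym, coding = FALSE, pd = pd, ld = ld, eqtl = FALSE,
        rsid = ncRs[i])
    }

    ## PD-only genes: within the physical window, outside any LD span.
    ## Hosted on narrow markers (wide LD spans engulf the whole PD window);
    ## for the HLA and panel-missing markers every in-window gene is PD-only.
    narrowIdx <- which(kind == "narrow")
    g <- 0L
    for (j in seq_len(nPdOnly)) {
      i <- narrowIdx[(j - 1L) %% length(narrowIdx) + 1L]
      slot <- (j - 1L) %/% length(narrowIdx)
      start <- P + 55000L + 9000L * slot + sample.int(2000L, 1)
      addGene(sprintf("GP%03d", j), i, start, start + 4000L,
              pd = TRUE, ld = FALSE)
    }
    ## PD-and-LD genes: inside the LD span (which lies within the window),
    ## not on the HLA or panel-missing markers.
    bothIdx <- setdiff(seq_len(nNc), c(hlaIdx, missIdx))
    for (j in seq_len(nBoth)) {
      i <- bothIdx[(j - 1L) %% length(bothIdx) + 1L]
      slot <- (j - 1L) %/% length(bothIdx)
      start <- P - 45000L + 12000L * slot + sample.int(2000L, 1)
      addGene(sprintf("GB%03d", j), i, start, start + 3000L,
              pd = TRUE, ld = TRUE)
    }
    ## LD-only genes: inside the wide span but beyond the physical window.
    wideIdx <- which(kind == "wide")
    for (j in seq_len(nLdOnly)) {
      i <- wideIdx[(j - 1L) %% length(wideIdx) + 1L]
      slot <- (j - 1L) %/% length(wideIdx)
      start <- P + 260000L + 8000L * slot + sample.int(2000L, 1)
      addGene(sprintf("GL%03d", j), i, start, start + 4000L,
              pd = FALSE, ld = TRUE)
    }
    ## HLA trap: in LD span of the HLA marker, outside its window; a correct
    ## pipeline skips LD there, so this gene must not be prioritized.
    hlaTrap <- NULL
    if (withHla) {
      hlaTrap <- "GHLATRAP"
      elements[[length(elements) + 1]] <- data.frame(
        symbol = hlaTrap, name = "protein coding gene",
        chrom = ncChrom[hlaIdx], start = P + 300000L, end = P + 304000L)
    }

    truth <- do.call(rbind, truthRows)

    ## eQTL rows for designated members of each class, plus eQTL-only genes
    addEqtl <- function(sym, i, tissues) {
      for (tis in tissues)
        eqtls[[length(eqtls) + 1]] <<- data.frame(
          rsid = ncRs[i], symbol = sym, tissue = tis)
      truth$eqtl[truth$symbol == sym] <<- TRUE
    }
    tiss <- c("skin_sun_exposed", "skin_not_sun_exposed")
    pick <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
    hostOf <- function(sym) match(truth$rsid[truth$symbol == sym], ncRs)
    for (s in pick("GP", nEqtlPdOnly))
      addEqtl(s, hostOf(s), if (s == "GP001") tiss else tiss[1])
    for (s in pick("GB", nEqtlBoth)) addEqtl(s, hostOf(s), tiss[2])
    for (s in pick("GL", nEqtlLdOnly)) addEqtl(s, hostOf(s), tiss[1])
    eqOnlyIdx <- setdiff(narrowIdx, c(hlaIdx, missIdx))
    for (j in seq_len(nEqtlOnly)) {
      sym <- sprintf("GE%03d", j)
      i <- eqOnlyIdx[j]
      truth <- rbind(truth, data.frame(
        symbol = sym, coding = FALSE, pd = FALSE, ld = FALSE, eqtl = FALSE,
        rsid = ncRs[i]))
      addEqtl(sym, i, if (j == 1L) tiss else tiss[2])
    }

    ## intronic hosts: even-indexed noncoding markers sit inside an ORF
    ## (exon away from the marker); odd-indexed markers stay intergenic
    for (i in seq_len(nNc)) {
      if (i %% 2L == 0L) {
        geneModels[[length(geneModels) + 1]] <- data.frame(
          symbol = sprintf("INTR%02d", i), chrom = ncChrom[i],
          start = c(P - 10000L, P - 10000L), end = c(P + 10000L, P - 9000L),
          feature = c("span", "exon"))
      }
    }

    ## junk elements: one per exclusion keyword, planted inside windows
    junk <- defaultExclusionKeywords()
    junkSyms <- sprintf("JUNK%02d", seq_along(junk))
    for (j in seq_along(junk)) {
      i <- (j - 1L) %% nNc + 1L
      elements[[length(elements) + 1]] <- data.frame(
        symbol = junkSyms[j], name = sprintf("some %s element", junk[j]),
        chrom = ncChrom[i], start = P + 20000L + 100L * j,
        end = P + 20050L + 100L * j)
    }

    snps <- do.call(rbind, snps)
    expectedComposition <- c(
      n_coding = sum(truth$coding),
      n_prioritized = sum(!truth$coding),
      eqtl_and_proximity = sum(!truth$coding & truth$eqtl & (truth$pd | truth$ld)),
      eqtl_only = sum(!truth$coding & truth$eqtl & !(truth$pd | truth$ld)),
      proximity_only = sum(!truth$coding & !truth$eqtl & (truth$pd | truth$ld)))
    list(snps = snps,
         geneModels = do.call(rbind, geneModels),
         elements = do.call(rbind, elements),
         proxies = do.call(rbind, proxies),
         eqtls = if (length(eqtls)) do.call(rbind, eqtls) else
           data.frame(rsid = character(), symbol = character(),
                      tissue = character()),
         hlaRegion = hlaRegion,
         truth = list(genes = truth, composition = expectedComposition,
                      junkSymbols = junkSyms, hlaTrap = hlaTrap))
  })
}

#' Synthetic familial and somatic gene lists with designed Venn overlaps
#'
#' Builds the two curated-list stand-ins around a given GWAS gene list so
#' the three-way merge has a known composition. Defaults mirror the study
#' conditions: 27 familial and 71 somatic genes, 2 genes in all three lists
#' and 7 in exactly two (3 GWAS+familial, 2 GWAS+somatic, 2
#' familial+somatic).
#'
#' @param gwasGenes character vector of GWAS-prioritized symbols.
#' @param seed RNG seed for picking the shared genes.
#' @param nFamilial,nSomatic list sizes.
#' @param nTriple genes present in all three lists.
#' @param nGwasFam,nGwasSom,nFamSom pairwise-only overlap counts.
#' @return list with \code{gwas}, \code{familial}, \code{somatic} and
#'   \code{truth} (expected union size and composition).
#' @export
simulateSeedLists <- function(gwasGenes, seed = 1L, nFamilial = 27,
                              nSomatic = 71, nTriple = 2, nGwasFam = 3,
                              nGwasSom = 2, nFamSom = 2) {
  gwasGenes <- unique(normalizeSymbols(gwasGenes))
  need <- nTriple + nGwasFam + nGwasSom
  .assert(length(gwasGenes) >= need, "GWAS list too short for the overlaps")
  .assert(nFamilial >= nTriple + nGwasFam + nFamSom, "familial quota too small")
  .assert(nSomatic >= nTriple + nGwasSom + nFamSom, "somatic quota too small")
  .withSeed(seed, {
    shared <- sample(gwasGenes, need)
    triple <- shared[seq_len(nTriple)]
    gf <- shared[nTriple + seq_len(nGwasFam)]
    gs <- shared[nTriple + nGwasFam + seq_len(nGwasSom)]
    fs <- sprintf("FS%03d", seq_len(nFamSom))
    famOnly <- sprintf("FAM%03d",
                       seq_len(nFamilial - nTriple - nGwasFam - nFamSom))
    somOnly <- sprintf("SOM%03d",
                       seq_len(nSomatic - nTriple - nGwasSom - nFamSom))
    familial <- c(triple, gf, fs, famOnly)
    somatic <- c(triple, gs, fs, somOnly)
    unionSize <- length(gwasGenes) + nFamilial + nSomatic -
      (nGwasFam + nGwasSom + nFamSom) - 2 * nTriple
    list(gwas = gwasGenes, familial = familial, somatic = somatic,
         truth = list(union = unionSize, triple = nTriple,
                      double = nGwasFam + nGwasSom + nFamSom))
  })
}

#' Synthetic literature interactome with planted network structure
#'
#' Emits an interaction table in the canonical dialect with a fully known
#' design: a dense connected component over \code{nCoreSeeds} seeds (its
#' spanning tree high-confidence so the component survives the 0.72 filter;
#' extra in-component edges drawn at \code{coreDensity}, a fraction of them
#' low-confidence), \code{nPendantPairs} isolated seed pairs, \code{nExtra}
#' seeds reachable only through bridges, \code{nBridges} true bridges each
#' wired to seeds with at least one unconnected pair, plus decoy
#' interactors wired to already-connected seed pairs or single seeds,
#' ubiquitin (UBB/UBC/UBD) edges, records with no PubMed id or
#' "unspecified"-only detection methods (low-confidence, as such records
#' are in practice), self-interactions, and records flagged as ambiguously
#' mapped or with nonstandard symbols.
#'
#' @param seeds character vector of seed symbols (e.g.
#'   \code{seedSymbols(seedTable)}).
#' @param seed RNG seed.
#' @param nCoreSeeds seeds in the directly-interacting core.
#' @param nPendantPairs isolated directly-interacting seed pairs.
#' @param nExtra seeds attached to the core only via bridges.
#' @param nBridges true bridge interactors.
#' @param coreDensity probability of an extra edge between two core seeds.
#' @param lowConfFrac fraction of extra core edges drawn below 0.72.
#' @param nDecoys non-bridge interactors.
#' @return list with \code{interactions} (data.frame) and \code{truth}
#'   (core seeds, pendant pairs, extra seeds, bridge set, expected level-one
#'   core node set, decoys, isolated seeds).
#' @export
simulateInteractome <- function(seeds, seed = 1L, nCoreSeeds = 148,
                                nPendantPairs = 4, nExtra = 46,
                                nBridges = 208, coreDensity = 0.08,
                                lowConfFrac = 0.25, nDecoys = 40) {
  seeds <- unique(normalizeSymbols(seeds))
  .assert(length(seeds) >= nCoreSeeds + 2 * nPendantPairs + nExtra,
          "not enough seeds for the requested design")
  .assert(nBridges >= nExtra,
          "need at least one bridge per bridge-attached extra seed")
  .withSeed(seed, {
    perm <- sample(seeds)
    core <- sort(perm[seq_len(nCoreSeeds)])
    pend <- perm[nCoreSeeds + seq_len(2 * nPendantPairs)]
    extra <- sort(perm[nCoreSeeds + 2 * nPendantPairs + seq_len(nExtra)])
    isolated <- sort(setdiff(seeds, c(core, pend, extra)))

    rows <- list()
    entrez <- new.env(parent = emptyenv())
    eid <- function(s) {
      v <- get0(s, envir = entrez)
      if (is.null(v)) {
        v <- as.character(10000 + length(ls(entrez)))
        assign(s, v, envir = entrez)
      }
      v
    }
    addRow <- function(a, b, conf, methods = "two hybrid",
                       pmids = "12345678", ea = eid(a), eb = eid(b)) {
      rows[[length(rows) + 1]] <<- data.frame(
        symbol_a = a, entrez_a = ea, symbol_b = b, entrez_b = eb,
        confidence = conf, detection_methods = methods, pubmed_ids = pmids,
        stringsAsFactors = FALSE)
    }
    hcPair <- new.env(parent = emptyenv())   # high-confidence seed-seed pairs
    markHc <- function(a, b)
      assign(paste(min(a, b), max(a, b), sep = "\r"), TRUE, envir = hcPair)
    isHc <- function(a, b)
      !is.null(get0(paste(min(a, b), max(a, b), sep = "\r"), envir = hcPair))

    ## core spanning tree (high confidence) + extra edges
    chain <- sample(core)
    for (i in seq_len(length(chain) - 1)) {
      addRow(chain[i], chain[i + 1], round(runif(1, 0.75, 0.95), 3))
      markHc(chain[i], chain[i + 1])
    }
    nC <- length(core)
    for (i in seq_len(nC - 1)) {
      js <- which(runif(nC - i) < coreDensity) + i
      for (j in js) {
        if (isHc(core[i], core[j])) next
        if (runif(1) < lowConfFrac) {
          addRow(core[i], core[j], round(runif(1, 0.3, 0.71), 3))
        } else {
          addRow(core[i], core[j], round(runif(1, 0.72, 0.99), 3))
          markHc(core[i], core[j])
        }
      }
    }
    ## pendant pairs
    pendPairs <- matrix(pend, ncol = 2, byrow = TRUE)
    for (r in seq_len(nrow(pendPairs))) {
      addRow(pendPairs[r, 1], pendPairs[r, 2], round(runif(1, 0.75, 0.95), 3))
      markHc(pendPairs[r, 1], pendPairs[r, 2])
    }
    ## bridges: first nExtra tether one extra seed each to the core, the
    ## rest span unconnected core seed pairs
    bridges <- sprintf("BRG%03d", seq_len(nBridges))
    for (k in seq_len(nBridges)) {
      if (k <= nExtra) {
        s1 <- extra[k]; s2 <- sample(core, 1)
      } else {
        repeat {
          s12 <- sample(core, 2)
          if (!isHc(s12[1], s12[2])) { s1 <- s12[1]; s2 <- s12[2]; break }
        }
      }
      addRow(bridges[k], s1, round(runif(1, 0.72, 0.99), 3))
      addRow(bridges[k], s2, round(runif(1, 0.72, 0.99), 3))
    }
    ## decoys: half close a triangle over an existing high-confidence core
    ## edge, half touch a single seed
    decoys <- sprintf("DCY%03d", seq_len(nDecoys))
    hcKeys <- ls(hcPair)
    for (k in seq_len(nDecoys)) {
      if (k %% 2 == 0) {
        pr <- strsplit(sample(hcKeys, 1), "\r", fixed = TRUE)[[1]]
        addRow(decoys[k], pr[1], round(runif(1, 0.72, 0.99), 3))
        addRow(decoys[k], pr[2], round(runif(1, 0.72, 0.99), 3))
      } else {
        addRow(decoys[k], sample(core, 1), round(runif(1, 0.72, 0.99), 3))
      }
    }
    ## quality-control junk (all low confidence, as unvetted records are):
    ## no PubMed id / unspecified-only methods / self-interactions
    if (length(isolated) >= 4) {
      addRow(isolated[1], isolated[2], 0.4, pmids = "")
      addRow(isolated[3], isolated[4], 0.4,
             methods = "unspecified", pmids = "999")
    }
    addRow(core[1], core[1], 0.9)                       # self-interaction
    ## ubiquitin decoy edges (high confidence, removed as unspecific)
    for (ub in c("UBB", "UBC", "UBD"))
      addRow(ub, sample(core, 1), round(runif(1, 0.8, 0.99), 3))
    ## flagged records wired like bridges: must be removed by the filter
    repeat {
      s12 <- sample(core, 2)
      if (!isHc(s12[1], s12[2])) break
    }
    addRow("AMBIG1", s12[1], 0.95, ea = "111;222")
    addRow("AMBIG1", s12[2], 0.95, ea = "111;222")
    addRow("odd_symbol", core[3], 0.95)

    interactions <- .deriveInteractionFlags(do.call(rbind, rows))
    list(interactions = interactions,
         truth = list(coreSeeds = core,
                      pendantPairs = pendPairs,
                      extraSeeds = extra,
                      bridges = bridges,
                      decoys = decoys,
                      isolatedSeeds = isolated,
                      l1CoreNodes = sort(c(core, extra, bridges))))
  })
}

#' Design a planted fold-change assignment
#'
#' Chooses which universe genes receive which planted log2 fold change so
#' that the nested fold-change classes and their overlaps with the model
#' gene set have designed sizes. \code{nFc}/\code{nModelFc} give cumulative
#' class sizes (FC2 >= FC3 >= FC4) and the model-gene share of each;
#' magnitudes place each exclusive stratum strictly between thresholds.
#' Signs alternate up/down.
#'
#' @param universe character vector of measured genes.
#' @param model character vector of model genes (subset of universe).
#' @param nFc cumulative class sizes, default c(732, 364, 120).
#' @param nModelFc model genes per class, default c(30, 12, 2).
#' @param magnitudes planted |log2FC| per exclusive stratum,
#'   default c(2.5, 3.5, 4.5).
#' @param seed RNG seed.
#' @return named numeric vector, gene -> planted log2 fold change (only
#'   nonzero entries), with attribute \code{classes} (list of planted FC2 /
#'   FC3 / FC4 gene sets).
#' @export
designFoldChangePlan <- function(universe, model, nFc = c(732, 364, 120),
                                 nModelFc = c(30, 12, 2),
                                 magnitudes = c(2.5, 3.5, 4.5), seed = 1L) {
  universe <- unique(normalizeSymbols(universe))
  model <- intersect(unique(normalizeSymbols(model)), universe)
  .assert(all(diff(nFc) <= 0) && all(diff(nModelFc) <= 0),
          "class sizes must be nested (non-increasing)")
  .assert(all(nModelFc <= nFc) && nModelFc[1] <= length(model),
          "model quotas exceed availability")
  .withSeed(seed, {
    other <- setdiff(universe, model)
    pickModel <- sample(model, nModelFc[1])
    pickOther <- sample(other, nFc[1] - nModelFc[1])
    ## exclusive strata, innermost (largest magnitude) first
    nEx <- c(nFc[1] - nFc[2], nFc[2] - nFc[3], nFc[3])
    nExM <- c(nModelFc[1] - nModelFc[2], nModelFc[2] - nModelFc[3], nModelFc[3])
    lfc <- numeric(0); classes <- list(fc2 = character(0),
                                       fc3 = character(0), fc4 = character(0))
    mi <- 0L; oi <- 0L
    for (s in 1:3) {
      gs <- c(pickModel[seq_len(nExM[s]) + mi],
              pickOther[seq_len(nEx[s] - nExM[s]) + oi])
      mi <- mi + nExM[s]; oi <- oi + (nEx[s] - nExM[s])
      sgn <- rep_len(c(1, -1), length(gs))
      lfc <- c(lfc, setNames(sgn * magnitudes[s], gs))
      classes$fc2 <- c(classes$fc2, gs)
      if (s >= 2) classes$fc3 <- c(classes$fc3, gs)
      if (s >= 3) classes$fc4 <- c(classes$fc4, gs)
    }
    attr(lfc, "classes") <- lapply(classes, sort)
    lfc
  })
}

#' Synthetic two-group intensity matrix
#'
#' Log-normal intensities emulating an array-style two-group comparison:
#' per-gene baseline log2 levels drawn uniformly, i.i.d. Gaussian noise on
#' the log2 scale (the simplest model consistent with the Welch-t
#' assumptions), and the planted log2 fold changes added to group 2.
#'
#' @param genes character vector of gene ids (the measured universe).
#' @param plantedLfc named numeric vector, gene -> log2 fold change (e.g.
#'   from [designFoldChangePlan()]); genes not named get 0.
#' @param groupSizes samples per group, default c(7, 45) (normal skin vs
#'   melanoma).
#' @param noiseSd log2-scale replicate noise, default 0.25.
#' @param seed RNG seed.
#' @return list with \code{exprs} (linear-scale genes x samples matrix),
#'   \code{groups} (factor, levels group1/group2) and \code{truth}
#'   (planted log2FC vector and planted class sets when present).
#' @export
simulateExpression <- function(genes, plantedLfc = numeric(0),
                               groupSizes = c(7, 45), noiseSd = 0.25,
                               seed = 1L) {
  genes <- unique(normalizeSymbols(genes))
  .assert(all(groupSizes >= 2), "need >= 2 samples per group")
  .assert(all(names(plantedLfc) %in% genes),
          "planted genes must be in the universe")
  .withSeed(seed, {
    n <- length(genes); n1 <- groupSizes[1]; n2 <- groupSizes[2]
    base <- runif(n, 6, 12)
    lfc <- setNames(numeric(n), genes)
    lfc[names(plantedLfc)] <- plantedLfc
    l1 <- matrix(rnorm(n * n1, mean = base, sd = noiseSd), nrow = n)
    l2 <- matrix(rnorm(n * n2, mean = base + lfc, sd = noiseSd), nrow = n)
    exprs <- 2^cbind(l1, l2)
    rownames(exprs) <- genes
    colnames(exprs) <- c(sprintf("normal_%02d", seq_len(n1)),
                         sprintf("tumor_%02d", seq_len(n2)))
    groups <- factor(rep(c("group1", "group2"), c(n1, n2)))
    list(exprs = exprs, groups = groups,
         truth = list(lfc = lfc[lfc != 0],
                      classes = attr(plantedLfc, "classes")))
  })
}

#' Synthetic treatment differential-expression table
#'
#' Emits a DE result table (gene, log2fc, p_value, p_adj) over a measured
#' universe in which exactly \code{round(fractionModel * |model|)} model
#' genes and a \code{fractionBackground} share of the remaining genes are
#' significant at adjusted p < 0.05, emulating a treated-vs-control
#' experiment whose hits are enriched in the network model.
#'
#' @param universe character vector of measured genes.
#' @param model character vector of model genes.
#' @param fractionModel fraction of model genes significant, default
#'   215/402.
#' @param fractionBackground significant fraction among non-model genes,
#'   default 0.40.
#' @param padjMax significance cut the table is built around, default 0.05.
#' @param seed RNG seed.
#' @return list with \code{de} (data.frame) and \code{truth} (the planted
#'   significant set and its model overlap).
#' @export
simulateDeTable <- function(universe, model, fractionModel = 215 / 402,
                            fractionBackground = 0.40, padjMax = 0.05,
                            seed = 1L) {
  universe <- unique(normalizeSymbols(universe))
  model <- intersect(unique(normalizeSymbols(model)), universe)
  .assert(fractionModel >= 0 && fractionModel <= 1 &&
          fractionBackground >= 0 && fractionBackground <= 1,
          "fractions must be in [0, 1]")
  .withSeed(seed, {
    other <- setdiff(universe, model)
    sigModel <- sample(model, round(fractionModel * length(model)))
    sigOther <- sample(other, round(fractionBackground * length(other)))
    sig <- universe %in% c(sigModel, sigOther)
    padj <- ifelse(sig, runif(length(universe), 1e-8, padjMax * 0.98),
                   runif(length(universe), padjMax * 1.04, 1))
    de <- data.frame(
      gene = universe,
      log2fc = ifelse(sig, rnorm(length(universe), 0, 2),
                      rnorm(length(universe), 0, 0.2)),
      p_value = padj * runif(length(universe), 0.05, 0.9),
      p_adj = padj, stringsAsFactors = FALSE)
    list(de = de,
         truth = list(significant = sort(c(sigModel, sigOther)),
                      modelOverlap = sort(sigModel)))
  })
}
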