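snp <- function(rsid, chrom, pos)
  data.frame(rsid = rsid, chrom = chrom, pos = pos)

gmRow <- function(symbol, chrom, start, end, feature)
  data.frame(symbol = symbol, chrom = chrom, start = start, end = end,
             feature = feature)

test_that("SNPs classify as coding / intronic / intergenic by ORF geometry", {
  gm <- rbind(gmRow("G1", "c1", 100, 1000, "span"),
              gmRow("G1", "c1", 100, 200, "exon"),
              gmRow("G1", "c1", 900, 1000, "utr3"))
  cls <- classifySnps(rbind(snp("r1", "c1", 150),    # inside exon
                            snp("r2", "c1", 500),    # in span, no exon
                            snp("r3", "c1", 5000),   # outside every span
                            snp("r4", "c1", 950),    # 3' UTR counts as coding
                            snp("r5", "c2", 150)),   # right pos, wrong chrom
                      gm)
  expect_equal(cls$category,
               c("coding", "intronic", "intergenic", "coding", "intergenic"))
  expect_equal(cls$host_genes[1], "G1")
  expect_equal(cls$host_genes[3], "")
})

test_that("a SNP in overlapping ORFs is attached to every host gene", {
  gm <- rbind(gmRow("A", "c1", 100, 300, "exon"),
              gmRow("B", "c1", 200, 400, "exon"))
  cls <- classifySnps(snp("r1", "c1", 250), gm)
  expect_equal(cls$host_genes, "A;B")
})

test_that("malformed gene-model intervals are rejected", {
  expect_error(classifySnps(snp("r1", "c1", 10),
                            gmRow("G1", "c1", 200, 100, "exon")),
               "start > end")
})

test_that("PD loci are +/- half-window, clipped at chromosome start", {
  expect_equal(buildPdLocus(snp("r", "c1", 300000))[, c("start", "end")],
               data.frame(start = 50000, end = 550000))
  expect_equal(buildPdLocus(snp("r", "c1", 100000))[, c("start", "end")],
               data.frame(start = 1, end = 350000))
  expect_equal(buildPdLocus(snp("r", "c1", 7), halfWindow = 0)[, c("start", "end")],
               data.frame(start = 7, end = 7))
})

test_that("PD locus width is constant except at the clipped chromosome start", {
  set.seed(42)
  pos <- sample.int(2000000, 50)
  loci <- buildPdLocus(snp(sprintf("r%02d", 1:50), "c1", pos))
  unclipped <- pos > 250000
  expect_true(all(loci$end[unclipped] - loci$start[unclipped] == 500000))
  expect_true(all(loci$start[!unclipped] == 1))
})

test_that("LD loci span the passing proxies and always contain the marker", {
  prox <- data.frame(rsid = "r1",
                     proxy_rsid = c("r1", "p1", "p2", "p3"),
                     r2 = c(1, 0.9, 0.8, 0.79),
                     proxy_pos = c(100000, 90000, 130000, 500000))
  loc <- buildLdLocus(snp("r1", "c1", 100000), prox)
  ## r2 = 0.8 is included (threshold inclusive), 0.79 is not
  expect_equal(c(loc$start, loc$end), c(90000, 130000))
  ## marker present with self-row only: marker-only window
  self <- prox[1, ]
  loc2 <- buildLdLocus(snp("r1", "c1", 100000), self)
  expect_equal(c(loc2$start, loc2$end), c(100000, 100000))
  ## no row at all: absent from the panel
  expect_equal(nrow(buildLdLocus(snp("rX", "c1", 5), prox)), 0)
  ## invalid r2
  bad <- data.frame(rsid = "r1", proxy_rsid = "p", r2 = 1.2, proxy_pos = 1)
  expect_error(buildLdLocus(snp("r1", "c1", 10), bad), "r2")
})

test_that("markers in the HLA interval get PD but no LD locus", {
  prox <- data.frame(rsid = "r1", proxy_rsid = "r1", r2 = 1,
                     proxy_pos = 100000)
  hla <- list(chrom = "c1", start = 99000, end = 101000)
  expect_equal(nrow(buildLdLocus(snp("r1", "c1", 100000), prox,
                                 hlaRegion = hla)), 0)
  expect_equal(nrow(buildPdLocus(snp("r1", "c1", 100000))), 1)
})

test_that("element-to-locus mapping is >= 1 bp inclusive overlap, same chromosome", {
  loci <- data.frame(rsid = "r1", chrom = "c1", start = 100, end = 500,
                     method = "PD")
  el <- function(sym, chrom, s, e)
    data.frame(symbol = sym, name = "x", chrom = chrom, start = s, end = e)
  expect_equal(mapElementsToLocus(loci, el("A", "c1", 600, 700))$symbol,
               character(0))
  expect_equal(mapElementsToLocus(loci, el("B", "c1", 500, 700))$symbol, "B")
  expect_equal(mapElementsToLocus(loci, el("C", "c1", 1, 9999))$symbol, "C")
  expect_equal(mapElementsToLocus(loci, el("D", "c2", 200, 300))$symbol,
               character(0))
})

test_that("keyword filter removes non-coding biotypes and is idempotent", {
  el <- data.frame(symbol = c("A", "TP53", "B", "C", "D"),
                   name = c("ABCD1 pseudogene 2", "TP53",
                            "novel transcript", "some lncRNA thing",
                            "plain protein coding"))
  out <- filterCodingElements(el)
  expect_equal(out$symbol, c("TP53", "D"))
  expect_equal(filterCodingElements(out), out)
  ## no surviving name contains any keyword
  for (kw in tolower(defaultExclusionKeywords()))
    expect_false(any(grepl(kw, tolower(out$name), fixed = TRUE)))
})

test_that("eQTL join unions both skin tissues and rejects coding markers", {
  snps <- cbind(snp(c("r1", "r2"), "c1", c(10, 20)),
                category = c("intronic", "intergenic"))
  eq <- data.frame(rsid = c("r1", "r1", "r1"),
                   symbol = c("A", "A", "B"),
                   tissue = c("skin_sun_exposed", "skin_not_sun_exposed",
                              "skin_not_sun_exposed"))
  j <- joinEqtl(snps, eq)
  expect_equal(j$r1, c("A", "B"))
  expect_equal(j$r2, character(0))
  codingSnp <- cbind(snp("r9", "c1", 5), category = "coding")
  expect_error(joinEqtl(codingSnp, eq), "coding")
  empty <- eq[0, ]
  expect_equal(joinEqtl(snps, empty)$r1, character(0))
})

test_that("prioritization evidence equals independent set algebra on random fixtures", {
  ## oracle: recompute each marker's PD / LD / eQTL gene set with plain
  ## arithmetic and union the evidence
  set.seed(11)
  for (rep in 1:5) {
    nSnp <- 6
    snps <- snp(sprintf("r%02d", 1:nSnp), sprintf("c%02d", 1:nSnp),
                sample(400000:600000, nSnp))
    nel <- 40
    chrom <- sample(snps$chrom, nel, replace = TRUE)
    start <- sample(1:900000, nel)
    elements <- data.frame(symbol = sprintf("E%02d", 1:nel),
                           name = "protein coding",
                           chrom = chrom, start = start, end = start + 5000)
    prox <- do.call(rbind, lapply(1:nSnp, function(i) {
      k <- sample(0:3, 1)
      data.frame(rsid = snps$rsid[i],
                 proxy_rsid = c(snps$rsid[i], sprintf("p%d_%d", i, seq_len(k))),
                 r2 = c(1, runif(k, 0.5, 1)),
                 proxy_pos = c(snps$pos[i],
                               sample(100000:900000, k, replace = TRUE)))
    }))
    eqtls <- data.frame(rsid = sample(snps$rsid, 5, replace = TRUE),
                        symbol = sample(elements$symbol, 5, replace = TRUE),
                        tissue = sample(c("skin_sun_exposed",
                                          "skin_not_sun_exposed"), 5,
                                        replace = TRUE))
    gm <- gmRow("HOST", snps$chrom[1], snps$pos[1] - 10, snps$pos[1] + 10,
                "exon")
    pr <- prioritizeGenes(snps, gm, elements, prox, eqtls, halfWindow = 50000)

    ## oracle
    expect_true(all(pr$genes$symbol[pr$genes$coding] == "HOST"))
    for (i in 2:nSnp) {                 # SNP 1 is coding, skip
      rs <- snps$rsid[i]
      onCh <- elements[elements$chrom == snps$chrom[i], ]
      pdExp <- onCh$symbol[onCh$end >= snps$pos[i] - 50000 &
                           onCh$start <= snps$pos[i] + 50000]
      pp <- prox[prox$rsid == rs & prox$r2 >= 0.8, ]
      lo <- min(c(snps$pos[i], pp$proxy_pos)); hi <- max(c(snps$pos[i], pp$proxy_pos))
      ldExp <- onCh$symbol[onCh$end >= lo & onCh$start <= hi]
      eqExp <- unique(eqtls$symbol[eqtls$rsid == rs])
      gotPd <- pr$genes$symbol[pr$genes$pd &
                               grepl(rs, pr$genes$source_rsids)]
      expect_true(all(pdExp %in% pr$genes$symbol[pr$genes$pd]))
      expect_true(all(ldExp %in% pr$genes$symbol[pr$genes$ld]))
      expect_true(all(eqExp %in% pr$genes$symbol[pr$genes$eqtl]))
    }
    ## every gene traces to >= 1 marker
    expect_true(all(nchar(pr$genes$source_rsids) > 0))
    ## composition recomputes from the flags
    nc <- pr$genes[!pr$genes$coding, ]
    expect_equal(unname(pr$composition["eqtl_and_proximity"]),
                 sum(nc$eqtl & (nc$pd | nc$ld)))
    expect_equal(unname(pr$composition["proximity_only"]),
                 sum(!nc$eqtl & (nc$pd | nc$ld)))
  }
})

test_that("a single coding SNP yields one gene with coding evidence only", {
  gm <- rbind(gmRow("G1", "c1", 100, 1000, "span"),
              gmRow("G1", "c1", 100, 200, "exon"))
  pr <- prioritizeGenes(snp("r1", "c1", 150), gm,
                        elements = data.frame(symbol = character(),
                                              name = character(),
                                              chrom = character(),
                                              start = integer(),
                                              end = integer()),
                        proxies = data.frame(rsid = character(),
                                             proxy_rsid = character(),
                                             r2 = numeric(),
                                             proxy_pos = integer()),
                        eqtls = data.frame(rsid = character(),
                                           symbol = character(),
                                           tissue = character()))
  expect_equal(pr$genes$symbol, "G1")
  expect_true(pr$genes$coding)
  expect_false(any(pr$genes$pd | pr$genes$ld | pr$genes$eqtl))
  expect_equal(unname(pr$composition["n_prioritized"]), 0)
})
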