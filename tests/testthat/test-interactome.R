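## small builder for in-memory interaction rows
irow <- function(a, b, conf = 0.9, methods = "two hybrid",
                 pmids = "123", ea = "1", eb = "2") {
  data.frame(symbol_a = a, entrez_a = ea, symbol_b = b, entrez_b = eb,
             confidence = conf, detection_methods = methods,
             pubmed_ids = pmids, ambiguous_mapping = FALSE,
             nonstandard_symbol = FALSE, stringsAsFactors = FALSE)
}

writeTempPpi <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeInteractions(df, path)
  path
}

test_that("interaction reader parses records, empty fields and derives flags", {
  df <- rbind(irow("A", "B"), irow("B", "C", pmids = ""),
              irow("C", "D", ea = "11;22"), irow("d", " e_x "))
  got <- readInteractions(writeTempPpi(df))
  expect_equal(nrow(got), 4)
  expect_equal(got$pubmed_ids[2], "")
  expect_true(got$ambiguous_mapping[3])
  expect_equal(got$symbol_a[4], "D")        # normalized
  expect_true(got$nonstandard_symbol[4])    # E_X fails the symbol pattern
})

test_that("reader rejects bad confidence and missing columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol_a\tsymbol_b\tconfidence", "A\tB\t1.2"), path)
  expect_error(readInteractions(path), "confidence")
  writeLines(c("symbol_a\tsymbol_b", "A\tB"), path)
  expect_error(readInteractions(path), "columns")
})

test_that("level-zero QC keeps pmid-backed, specified-method, non-self records", {
  df <- rbind(
    irow("A", "B", methods = "unspecified"),              # unspecified only
    irow("A", "C", methods = "unspecified;two hybrid"),   # mixed: kept
    irow("A", "D", pmids = ""),                           # no pmid
    irow("E", "E"),                                       # self
    irow("F", "G"))                                       # clean
  got <- qcLevelZero(df)
  expect_equal(sort(paste(got$symbol_a, got$symbol_b)), c("A C", "F G"))
})

test_that("high-confidence filter: inclusive threshold, ubiquitin and flags", {
  df <- rbind(irow("A", "B", conf = 0.72),
              irow("A", "C", conf = 0.7199),
              irow("TP53", "UBC", conf = 0.99),
              irow("D", "E", conf = 0.9, ea = "1;2"),
              irow("F", "F", conf = 0.9))
  df2 <- readInteractions(writeTempPpi(df))
  got <- filterHighConfidence(df2)
  expect_equal(paste(got$symbol_a, got$symbol_b), "A B")
  ## strict comparison drops the boundary record
  expect_equal(nrow(filterHighConfidence(df2, strictGt = TRUE)), 0)
})

test_that("raising the confidence threshold never grows the edge set", {
  set.seed(31)
  df <- do.call(rbind, lapply(1:60, function(i)
    irow(sample(LETTERS[1:10], 1), sample(LETTERS[1:10], 1),
         conf = round(runif(1), 3))))
  prev <- Inf
  for (thr in c(0.2, 0.5, 0.72, 0.9)) {
    n <- nrow(filterHighConfidence(df, threshold = thr))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("bridge definition on the two canonical cases", {
  seeds <- c("S1", "S2")
  ## X adjacent to both seeds, seeds unconnected -> bridge
  expect_equal(findBridges(seeds, rbind(irow("X", "S1"), irow("X", "S2"))),
               "X")
  ## seeds already directly connected -> not a bridge
  expect_equal(findBridges(seeds, rbind(irow("X", "S1"), irow("X", "S2"),
                                        irow("S1", "S2"))),
               character(0))
})

test_that("bridge set equals the brute-force pairwise oracle on random graphs", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    nodes <- sprintf("N%02d", seq_len(n))
    seeds <- sample(nodes, ceiling(n / 3))
    nedge <- sample(10:60, 1)
    a <- sample(nodes, nedge, replace = TRUE)
    b <- sample(nodes, nedge, replace = TRUE)
    keep <- a != b
    df <- do.call(rbind, Map(irow, a[keep], b[keep]))
    expect_equal(findBridges(seeds, df),
                 bruteBridges(seeds, data.frame(a = a[keep], b = b[keep])))
  }
})

test_that("level-zero census separates components, core and isolated seeds", {
  seeds <- c("A", "B", "C", "D", "E")
  l0 <- buildLevelZero(seeds, rbind(irow("A", "B"), irow("C", "D")))
  expect_equal(l0$report$n_nodes, c(2, 2))
  expect_equal(l0$core, c("A", "B"))       # tie broken lexicographically
  expect_equal(l0$isolated, "E")
  ## no seed-seed edges at all
  l0b <- buildLevelZero(seeds, irow("X", "Y"))
  expect_equal(nrow(l0b$report), 0)
  expect_equal(l0b$isolated, sort(seeds))
})

test_that("level-one keeps bridges on path duty and drops decoys", {
  seeds <- c("S1", "S2", "S3")
  df <- rbind(irow("X", "S1"), irow("X", "S2"),    # true bridge
              irow("S1", "S3"),
              irow("Y", "S1"), irow("Y", "S3"))    # decoy: S1-S3 connected
  l1 <- buildLevelOne(seeds, df)
  expect_equal(l1$bridges, "X")
  roles <- nodeRoles(l1$core)
  expect_setequal(names(roles), c("S1", "S2", "S3", "X"))
  expect_equal(sum(roles == "bridge"), 1L)
  ## level-one node set = seeds plus bridges, never decoys
  expect_setequal(names(nodeRoles(l1$network)), c(seeds, "X"))
})

test_that("level-one recovers the generator's planted design exactly", {
  seeds <- sprintf("SD%02d", 1:40)
  sim <- simulateInteractome(seeds, seed = 5, nCoreSeeds = 20,
                             nPendantPairs = 2, nExtra = 5, nBridges = 12,
                             coreDensity = 0.15, nDecoys = 6)
  l0 <- buildLevelZero(seeds, qcLevelZero(sim$interactions))
  expect_equal(sort(l0$core), sim$truth$coreSeeds)
  expect_equal(l0$report$n_nodes, c(20, 2, 2))
  hc <- filterHighConfidence(sim$interactions)
  l1 <- buildLevelOne(seeds, hc)
  expect_equal(l1$bridges, sort(sim$truth$bridges))
  expect_equal(sort(names(nodeRoles(l1$core))), sim$truth$l1CoreNodes)
  ## every reported bridge satisfies the definitional predicate post hoc
  pr <- unique(data.frame(a = pmin(hc$symbol_a, hc$symbol_b),
                          b = pmax(hc$symbol_a, hc$symbol_b)))
  expect_equal(l1$bridges, bruteBridges(seeds, pr))
})

test_that("edge set is invariant under row order and endpoint swap", {
  df <- rbind(irow("A", "B"), irow("C", "A"), irow("B", "D"))
  swapped <- df[c(3, 1, 2), ]
  tmp <- swapped$symbol_a; swapped$symbol_a <- swapped$symbol_b
  swapped$symbol_b <- tmp
  l1a <- buildLevelZero(c("A", "B", "C", "D"), df)
  l1b <- buildLevelZero(c("A", "B", "C", "D"), swapped)
  canon <- function(net) {
    el <- igraph::as_edgelist(networkGraph(net))
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_equal(canon(l1a$network), canon(l1b$network))
})

test_that("hub ranking is by degree then name and matches an edge recount", {
  seeds <- c("H", sprintf("S%02d", 1:20))
  df <- do.call(rbind, lapply(sprintf("S%02d", 1:20), function(s)
    irow("H", s)))
  l0 <- buildLevelZero(seeds, df)
  hubs <- hubNodes(l0$network, minDegree = 14)
  expect_equal(hubs$symbol, "H")
  expect_equal(hubs$degree, 20L)
  expect_equal(nrow(hubNodes(l0$network, minDegree = 21)), 0)
  ## recount incident edges independently
  el <- igraph::as_edgelist(networkGraph(l0$network))
  expect_equal(hubs$degree, sum(el == "H"))
})

test_that("networks round-trip through edge/node TSVs and export GraphML", {
  seeds <- c("S1", "S2", "S3")
  l1 <- buildLevelOne(seeds, rbind(irow("X", "S1"), irow("X", "S2")))
  ep <- withr::local_tempfile(fileext = ".tsv")
  np <- withr::local_tempfile(fileext = ".tsv")
  writePpiNetwork(l1$network, ep, np)
  back <- readPpiNetwork(ep, np, level = 1L)
  expect_equal(sort(names(nodeRoles(back))), sort(names(nodeRoles(l1$network))))
  expect_equal(nodeRoles(back)[sort(names(nodeRoles(back)))],
               nodeRoles(l1$network)[sort(names(nodeRoles(l1$network)))])
  gml <- withr::local_tempfile(fileext = ".graphml")
  exportGraphML(l1$core, gml)
  expect_true(file.exists(gml) && file.size(gml) > 0)
})
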