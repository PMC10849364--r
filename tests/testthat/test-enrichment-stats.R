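test_that("Welch statistic, df and p agree with stats::t.test to 1e-10", {
  set.seed(41)
  for (rep in 1:25) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    x <- rnorm(n1, 0, runif(1, 0.5, 3))
    y <- rnorm(n2, runif(1, -2, 2), runif(1, 0.5, 3))
    got <- welchTest(x, y)
    ref <- stats::t.test(y, x, var.equal = FALSE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch degenerate and error cases", {
  expect_equal(welchTest(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welchTest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  z <- welchTest(c(5, 5, 5), c(5, 5))          # zero variance, equal means
  expect_equal(c(z$t, z$p), c(0, 1))
  sep <- welchTest(c(1, 2, 3), c(11, 12, 13) + rnorm(3, 0, 1e-3))
  expect_lt(sep$p, 0.01)
  expect_error(welchTest(1, c(1, 2)), "at least 2")
})

test_that("row-wise Welch inside validateExpression matches per-row t.test", {
  set.seed(43)
  mat <- 2^matrix(rnorm(20 * 10, 8, 0.5), nrow = 20,
                  dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  groups <- rep(c("a", "b"), each = 5)
  st <- validateExpression(mat, groups)
  for (i in seq_len(20)) {
    ref <- stats::t.test(log2(mat[i, 6:10]), log2(mat[i, 1:5]))
    expect_equal(st$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(st$p[i], ref$p.value, tolerance = 1e-10)
  }
  expect_equal(st$log2fc,
               unname(log2(rowMeans(mat[, 6:10]) / rowMeans(mat[, 1:5]))),
               tolerance = 1e-12)
})

test_that("validateExpression accepts a SummarizedExperiment", {
  mat <- 2^matrix(rnorm(6 * 8, 8, 0.5), nrow = 6,
                  dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:8)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = mat),
    colData = S4Vectors::DataFrame(group = rep(c("n", "t"), each = 4)))
  expect_equal(validateExpression(se),
               validateExpression(mat, rep(c("n", "t"), each = 4)))
})

test_that("Bonferroni mask is strict and reproduces the printed cut", {
  bm <- bonferroniMask(c(0.004, 0.005, 0.006), alpha = 0.05)
  ## m = 3 here; threshold from m = 10 p-values
  expect_equal(bonferroniMask(rep(0.5, 10))$threshold, 0.005)
  expect_equal(bonferroniMask(rep(0.5, 10), 0.05)$significant,
               rep(FALSE, 10))
  ## exact boundary is not significant
  expect_equal(bonferroniMask(c(0.005, 0.0049), alpha = 0.01)$significant,
               c(FALSE, TRUE))
  ## the published genome-wide cut: 0.05 over 22,321 tests
  thr <- bonferroniMask(rep(1, 22321))$threshold
  expect_equal(signif(thr, 3), 2.24e-6)
})

test_that("fold-change classes are nested, gated on significance, strict", {
  lfc <- c(3.5, -8, 2, 4.2, -2.5, 0.5)
  sig <- c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  cls <- fcClasses(lfc, sig)
  expect_equal(unname(cls[1, ]), c(TRUE, TRUE, FALSE))
  expect_equal(unname(cls[2, ]), c(FALSE, FALSE, FALSE)) # not significant
  expect_equal(unname(cls[3, ]), c(FALSE, FALSE, FALSE)) # exactly 2: strict
  expect_equal(unname(cls[4, ]), c(TRUE, TRUE, TRUE))
  expect_equal(unname(cls[5, ]), c(TRUE, FALSE, FALSE))
  ## nesting holds on random inputs, both scales
  set.seed(47)
  lfc <- rnorm(200, 0, 3); sig <- runif(200) < 0.5
  for (sc in c("log2", "linear")) {
    m <- fcClasses(lfc, sig, scale = sc)
    expect_true(all(!m[, "fc3"] | m[, "fc2"]))
    expect_true(all(!m[, "fc4"] | m[, "fc3"]))
    expect_true(all(!m[!sig, ]))
  }
  ## linear scale: log2fc 1.2 is a 2.3-fold change
  expect_true(fcClasses(1.2, TRUE, scale = "linear")[, "fc2"])
  expect_false(fcClasses(1.2, TRUE, scale = "log2")[, "fc2"])
})

test_that("overlap enrichment handles saturation, empty query and determinism", {
  uni <- sprintf("u%03d", 1:30)
  expect_warning(sat <- overlapEnrichment(uni, uni, uni, nSims = 50, seed = 1),
                 "degenerate")
  expect_equal(sat@pNorm, 1)            # k equals the degenerate null mean
  expect_true(sat@degenerate)
  ## empty query: zero overlap, and the all-zero null is degenerate
  expect_warning(
    emp <- overlapEnrichment(character(0), uni[1:5], uni, nSims = 50, seed = 1),
    "degenerate")
  expect_equal(emp@nOverlap, 0L)
  a <- overlapEnrichment(uni[1:10], uni[5:20], uni, nSims = 500, seed = 9)
  b <- overlapEnrichment(uni[1:10], uni[5:20], uni, nSims = 500, seed = 9)
  expect_equal(a@pNorm, b@pNorm)
  expect_equal(a@nullMean, b@nullMean)
  ## genes outside the universe are dropped with a warning (the clipped
  ## query then saturates the universe, so the null is degenerate too)
  expect_warning(
    expect_warning(overlapEnrichment(sprintf("u%03d", 1:40), uni[1:3],
                                     uni[1:20], nSims = 50, seed = 1),
                   "outside the universe"),
    "degenerate")
})

test_that("simulated null mean matches the hypergeometric expectation", {
  uni <- sprintf("u%04d", 1:500)
  model <- uni[1:50]
  res <- overlapEnrichment(uni[26:75], model, uni, nSims = 20000, seed = 3)
  ## E[overlap] = |q| * |m| / N = 50 * 50 / 500 = 5
  expect_equal(res@nullMean, 5, tolerance = 0.1)
  expect_equal(res@nOverlap, 25L)
})

test_that("DE overlay reproduces the planted fraction and a brute-force filter", {
  model <- sprintf("M%03d", 1:402)
  uni <- c(model, sprintf("U%04d", 1:5000))
  sim <- simulateDeTable(uni, model, fractionModel = 215 / 402,
                         fractionBackground = 0.3, seed = 6)
  ov <- overlayDe(sim$de, model)
  expect_equal(ov$n_overlap, 215L)
  expect_equal(ov$fraction, 215 / 402)
  expect_equal(ov$overlap, sim$truth$modelOverlap)
  ## brute force: filter then intersect
  brute <- sort(intersect(model, sim$de$gene[sim$de$p_adj < 0.05]))
  expect_equal(ov$overlap, brute)
  ## no DE genes
  none <- sim$de; none$p_adj <- 1
  expect_equal(overlayDe(none, model)$fraction, 0)
})

test_that("hypergeometric term enrichment matches tail-sum enumeration and BH", {
  uni <- sprintf("g%02d", 1:40)
  ann <- list(T1 = uni[1:8], T2 = uni[30:40], T3 = uni[1:20])
  query <- uni[1:10]
  res <- hypergeomTermEnrichment(query, ann, uni)
  expect_equal(res$term_id[1], "T1")      # query covers T1 almost fully
  for (i in seq_len(nrow(res))) {
    K <- res$term_size[i]; k <- res$intersection_size[i]
    expect_equal(res$p_value[i], hyperTailSum(k, K, 40, 10),
                 tolerance = 1e-12)
  }
  expect_equal(sort(res$adjusted_p_value),
               sort(stats::p.adjust(res$p_value, "BH")))
  ## disjoint term has p = 1
  expect_equal(res$p_value[res$term_id == "T2"], 1)
  expect_error(hypergeomTermEnrichment(query, ann, character(0)), "universe")
})
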