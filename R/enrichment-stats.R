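#' @importFrom stats pnorm pt phyper p.adjust sd var
#' @importFrom SummarizedExperiment colData assay
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Welch's two-sample t-test (direct formulas)
#'
#' Welch-Satterthwaite statistic, degrees of freedom and two-sided p-value
#' for two independent samples with unequal variances. The statistic is
#' oriented as group2 minus group1. When both variances are zero and the
#' means are equal the test is degenerate and returns t = 0, p = 1.
#'
#' @param x,y numeric sample vectors (each of length >= 2).
#' @return named list with \code{t}, \code{df}, \code{p}.
#' @export
welchTest <- function(x, y) {
  .assert(length(x) >= 2 && length(y) >= 2,
          "Welch test needs at least 2 samples per group")
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  diff <- mean(y) - mean(x)
  if (se2 == 0) {
    if (diff == 0) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(diff) * Inf, df = NA_real_, p = 0))
  }
  t <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

## row-wise Welch over a matrix split into two sample groups
.welchRows <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(mat[, idx1, drop = FALSE])
  m2 <- rowMeans(mat[, idx2, drop = FALSE])
  v1 <- rowSums((mat[, idx1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat[, idx2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  deg <- se2 == 0
  if (any(deg)) {                      # zero variance in both groups
    same <- deg & (m2 - m1 == 0)
    t[same] <- 0; p[same] <- 1
    t[deg & !same] <- sign((m2 - m1)[deg & !same]) * Inf
    p[deg & !same] <- 0
    df[deg] <- NA_real_
  }
  data.frame(t = t, df = df, p = p)
}

#' Bonferroni significance mask
#'
#' Strict comparison p < alpha / m, matching the published "P <" cut (with
#' alpha = 0.05 and the 22,321 genes of the two-group re-analysis this gives
#' the 2.24e-6 threshold).
#'
#' @param p numeric vector of p-values.
#' @param alpha family-wise error rate, default 0.05.
#' @return list with \code{threshold} (= alpha/m) and logical
#'   \code{significant} mask.
#' @export
bonferroniMask <- function(p, alpha = 0.05) {
  m <- length(p)
  .assert(m >= 1, "need at least one p-value")
  thr <- alpha / m
  list(threshold = thr, significant = p < thr)
}

#' Nested fold-change classes
#'
#' Assigns significant genes to the nested classes FC2 / FC3 / FC4: class
#' FC_k contains the significant genes with absolute fold change strictly
#' greater than k. On the default \code{scale = "log2"} the thresholds apply
#' to the log2 fold change; with \code{scale = "linear"} they apply to the
#' signed linear ratio (2^log2fc, negated for down-regulation). Genes that
#' are not significant belong to no class regardless of their fold change.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param significant logical vector (same length).
#' @param thresholds increasing magnitudes, default c(2, 3, 4).
#' @param scale "log2" or "linear".
#' @return logical matrix with one column per threshold (named fc2, fc3,
#'   fc4 for the defaults); columns are nested by construction.
#' @export
fcClasses <- function(log2fc, significant, thresholds = c(2, 3, 4),
                      scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  .assert(length(log2fc) == length(significant),
          "log2fc and significant lengths differ")
  fc <- if (scale == "log2") log2fc
        else sign(log2fc) * 2^abs(log2fc)
  out <- vapply(thresholds, function(k) significant & abs(fc) > k,
                logical(length(log2fc)))
  out <- matrix(out, ncol = length(thresholds))
  colnames(out) <- paste0("fc", thresholds)
  out
}

#' Two-group expression re-analysis
#'
#' Re-analysis of a two-group intensity matrix in the style of the
#' melanoma-vs-normal-skin comparison: per-gene log2 fold change
#' (log2 of the group-2/group-1 linear mean ratio), Welch t-test on
#' log2-transformed intensities, strict Bonferroni correction, and nested
#' fold-change classes for the significant genes.
#'
#' @param object genes x samples matrix of linear-scale intensities with
#'   unique rownames, or a \code{SummarizedExperiment} whose first assay is
#'   the intensity matrix and whose colData has a \code{group} column.
#' @param groups factor/vector with two levels, one entry per sample (for
#'   the matrix method). The first level is the reference (e.g. normal skin).
#' @param alpha family-wise error rate for Bonferroni, default 0.05.
#' @param fcThresholds fold-change class magnitudes, default c(2, 3, 4).
#' @param fcScale scale the thresholds apply on, see [fcClasses()].
#' @return data.frame with one row per gene: \code{gene}, \code{log2fc},
#'   \code{t}, \code{df}, \code{p}, \code{significant} and one logical
#'   column per fold-change class.
#' @export
setGeneric("validateExpression",
           function(object, groups, alpha = 0.05, fcThresholds = c(2, 3, 4),
                    fcScale = "log2")
             standardGeneric("validateExpression"))

#' @rdname validateExpression
#' @export
setMethod("validateExpression", "matrix",
  function(object, groups, alpha = 0.05, fcThresholds = c(2, 3, 4),
           fcScale = "log2") {
    .assert(!is.null(rownames(object)) && !anyDuplicated(rownames(object)),
            "expression matrix needs unique rownames (gene ids)")
    groups <- as.factor(groups)
    .assert(nlevels(groups) == 2, "exactly two sample groups required")
    .assert(length(groups) == ncol(object),
            "one group label per sample required")
    idx1 <- which(groups == levels(groups)[1])
    idx2 <- which(groups == levels(groups)[2])
    .assert(length(idx1) >= 2 && length(idx2) >= 2,
            "at least 2 samples per group required")
    .assert(all(object > 0), "intensities must be positive (linear scale)")
    log2fc <- log2(rowMeans(object[, idx2, drop = FALSE]) /
                   rowMeans(object[, idx1, drop = FALSE]))
    wt <- .welchRows(log2(object), idx1, idx2)
    bf <- bonferroniMask(wt$p, alpha)
    cls <- fcClasses(log2fc, bf$significant, fcThresholds, fcScale)
    res <- data.frame(gene = rownames(object), log2fc = log2fc,
                      t = wt$t, df = wt$df, p = wt$p,
                      significant = bf$significant,
                      stringsAsFactors = FALSE, row.names = NULL)
    cbind(res, as.data.frame(cls))
  })

#' @rdname validateExpression
#' @export
setMethod("validateExpression", "SummarizedExperiment",
  function(object, groups, alpha = 0.05, fcThresholds = c(2, 3, 4),
           fcScale = "log2") {
    if (missing(groups))
      groups <- SummarizedExperiment::colData(object)$group
    validateExpression(as.matrix(SummarizedExperiment::assay(object, 1)),
                       groups, alpha, fcThresholds, fcScale)
  })

#' Monte-Carlo gene-set overlap enrichment
#'
#' Tests whether a query gene set overlaps the network-model gene set more
#' than random same-size gene lists do. Each of \code{nSims} simulations
#' draws \code{|query|} genes uniformly without replacement from the
#' universe and records the overlap with the model set; the p-value is the
#' upper tail of a normal with the sample mean and sd (n-1 denominator) of
#' the simulated overlaps, with no continuity correction
#' (\code{pnorm(k, mean, sd, lower.tail = FALSE)}). Lists are plain gene
#' label draws, not degree-preserving.
#'
#' @param query,model,universe character gene vectors; query and model are
#'   intersected with the universe (with a warning when genes fall outside).
#' @param nSims number of simulations, default 100000.
#' @param seed RNG seed; the result is deterministic given the seed.
#' @return an [OverlapResult-class].
#' @export
overlapEnrichment <- function(query, model, universe, nSims = 100000,
                              seed = 1L) {
  universe <- unique(normalizeSymbols(universe))
  query <- unique(normalizeSymbols(query))
  model <- unique(normalizeSymbols(model))
  if (!all(query %in% universe)) {
    warning("query genes outside the universe were dropped")
    query <- intersect(query, universe)
  }
  if (!all(model %in% universe)) {
    warning("model genes outside the universe were dropped")
    model <- intersect(model, universe)
  }
  .assert(length(query) <= length(universe), "query larger than universe")
  k <- length(intersect(query, model))
  member <- universe %in% model
  nU <- length(universe); nQ <- length(query)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  draws <- if (nQ == 0) rep(0L, nSims) else
    vapply(seq_len(nSims),
           function(i) sum(member[sample.int(nU, nQ)]), integer(1))
  mu <- mean(draws)
  sg <- stats::sd(draws)
  degenerate <- sg == 0
  p <- if (degenerate) {
    warning("degenerate null: all simulated overlaps identical")
    if (k > mu) 0 else 1
  } else stats::pnorm(k, mean = mu, sd = sg, lower.tail = FALSE)
  new("OverlapResult", nOverlap = as.integer(k), nQuery = as.integer(nQ),
      nModel = as.integer(length(model)), nUniverse = as.integer(nU),
      nSims = as.integer(nSims), nullMean = mu, nullSd = sg, pNorm = p,
      seed = as.integer(seed), degenerate = degenerate)
}

#' Overlay a differential-expression table on the network model
#'
#' Intersects the genes significant in a DE result table (adjusted p below
#' \code{padjMax}, strict) with the model gene set.
#'
#' @param deTable data.frame with columns \code{gene}, \code{log2fc} (or
#'   \code{log2FC}), \code{p_value}/\code{pvalue}, \code{p_adj}/\code{padj}.
#' @param model character vector of model genes (nonempty).
#' @param padjMax adjusted-p cut, default 0.05.
#' @return list with \code{overlap} (sorted symbols), \code{n_overlap},
#'   \code{n_model} and \code{fraction} (= n_overlap / n_model).
#' @export
overlayDe <- function(deTable, model, padjMax = 0.05) {
  model <- unique(normalizeSymbols(model))
  .assert(length(model) > 0, "model gene set is empty")
  padj <- deTable$p_adj %||% deTable$padj
  .assert(!is.null(padj), "DE table needs a p_adj/padj column")
  .assert("gene" %in% names(deTable), "DE table needs a gene column")
  sig <- normalizeSymbols(deTable$gene[!is.na(padj) & padj < padjMax])
  ov <- sort(intersect(model, sig))
  list(overlap = ov, n_overlap = length(ov), n_model = length(model),
       fraction = length(ov) / length(model))
}

#' Hypergeometric term enrichment with BH correction
#'
#' Offline enrichment utility: one-sided hypergeometric p per term
#' (probability of at least the observed query/term intersection under
#' uniform sampling from the universe), Benjamini-Hochberg adjusted across
#' terms. Produces term records in the shape consumed by the semantic
#' grouping step.
#'
#' @param query character gene vector.
#' @param annotations named list, term id -> character vector of annotated
#'   genes (subsets of the universe; genes outside are dropped).
#' @param universe character gene vector (nonempty).
#' @param termNames optional named character vector, term id -> readable name.
#' @return data.frame with \code{term_id}, \code{term_name},
#'   \code{p_value}, \code{adjusted_p_value}, \code{term_size},
#'   \code{intersection_size}, sorted by p.
#' @export
hypergeomTermEnrichment <- function(query, annotations, universe,
                                    termNames = NULL) {
  universe <- unique(normalizeSymbols(universe))
  .assert(length(universe) > 0, "empty universe")
  query <- intersect(unique(normalizeSymbols(query)), universe)
  N <- length(universe); n <- length(query)
  rows <- lapply(names(annotations), function(tid) {
    term <- intersect(unique(normalizeSymbols(annotations[[tid]])), universe)
    K <- length(term)
    k <- length(intersect(query, term))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid,
               term_name = if (!is.null(termNames)) unname(termNames[tid]) else tid,
               p_value = p, term_size = K, intersection_size = k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id),
             c("term_id", "term_name", "p_value", "adjusted_p_value",
               "term_size", "intersection_size")]
  rownames(out) <- NULL
  out
}
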