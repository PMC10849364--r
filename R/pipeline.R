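#' @importFrom yaml read_yaml write_yaml
#' @importFrom jsonlite write_json
#' @importFrom tools md5sum
NULL

.CONFIG_KEYS <- c(
  ## input paths (all optional; stages without inputs are skipped)
  "snps", "gene_models", "elements", "ld_proxies", "eqtls",
  "gwas_list", "familial_list", "somatic_list", "ppi",
  "expression", "expression_groups", "de_tables", "terms", "lexicon",
  ## thresholds (defaults are the published constants)
  "hla_region",
  "half_window", "r2_min", "confidence", "min_nodes", "min_ratio",
  "padj", "alpha", "fc_thresholds", "n_sims", "min_degree",
  "max_term_size", "min_intersection", "coverage",
  "rng_seed", "out_dir")

.CONFIG_DEFAULTS <- list(
  half_window = 250000, r2_min = 0.8, confidence = 0.72,
  min_nodes = 10, min_ratio = 0.7, padj = 0.05, alpha = 0.05,
  fc_thresholds = c(2, 3, 4), n_sims = 100000, min_degree = 14,
  max_term_size = 300, min_intersection = 3, coverage = 0.5,
  rng_seed = 1L, out_dir = "melanet_out")

#' Read and validate a pipeline run configuration
#'
#' The configuration is a single human-readable YAML file; every published
#' constant is a named key with the published value as default, so any
#' deviation is visible in the run manifest. Unknown keys are rejected;
#' thresholds are checked against their documented ranges. Relative input
#' paths are resolved against the directory of the config file.
#'
#' @param path YAML config path.
#' @return validated named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(.CONFIG_DEFAULTS))
    if (is.null(cfg[[k]])) cfg[[k]] <- .CONFIG_DEFAULTS[[k]]
  .assert(cfg$r2_min >= 0 && cfg$r2_min <= 1, "r2_min outside [0, 1]")
  .assert(cfg$confidence >= 0 && cfg$confidence <= 1,
          "confidence outside [0, 1]")
  .assert(cfg$padj > 0 && cfg$padj <= 1, "padj outside (0, 1]")
  .assert(cfg$alpha > 0 && cfg$alpha <= 1, "alpha outside (0, 1]")
  .assert(cfg$min_ratio >= 0, "min_ratio must be >= 0")
  .assert(cfg$half_window >= 0, "half_window must be >= 0")
  .assert(cfg$n_sims >= 1, "n_sims must be >= 1")
  base <- dirname(normalizePath(path))
  pathKeys <- c("snps", "gene_models", "elements", "ld_proxies", "eqtls",
                "gwas_list", "familial_list", "somatic_list", "ppi",
                "expression", "expression_groups", "terms", "lexicon")
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  for (k in pathKeys) if (!is.null(cfg[[k]])) cfg[[k]] <- resolve(cfg[[k]])
  if (!is.null(cfg$de_tables))
    cfg$de_tables <- lapply(cfg$de_tables, resolve)
  cfg
}

#' Run the end-to-end risk-network pipeline
#'
#' Executes, in order: GWAS gene prioritization, three-source seed merging,
#' level-zero and level-one network construction with QC, modularity
#' clustering with cluster QC, two-group expression validation with
#' Monte-Carlo overlap enrichment of each fold-change class against the
#' model, differential-expression overlays with their own enrichment tests,
#' and keyword grouping of an enrichment-term table. Stages whose inputs
#' are absent from the config are skipped (e.g. a run may start from
#' provided seed lists instead of SNP tables). All stage outputs are TSVs
#' under \code{out_dir}; a JSON manifest records the package version, seed,
#' thresholds, input digests and per-stage row counts, and is byte-stable
#' across re-runs of identical config and inputs. Any stage error aborts
#' with the stage name.
#'
#' @param config a config list from [readRunConfig()] or a path to the
#'   YAML file.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "melanet",
    version = as.character(utils::packageVersion("melanet")),
    rng_seed = config$rng_seed,
    thresholds = config[c("half_window", "r2_min", "confidence", "min_nodes",
                          "min_ratio", "padj", "alpha", "fc_thresholds",
                          "n_sims", "min_degree")],
    inputs = list(), stages = list())
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  digestInputs <- function(...) {
    for (p in c(...)) {
      if (is.null(p)) next
      manifest$inputs[[basename(p)]] <<- unname(tools::md5sum(p))
    }
  }

  ## --- prioritize ------------------------------------------------------
  gwasList <- NULL
  if (!is.null(config$snps)) {
    stage("prioritize", {
      digestInputs(config$snps, config$gene_models, config$elements,
                   config$ld_proxies, config$eqtls)
      pr <- prioritizeGenes(
        snps = .readTsv(config$snps),
        geneModels = .readTsv(config$gene_models),
        elements = .readTsv(config$elements),
        proxies = .readTsv(config$ld_proxies),
        eqtls = .readTsv(config$eqtls),
        halfWindow = config$half_window, r2Min = config$r2_min,
        hlaRegion = config$hla_region)
      .writeTsv(pr$genes, file.path(outDir, "prioritized_genes.tsv"))
      gwasList <- pr$genes$symbol
      results$prioritize <- pr
      manifest$stages$prioritize <- list(
        n_snps = nrow(pr$snps), n_genes = nrow(pr$genes),
        composition = as.list(pr$composition))
    })
  } else if (!is.null(config$gwas_list)) {
    gwasList <- readGeneList(config$gwas_list)
    digestInputs(config$gwas_list)
  }

  ## --- merge seeds -----------------------------------------------------
  seeds <- NULL
  if (!is.null(gwasList) && !is.null(config$familial_list) &&
      !is.null(config$somatic_list)) {
    stage("merge_seeds", {
      digestInputs(config$familial_list, config$somatic_list)
      seeds <- mergeSeedLists(gwasList,
                               readGeneList(config$familial_list),
                               readGeneList(config$somatic_list))
      writeSeedTable(seeds, file.path(outDir, "seeds.tsv"))
      manifest$stages$merge_seeds <- as.list(seedComposition(seeds))
    })
  }

  ## --- networks --------------------------------------------------------
  model <- NULL
  if (!is.null(seeds) && !is.null(config$ppi)) {
    stage("network", {
      digestInputs(config$ppi)
      ppi <- readInteractions(config$ppi)
      l0 <- buildLevelZero(seeds, qcLevelZero(ppi))
      hc <- filterHighConfidence(ppi, threshold = config$confidence)
      l1 <- buildLevelOne(seeds, hc)
      writePpiNetwork(l0$network, file.path(outDir, "level0_edges.tsv"),
                      file.path(outDir, "level0_nodes.tsv"))
      writePpiNetwork(l1$core, file.path(outDir, "model_edges.tsv"),
                      file.path(outDir, "model_nodes.tsv"))
      .writeTsv(l1$report, file.path(outDir, "level1_components.tsv"))
      hubs <- hubNodes(l1$core, config$min_degree)
      .writeTsv(hubs, file.path(outDir, "model_hubs.tsv"))
      model <- sort(names(nodeRoles(l1$core)))
      results$level0 <- l0
      results$level1 <- l1
      results$hubs <- hubs
      manifest$stages$network <- list(
        n_interactions = nrow(ppi), n_qc_level0 = nrow(qcLevelZero(ppi)),
        n_high_confidence = nrow(hc),
        level0_core = length(l0$core),
        level0_isolated = length(l0$isolated),
        model_nodes = length(model),
        model_seeds = sum(nodeRoles(l1$core) == "seed"),
        model_bridges = sum(nodeRoles(l1$core) == "bridge"),
        n_hubs = nrow(hubs))
    })
  }

  ## --- clustering ------------------------------------------------------
  if (!is.null(results$level1)) {
    stage("cluster", {
      part <- greedyModularity(results$level1$core)
      qc <- qcClusters(part, nodeRoles(results$level1$core),
                       minNodes = config$min_nodes,
                       minRatio = config$min_ratio)
      mem <- communityMembership(part)
      .writeTsv(data.frame(node = names(mem), cluster_id = unname(mem)),
                file.path(outDir, "clusters.tsv"))
      .writeTsv(qc, file.path(outDir, "cluster_qc.tsv"))
      results$partition <- part
      results$clusterQc <- qc
      manifest$stages$cluster <- list(
        n_clusters = nrow(qc), n_passed_qc = sum(qc$passed_qc),
        modularity = modularityQ(part))
    })
  }

  ## --- expression validation -------------------------------------------
  if (!is.null(config$expression) && !is.null(model)) {
    stage("expression", {
      digestInputs(config$expression, config$expression_groups)
      mat <- as.matrix(.readTsv(config$expression, row.names = 1))
      grp <- .readTsv(config$expression_groups)
      groups <- factor(grp$group[match(colnames(mat), grp$sample)])
      st <- validateExpression(mat, groups, alpha = config$alpha,
                               fcThresholds = config$fc_thresholds)
      .writeTsv(st, file.path(outDir, "expression_stats.tsv"))
      universe <- st$gene
      fcCols <- paste0("fc", config$fc_thresholds)
      ovs <- lapply(seq_along(fcCols), function(i) {
        q <- st$gene[st[[fcCols[i]]]]
        overlapEnrichment(q, model, universe, nSims = config$n_sims,
                          seed = config$rng_seed + i)
      })
      names(ovs) <- fcCols
      .writeTsv(data.frame(
        class = fcCols,
        n_query = vapply(ovs, function(o) o@nQuery, integer(1)),
        n_overlap = vapply(ovs, function(o) o@nOverlap, integer(1)),
        null_mean = vapply(ovs, function(o) o@nullMean, numeric(1)),
        null_sd = vapply(ovs, function(o) o@nullSd, numeric(1)),
        p_norm = vapply(ovs, function(o) o@pNorm, numeric(1))),
        file.path(outDir, "expression_overlap.tsv"))
      results$expressionStats <- st
      results$expressionOverlaps <- ovs
      manifest$stages$expression <- list(
        n_genes = nrow(st), n_significant = sum(st$significant),
        bonferroni_threshold = config$alpha / nrow(st),
        class_sizes = lapply(ovs, function(o) o@nQuery),
        p_norm = lapply(ovs, function(o) o@pNorm))
    })
  }

  ## --- DE overlays -----------------------------------------------------
  if (!is.null(config$de_tables) && !is.null(model)) {
    stage("de_overlay", {
      overlays <- list()
      for (nm in names(config$de_tables)) {
        digestInputs(config$de_tables[[nm]])
        de <- .readTsv(config$de_tables[[nm]])
        ov <- overlayDe(de, model, padjMax = config$padj)
        sig <- normalizeSymbols(de$gene[de$p_adj < config$padj])
        enr <- overlapEnrichment(intersect(model, normalizeSymbols(de$gene)),
                                 sig, normalizeSymbols(de$gene),
                                 nSims = config$n_sims,
                                 seed = config$rng_seed + 100 + length(overlays))
        overlays[[nm]] <- list(overlay = ov, enrichment = enr)
      }
      .writeTsv(data.frame(
        treatment = names(overlays),
        n_overlap = vapply(overlays, function(o) o$overlay$n_overlap, integer(1)),
        n_model = vapply(overlays, function(o) o$overlay$n_model, integer(1)),
        fraction = vapply(overlays, function(o) o$overlay$fraction, numeric(1)),
        p_norm = vapply(overlays, function(o) o$enrichment@pNorm, numeric(1))),
        file.path(outDir, "de_overlap.tsv"))
      results$deOverlays <- overlays
      manifest$stages$de_overlay <- lapply(overlays, function(o)
        list(n_overlap = o$overlay$n_overlap,
             fraction = o$overlay$fraction, p_norm = o$enrichment@pNorm))
    })
  }

  ## --- term grouping ---------------------------------------------------
  if (!is.null(config$terms)) {
    stage("term_grouping", {
      digestInputs(config$terms, config$lexicon)
      terms <- .readTsv(config$terms)
      lex <- if (!is.null(config$lexicon)) readLines(config$lexicon)
             else defaultLexicon()
      ft <- filterTerms(terms, maxTermSize = config$max_term_size,
                        minIntersection = config$min_intersection)
      grp <- groupByKeywords(ft, lex)
      top <- topGroups(grp$groups, coverage = config$coverage)
      .writeTsv(grp$groups, file.path(outDir, "term_groups.tsv"))
      .writeTsv(top, file.path(outDir, "term_groups_top.tsv"))
      results$termGroups <- grp
      results$topGroups <- top
      manifest$stages$term_grouping <- list(
        n_terms_in = nrow(terms), n_terms_kept = nrow(ft),
        n_groups = nrow(grp$groups), n_top = nrow(top))
    })
  }

  outFiles <- sort(list.files(outDir, full.names = TRUE))
  outFiles <- outFiles[!grepl("manifest[.]json$", outFiles)]
  manifest$outputs <- as.list(stats::setNames(
    unname(tools::md5sum(outFiles)), basename(outFiles)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Write a complete synthetic input bundle plus run config
#'
#' Generates every file the pipeline consumes - SNP fixture tables, familial
#' and somatic gene lists, the interaction table, the two-group intensity
#' matrix with sample groups, and two treatment DE tables - and a matching
#' \code{config.yaml}, all under one directory. Two presets are available:
#' \code{"study"} reproduces the study-scale conditions (54 markers,
#' 145/27/71 seed lists, a 402-node model, 7 vs 45 samples over a
#' 22,321-gene universe) and \code{"demo"} is a small fast variant with the
#' same structure for examples and tests.
#'
#' @param dir output directory (created).
#' @param seed master RNG seed; sub-generators derive fixed offsets.
#' @param preset "demo" or "study".
#' @return list with \code{config} (path to the YAML), \code{paths} and the
#'   generators' \code{truth} objects.
#' @export
writeSyntheticBundle <- function(dir, seed = 1L,
                                 preset = c("demo", "study")) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  if (preset == "study") {
    fix <- simulateSnpFixture(seed = seed + 1)
    lists <- simulateSeedLists(fix$truth$genes$symbol, seed = seed + 2)
    seedsAll <- unique(c(lists$gwas, lists$familial, lists$somatic))
    net <- simulateInteractome(seedsAll, seed = seed + 3)
    universe <- unique(c(net$truth$l1CoreNodes, seedsAll,
                         sprintf("UNIV%05d", seq_len(22321))))[seq_len(22321)]
    plan <- designFoldChangePlan(universe, net$truth$l1CoreNodes,
                                 seed = seed + 4)
    expr <- simulateExpression(universe, plan, groupSizes = c(7, 45),
                               seed = seed + 5)
    deH <- simulateDeTable(universe, net$truth$l1CoreNodes,
                           fractionModel = 215 / 402,
                           fractionBackground = 0.40, seed = seed + 6)
    deB <- simulateDeTable(universe, net$truth$l1CoreNodes,
                           fractionModel = 112 / 402,
                           fractionBackground = 0.20, seed = seed + 7)
    nSims <- 100000
  } else {
    fix <- simulateSnpFixture(seed = seed + 1, nCoding = 3, nNarrow = 8,
                              nWide = 2, nPdOnly = 12, nBoth = 6,
                              nLdOnly = 2, nEqtlOnly = 1, nEqtlPdOnly = 3,
                              nEqtlBoth = 2, nEqtlLdOnly = 1)
    lists <- simulateSeedLists(fix$truth$genes$symbol, seed = seed + 2,
                               nFamilial = 8, nSomatic = 10, nTriple = 1,
                               nGwasFam = 1, nGwasSom = 1, nFamSom = 1)
    seedsAll <- unique(c(lists$gwas, lists$familial, lists$somatic))
    net <- simulateInteractome(seedsAll, seed = seed + 3, nCoreSeeds = 20,
                               nPendantPairs = 2, nExtra = 5, nBridges = 12,
                               coreDensity = 0.15, nDecoys = 6)
    universe <- unique(c(net$truth$l1CoreNodes, seedsAll,
                         sprintf("UNIV%04d", seq_len(600))))
    plan <- designFoldChangePlan(universe, net$truth$l1CoreNodes,
                                 nFc = c(40, 20, 8), nModelFc = c(6, 3, 1),
                                 seed = seed + 4)
    expr <- simulateExpression(universe, plan, groupSizes = c(5, 8),
                               seed = seed + 5)
    deH <- simulateDeTable(universe, net$truth$l1CoreNodes,
                           fractionModel = 0.5, fractionBackground = 0.2,
                           seed = seed + 6)
    deB <- simulateDeTable(universe, net$truth$l1CoreNodes,
                           fractionModel = 0.25, fractionBackground = 0.1,
                           seed = seed + 7)
    nSims <- 2000
  }

  .writeTsv(fix$snps, p("snps.tsv"))
  .writeTsv(fix$geneModels, p("gene_models.tsv"))
  .writeTsv(fix$elements, p("elements.tsv"))
  .writeTsv(fix$proxies, p("ld_proxies.tsv"))
  .writeTsv(fix$eqtls, p("eqtls.tsv"))
  writeLines(c("# familial melanoma genes (synthetic)", lists$familial),
             p("familial.txt"))
  writeLines(c("# somatic melanoma genes (synthetic)", lists$somatic),
             p("somatic.txt"))
  writeInteractions(net$interactions, p("ppi.tsv"))
  exprDf <- data.frame(gene = rownames(expr$exprs),
                       round(expr$exprs, 4), check.names = FALSE)
  .writeTsv(exprDf, p("expression.tsv"))
  .writeTsv(data.frame(sample = colnames(expr$exprs),
                       group = as.character(expr$groups)),
            p("expression_groups.tsv"))
  .writeTsv(deH$de, p("de_harmine.tsv"))
  .writeTsv(deB$de, p("de_berberine.tsv"))

  cfg <- list(
    snps = "snps.tsv", gene_models = "gene_models.tsv",
    elements = "elements.tsv", ld_proxies = "ld_proxies.tsv",
    eqtls = "eqtls.tsv", familial_list = "familial.txt",
    somatic_list = "somatic.txt", ppi = "ppi.tsv",
    expression = "expression.tsv",
    expression_groups = "expression_groups.tsv",
    de_tables = list(harmine = "de_harmine.tsv",
                     berberine = "de_berberine.tsv"),
    hla_region = fix$hlaRegion,
    n_sims = nSims, rng_seed = seed, out_dir = file.path(dir, "out"))
  yaml::write_yaml(cfg, p("config.yaml"))

  list(config = p("config.yaml"),
       paths = list(dir = dir),
       truth = list(fixture = fix$truth, lists = lists$truth,
                    network = net$truth, expression = expr$truth,
                    de = list(harmine = deH$truth, berberine = deB$truth)))
}
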