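# melanet

Seeded protein–protein interaction (PPI) network modeling of the cutaneous
melanoma risk-gene landscape, for computational biologists studying how a
disease's genetic risk elements operate together as a functional unit rather
than as isolated genes.

## What it does

Melanoma risk is spread over germline familial mutations, recurrent somatic
mutations, and dozens of GWAS loci whose causal genes are uncertain. `melanet`
implements the full in-silico modeling pipeline around that problem:

1. **GWAS locus-to-gene prioritization.** Risk SNPs are classified as coding
   (exon/3′ UTR of a coding ORF), intronic, or intergenic. For each noncoding
   marker, candidate genes are collected from a physical-distance locus
   (±250 kb), a linkage-disequilibrium locus (all proxies with *r*² ≥ 0.8),
   and skin eQTL associations; elements whose names carry non-coding biotype
   keywords (pseudogene, antisense, lncRNA, …) are removed.
2. **Seed-list merging.** GWAS, familial and somatic gene lists are unioned
   into a unique risk-gene table with per-source provenance and Venn
   composition counts.
3. **Network construction.** From a HIPPIE-style literature interaction
   table: a *level-zero* network of direct seed–seed interactions (records
   without a PubMed id or with only "unspecified" detection methods are
   discarded), and a *level-one* network that keeps high-confidence records
   (score ≥ 0.72; ubiquitin partners UBB/UBC/UBD and ambiguous mappings
   removed) and adds *bridges* — non-seed proteins interacting with ≥ 2 seeds
   that are not directly connected. The largest connected component of the
   level-one graph is the disease model.
4. **Clustering.** Fast-greedy (Clauset–Newman–Moore style) modularity
   maximization with a deterministic tie-break, followed by cluster QC
   (size ≥ 10 nodes and seed:bridge ratio ≥ 0.7).
5. **Statistical validation.** Two-group expression re-analysis (Welch *t*
   per gene, strict Bonferroni, nested fold-change classes |FC| > 2/3/4) and
   a Monte-Carlo overlap-enrichment test: the observed overlap *k* between a
   gene set and the model is compared against 100,000 random same-size gene
   lists, with p = 1 − Φ((k − μ)/σ) from the fitted null.
6. **Term post-processing.** Term-size / intersection-size filters,
   keyword-lexicon semantic grouping with contribution percentages, top-group
   selection covering > 50% of the enrichment, and ontology parent–child
   components.

A synthetic-data module generates every input the pipeline consumes — with
planted ground truth — standing in for HIPPIE, dbSNP/SNPsnap, GTEx, the
GDS1375 arrays and treatment RNA-seq DE tables, so the entire analysis is
testable offline.

## Worked example

```r
library(melanet)

dir <- tempfile()
b <- writeSyntheticBundle(dir, seed = 5, preset = "demo")
res <- runPipeline(b$config)

res$level1$core
#> PpiNetwork level 1: 37 nodes (25 seeds, 12 bridges), 66 edges

seedComposition(readSeedTable(file.path(dir, "out", "seeds.tsv")))
#> single double triple  total
#>     33      3      1     37

res$deOverlays$harmine$overlay$n_overlap   # model genes DE after treatment
#> [1] 18
```

The model network is the largest level-one component (seeds plus bridges);
the seed table shows how many risk genes came from one, two or all three
sources; the overlay count is how many model genes moved under treatment
(18/37 here, by the bundle's planted design). `res$manifest` records seeds,
thresholds and input digests, and re-running the same config reproduces
byte-identical outputs.

A thin command-line wrapper ships in `inst/scripts/melanet.R`
(`Rscript melanet.R synth --dir d --seed 17` / `Rscript melanet.R run
--config d/config.yaml`).

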