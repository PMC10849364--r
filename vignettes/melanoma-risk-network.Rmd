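---
title: "Modeling the melanoma risk-gene network: methods and design"
author: "melanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the melanoma risk-gene network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melanet)
```

## The modeling approach

Complex diseases such as cutaneous melanoma are driven by many risk elements
of individually small effect. `melanet` treats the disease's genetic risk
landscape as a single object: the risk genes ("seeds") are mapped onto the
literature protein interactome, expanded by one shell of shared interactors
("bridges"), and the resulting network model is interrogated as a unit —
partitioned into functional communities and tested for enrichment of
independently derived gene sets (differential expression in tumor tissue, or
after drug treatment).

The pipeline assumes only that (i) proteins that work together tend to
interact, so co-disease genes should be closer than random in the
interactome, and (ii) literature interaction tables, after confidence and
provenance QC, are a usable if incomplete snapshot of that interactome.
Ascertainment bias is inherent: well-studied proteins have more recorded
interactions, which is why the statistics compare against explicit random
nulls rather than interpreting raw connectivity.

## Stages and their parameters

### Locus-to-gene prioritization

A marker inside an exon or 3′ UTR of a coding ORF is taken to act through
that gene. Noncoding markers are annotated three ways, and every candidate
gene keeps its evidence flags:

| parameter | default | meaning |
|---|---|---|
| `halfWindow` | 250,000 bp | physical-distance window around the marker |
| `r2Min` | 0.8 | proxy inclusion cut for the LD locus (inclusive) |
| eQTL tissues | skin, sun-exposed + not-sun-exposed | union per marker |
| exclusion keywords | `defaultExclusionKeywords()` | non-coding biotypes removed by name substring |

Coordinates are 1-based, intervals inclusive at both ends, and overlap means
at least one shared base pair; windows are clipped at position 1 only (no
assembly lengths are required). Gene symbols are uppercased and trimmed
before any set operation so joins across sources behave as set algebra.
Markers flagged inside a configurable HLA interval are annotated by physical
distance only — LD structure there is too complex to trust a proxy panel —
and a marker with no row at all in the proxy table is treated as absent from
the panel (presence without usable proxies is encoded by a self row). The
keyword filter matches case-insensitive substrings and includes both the
"IncRNA" and "lncRNA" spellings of the long-noncoding keyword, so either
rendering of annotation exports is caught. A marker lying in exons of two
overlapping ORFs is attached to both, since nothing in the data
disambiguates the host.

### Seed merging and network construction

The GWAS, familial and somatic lists merge into a provenance-flagged
`SeedTable`; a locus like CDKN2A that encodes two proteins is one node
because the table is keyed by symbol.

Level-zero QC keeps interaction records with at least one PubMed id and at
least one detection method other than "unspecified", and drops
self-interactions. The level-one download is instead filtered by confidence
score at 0.72 — the high-confidence third quartile of the HIPPIE score
distribution. The cut is applied *inclusively* (`>= 0.72`); the boundary had
to be fixed one way and exposing `strictGt` makes the choice testable.
Ubiquitin partners (UBB, UBC, UBD) are removed as unspecific, as are records
with ambiguous Entrez mappings or nonstandard symbols. A non-seed interactor
is a bridge when among its seed neighbors at least one pair lacks a direct
edge — the existential reading: one unconnected pair suffices for a
candidate touching three or more seeds. Level-one seed–seed edges come from
the high-confidence set, not from the manually QC'd level-zero set, because
the confidence rule governs the whole level-one download; bridge–bridge
edges are out of scope by construction. Components are ranked by size with
ties broken by the smallest member name, so output ordering is
deterministic. Hubs default to degree ≥ 14, the published hub range being
14–41 edges.

### Clustering

`greedyModularity()` is agglomerative modularity maximization: starting from
singletons, repeatedly merge the connected community pair with the largest
modularity gain ΔQ = e_ij/m − d_i d_j /(2m²), stopping when no merge has
ΔQ > 0. Two numerical choices matter:

* **Tie-break.** Equal gains (within 1e-12) are resolved by the smallest
  lexicographic (min-label, max-label) community pair, labels being the
  smallest member node. Partitions are therefore bit-reproducible. Exhaustive
  branching over all maximal-gain merges on small graphs shows tie branches
  can end at different final Q; the deterministic rule selects one reachable
  leaf, and the test suite verifies membership in that exhaustively
  enumerated set rather than pretending greedy agglomeration has a unique
  optimum.
* **Q of the final partition** is computed with `igraph::modularity`, an
  implementation independent of the merge loop's incremental bookkeeping.

Cluster QC requires `minNodes` (default 10) and a seed:bridge ratio of at
least 0.7. The size threshold is a declared convention — the published QC
names a size criterion without printing the number. A cluster with zero
bridges passes the ratio (treated as +∞): an all-seed community is maximally
seed-enriched.

### Expression re-analysis and overlap enrichment

Intensities are linear-scale; the Welch test runs on log2-transformed values
(where the i.i.d. Gaussian assumption is plausible for array-style data)
while the reported log2 fold change is the log ratio of linear group means.
Bonferroni is strict (`p < alpha/m`); with the 22,321 genes of the two-group
re-analysis this lands on the 2.24e-6 genome-wide cut. Fold-change classes
are nested and gated on significance, with thresholds applied to the log2
fold change by default (`fcScale = "log2"`); the published class definitions
("fold change > 2") do not disambiguate the scale, so the linear alternative
is implemented and tested too.

The overlap test draws `nSims` (default 100,000) same-size gene lists
uniformly *without* replacement from the universe — plain label draws, not
degree-preserving — and reports p = `pnorm(k, mean, sd, lower.tail = FALSE)`
with the sample mean and n−1 sd of the simulated overlaps, no continuity
correction. The universe defaults to the genes measured in the experiment,
the natural sampling frame for "random gene lists". Degenerate nulls
(sd = 0) report p = 0 or 1 by the sign of k − mean, with a warning. Two
caveats are deliberate and documented:

* overlaps are integers, so the p distribution under the null is discrete;
  calibration tests bound the Kolmogorov–Smirnov distance to uniform (< 0.1)
  rather than demanding continuous uniformity;
* a normal fitted to the null has lighter tails than the exact
  hypergeometric. Within ~3–4 sd the normal p tracks the exact tail within
  an order of magnitude; far beyond that it underestimates (e.g. an overlap
  7 sd out: exact tail ~6e-9, fitted-normal ~2e-13). Reported p-values in
  that regime should be read as "extremely significant" rather than as
  literal probabilities.

`hypergeomTermEnrichment()` (exact tail via `phyper`, BH correction) is
plumbing so the pipeline runs offline; it does not reimplement any
server-side multiple-testing scheme.

### Term grouping

Term filters are configurable in both threshold and comparator because
published analyses legitimately vary between `<` and `<=` term-size cuts;
the intersection-size rule removes terms with ≤ `minIntersection` query
genes. Keyword grouping assigns each term to the *first* matching lexicon
keyword (case-insensitive substring): an ordered lexicon is a declared
convention, not a reconstruction of any unpublished in-house pipeline, and
the lexicon is data — `defaultLexicon()` ships only for demonstrations.
Top groups are the shortest count-ordered prefix whose cumulative
contribution strictly exceeds the coverage (default 50%), ties resolved by
smaller minimum adjusted p then keyword.

## The synthetic-data module

Every pipeline input is generated with planted ground truth, emulating the
statistical structure of the real sources at the study's magnitudes:

* **SNP fixture** — 54 markers (10 coding), candidate genes planted into
  designed evidence classes: 127 PD, 53 LD and 27 eQTL genes with
  |PD∩LD| = 47, giving 25 eQTL-plus-proximity, 2 eQTL-only and 108
  proximity-only genes of 135 (these counts are mutually consistent by
  inclusion–exclusion). Wide LD spans (±400 kb) host the LD-only genes, an
  HLA marker carries an LD "trap" gene a correct pipeline must skip, one
  marker is absent from the proxy panel, and junk elements carry every
  exclusion keyword.
* **Seed lists** — 145/27/71 with 2 genes in all three lists and 7 in
  exactly two, a 232-gene union.
* **Interactome** — a 148-seed connected core (its spanning tree
  high-confidence so it survives the 0.72 cut; extra in-core edges at
  density 0.08, a quarter of them low-confidence), 4 pendant seed pairs, 46
  seeds reachable only via bridges, and 208 true bridges, so the level-one
  core has 402 nodes (194 seeds + 208 bridges). Decoy interactors attach to
  already-connected pairs or to single seeds; QC junk (no PubMed,
  unspecified-only, self-interactions, ubiquitin edges, flagged mappings)
  exercises every filter.
* **Expression** — 7 vs 45 samples over 22,321 genes; log-normal
  intensities with i.i.d. Gaussian noise on the log2 scale, sd 0.25 — a
  quiet-array noise level at which a power calculation puts per-gene
  recovery of the weakest planted effect (|log2FC| = 2.2) above 98%, safely
  over the ≥ 90% recovery the tests require. Planted fold-change strata sit
  strictly between class thresholds (±2.5, ±3.5, ±4.5) with designed class
  sizes (732/364/120) and model overlaps (30/12/2).
* **DE tables** — adjusted p planted below/above 0.05 so that exactly
  215/402 (and 112/402) model genes are significant, over background DE
  rates of 0.40 and 0.20 chosen a priori so the Monte-Carlo z-scores sit in
  a realistic strong/moderate enrichment regime.

What the generator does **not** emulate: probe-level array artifacts and
normalization, heteroskedastic or correlated gene noise, degree-correlated
ascertainment in the interactome, realistic LD decay, or read-level RNA-seq.
Passing tests therefore demonstrate that the *procedures* are implemented
correctly and recover planted truth under their stated assumptions — not
that any particular biological dataset would yield the same counts.

## Problem sizes and determinism

Unit tests run on small presets (tens of genes, ≤ 40-node graphs); the
statistical properties use 500 calibration repetitions at 2,000 simulations,
100,000-simulation checks on 1,000–22,321-gene universes, and exhaustive
merge-tree enumeration on ≤ 7-node graphs — sizes chosen so the whole suite
completes in well under a minute while keeping Monte-Carlo error far below
the asserted tolerances. Every generator and every stochastic operation is a
pure function of its seed; the pipeline manifest records package version,
seed, thresholds and input digests, and identical config plus inputs yield
byte-identical output tables.

## Known limitations

* The model inherits the interactome's literature bias; hubs may reflect
  study intensity as much as biology.
* Bridge expansion stops at one shell; no level-2 or bridge–bridge edges.
* The random-list null is not degree-preserving, matching the published
  procedure; a graph-aware null would be stricter.
* Greedy modularity is a heuristic: no claim of optimal partitions, and the
  cluster count on real data depends on the interactome snapshot.
* Fold-change-class scale and the simulation universe are configurable
  because the source conventions are ambiguous; defaults are documented
  above.
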