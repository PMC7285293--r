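---
title: "Detecting metabolic gene clusters and tandem arrays, and screening them by co-expression"
author: "clusterscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting metabolic gene clusters and tandem arrays, and screening them by co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterscout)
```

## The model and its assumptions

`clusterscout` formalizes a two-stage search for the genomic signatures of
plant specialized metabolism.

**Stage 1: neighborhood chaining.** The unit of analysis is the gene (never
the transcript: only GFF3 features of a single configurable type, default
`gene`, are read). Genes assigned to one of the signature enzyme families —
P450, 2ODD, TPS, PKS, UGT by default — are chained per chromosome in
coordinate order. Two consecutive family genes belong to the same chain iff

1. at most `max_intervening` unassigned genes lie between them, **and**
2. at most `max_gap_bp` bases separate them, where the gap is the number of
   bases strictly between the end of the earlier and the start of the later
   gene (`max(0, start_j − end_i − 1)`; overlapping or abutting gene models
   count as gap 0).

Maximal chains with at least `min_genes` members are emitted as regions.
The classical definition of a biosynthetic gene cluster requires at least
three *different classes* of enzymatic genes of one pathway; with a
five-family catalog that bar is deliberately relaxed to two distinct
families for the survey category (`multi_family_cluster`), because
non-signature classes — BAHD/SCPL acyltransferases, oxidases — are
invisible to the catalog, and requiring three visible families would miss
textbook clusters such as the thalianol region (TPS + three P450s, plus an
acyltransferase the catalog cannot see). The `strict_cluster` flag records
the ≥ 3-family condition separately, so users who widen the family universe
can apply the classical bar. Regions failing the multi-family bar are
`single_family_tandem` arrays, the substrate of neo-functionalization;
their `dominant_family` is the most frequent member family.

Two assumptions are worth making explicit. Strand is parsed and carried but
never used: characterized plant clusters mix gene orientations. And pathway
membership is *not* inferred — proximity plus family composition yields
candidates, nothing more; the "same pathway" clause of the classical
definition is not computable from an annotation.

**Stage 2: mutual-rank screening.** Co-regulation is the discriminating
evidence for a functional cluster. Raw expression is transformed to
`log2(x + pseudo_count)`; genes expressed in fewer than
`min_expressed_samples` samples, or with zero variance, are dropped.
Pearson correlations are computed across samples, and each pair is scored
by the mutual rank `MR(i, j) = sqrt(rank_i(j) * rank_j(i))` — the geometric
mean of the two reciprocal rank positions, with tied correlations receiving
average (fractional) ranks, which keeps the matrix symmetric and the
computation deterministic. Rank-based scores are robust to the uneven
correlation baselines of heterogeneous compendia, which is why the
ATTED-II-style MR rather than a plain correlation cutoff is the primary
threshold. Edges satisfy `MR <= mr_max` (and optionally `pcc >= pcc_min`);
a candidate region qualifies as a co-expressed neighboring-gene cluster
when at least `min_coexpressed_members` of its members fall into one
connected component of the network. Connected components — not density
clustering — define "networks" here: the expected topology is small,
well-separated subnetworks, and components are the simplest faithful
reading of that.

By default the correlation matrix is computed over the union of
candidate-region genes only (a target-set screen of a few hundred genes),
with `genome_wide = TRUE` available when a full matrix is wanted. Region
members missing from the expression matrix are tolerated — they simply
count as "not in the network".

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `max_gap_bp` | 50 000 | bp | span scale of characterized plant clusters (tens of kb) |
| `max_intervening` | 3 | genes | clusters tolerate a few interleaved non-enzyme genes |
| `min_genes` | 3 | genes | the at-least-three-genes region definition |
| `min_distinct_families` | 2 | families | see the relaxation argument above |
| `min_jaccard` (matching) | 0.5 | — | a detected region must share most members with truth to count |
| `pseudo_count` | 1 | — | standard log2(x+1); exact inverse of the generator's export |
| `min_expressed_samples` | 3 | samples | below this a correlation is meaningless |
| `mr_max` | 30 | rank | customary MR cutoff on compendium-scale gene sets |
| `pcc_min` | disabled | — | optional belt-and-braces correlation floor |
| `min_coexpressed_members` | 3 | genes | mirrors `min_genes`: a co-expressed cluster needs ≥ 3 members |

No published value exists for the proximity constants or for the screen's
minimum size; the defaults above are this package's choices, exposed as
plain arguments (and CLI flags) throughout.

`run_demo()` overrides the network thresholds to `mr_max = 5`,
`pcc_min = 0.3`. This is deliberate: MR is bounded by n − 1, so on the
demo's ~18-gene candidate set an `mr_max` of 30 is a complete graph and
discriminates nothing. The two demo thresholds follow from the generator's
calibration, chosen before any tuning: the expected within-module
correlation at the default loading/noise is 0.5 (see below) while null
correlations at 100 samples are approximately N(0, 1/√97), so 0.3 sits
several null standard deviations above 0 and well below the module mean,
and mutually top-ranked module members have MR ≲ module size ≪ 5.

## What the synthetic generator emulates — and what it does not

`simulate_genome()` emulates an annotated plant genome at survey
granularity: 5 chromosomes of 30 Mb carrying 200 background genes, a
background family-labelling rate of 0.1, and five planted regions — a
thalianol-like TPS+P450×3 cluster and a P450/2ODD/UGT cluster (both
co-regulated), a four-family cluster without co-regulation, and UGT×4 and
P450×3 tandem arrays. Product strings are generated to match the default
keyword rules, so keyword assignment reproduces the generator's catalog
exactly.

Placement enforces a *recoverability contract*: planted regions sit at
evenly spaced anchors, background genes are excluded from an isolation zone
(60 kb, above the 50 kb default gap) around each planted span, and a
background gene keeps its family label only when it lies more than the
isolation radius from every other labelled background gene. Consequently
background genes can never chain into a ≥ 3-member region and planted
regions can never be extended or merged — detection at default settings
recovers the truth with precision = recall = 1 *by construction*. That is
the point of the contract: it turns end-to-end recovery into a sharp test
of the detector's bookkeeping rather than a statistical gamble.

`simulate_expression()` uses a one-factor linear latent model on the log2
scale: gene baselines are N(mean 5, sd 1); each co-regulated region gets
one factor `f_s ~ N(0, 1)` per sample, and member values are
`baseline + b·f_s + ε`, `ε ~ N(0, σ²)`. The implied within-module
correlation is the classical one-factor value **b²/(b² + σ²)** — 0.5 at
the defaults b = 1, σ = 1 — and between-module correlation is 0. Matrices
are exported on the raw scale as `pmax(2^v − 1, 0)`, the exact inverse of
the default preprocessing wherever no clipping occurs (with baseline mean
5, clipping is a > 3σ event per cell).

What the generator does **not** emulate, and therefore what passing tests
do not show about real data: annotation error (missed or split gene
models), family mis-assignment, chance background clustering (excluded by
the contract — the detector is stress-tested against chance clustering
separately, via a brute-force enumeration oracle on unconstrained random
genomes), heavy-tailed count noise and batch structure in expression,
condition-specific co-regulation, and any evolutionary process
(duplication/divergence) behind tandem arrays. Real surveys should treat
the qualifying list as candidates for experimental validation, nothing
stronger.

## Numerical and degenerate-input choices

- **Coordinates** are 1-based inclusive end-to-end (the GFF3 and GRanges
  convention); only the BED export shifts to 0-based half-open. Gap
  arithmetic uses the strictly-between base count, which equals the 0-based
  half-open difference, so no off-by-one ambiguity arises.
- **Determinism.** Genes are pre-sorted by (chrom, start, end, gene_id);
  ties in dominant-family selection break by canonical family order;
  greedy region matching orders by (Jaccard desc, detected index, truth
  index); network exports are written with fixed formatting, so identical
  inputs give byte-identical files. All generators consume an explicit
  seed and restore the caller's RNG state.
- **Degenerate inputs.** Empty annotations, empty catalogs and empty region
  sets flow through every stage (empty outputs, all-zero summaries);
  matching against an empty truth or detected set returns the vacuous 1.
  A region with no internal network edge reports a `mean_mr_within` of 0
  as a sentinel. Fewer than 3 expression samples is an error, not a
  warning.
- **Monotonicity.** Loosening `max_gap_bp` or `max_intervening` can only
  merge chains, never split them: each region found at tighter settings is
  contained in exactly one region at looser settings, and total emitted
  membership never shrinks. Note the emitted-region *count* is not
  monotone — two sub-threshold chains can merge past `min_genes`, creating
  a region where none existed — which is why the invariant is stated (and
  tested) as containment, not as a count.
- **Problem sizes.** The test suite runs the detector-vs-oracle comparison
  on 30 random genomes of ≤ 200 genes, mutual-rank oracles up to 50 genes,
  the calibration check on an 8-member module at 200 samples, and the
  end-to-end demo at 3 seeds — sizes chosen so the whole suite stays
  interactive (~20 s) while every code path is exercised.

## Known limitations

- Family assignment by keyword is a transparent heuristic, not a substitute
  for domain/HMM-based annotation; a curated family table always overrides
  it, and that is the recommended input for real genomes.
- Published survey counts for real genomes are not reproducible from this
  package alone: they depend on genome versions and proximity criteria that
  are not part of any standard; the package therefore validates survey
  *arithmetic* (category additivity) and algorithmic correctness
  (oracle equality, planted recovery), not historical tallies.
- The screen's qualifying rule (components + minimum member count) is one
  defensible reading of "co-expressed neighboring-gene network"; density- or
  clique-based alternatives would be stricter and are not implemented.
- No synteny, no cross-species comparison, no sequence-level evidence.

## A minimal session

```{r demo, eval = FALSE}
library(clusterscout)

# survey a genome
genes   <- read_gff3("genome.gff3")
catalog <- read_family_table("families.tsv")   # or assign_families_by_keyword(genes)
regions <- detect_neighborhoods(genes, catalog)
summarize_survey(regions, label = "my genome")

# screen candidates by co-expression
raw <- read_expression_matrix("expression.tsv")
lg  <- preprocess_expression(raw)
pc  <- pcc_matrix(lg[rownames(lg) %in% unlist(strsplit(regions$member_ids, ",")), ])
net <- build_network(pc, mutual_rank(pc), mr_max = 5, pcc_min = 0.3)
extract_coexpressed_regions(net, regions)

# or the whole thing on synthetic data
run_demo(seed = 1)
```
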