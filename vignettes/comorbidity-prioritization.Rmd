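---
title: "Prioritizing comorbidity candidate genes from paired disease networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing comorbidity candidate genes from paired disease networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbinet)
```

## The model

Two diseases that co-occur in patients more often than chance are called
comorbid. The working hypothesis of this package is that genes associated
with *both* diseases — and in particular genes that occupy structurally
and functionally central positions in the network those shared
associations form — are the most plausible drivers of the comorbid
condition. The analysis object is an **associative network**: a typed
multigraph whose vertices are gene and protein forms of gene symbols and
whose edges carry one of a registered vocabulary of interaction types
(association, genetic regulation, expression up-/down-regulation,
activity/degradation/transport regulation, protein–protein interaction,
expression, co-expression, chemical transformation, treatment). Such
networks are produced upstream by literature-mining knowledgebases; this
package starts from their exported edge lists.

The **complete comorbidity network** of a disease pair is the
intersection of the two single-disease networks. Intersection matches
edges on endpoints, interaction type *and* direction — two diseases
sharing an association between X and Y but disagreeing on its type do not
share that edge. This is deliberate: shared interaction counts are
reported per type, which is only meaningful under type-level
intersection. Shared vertices with no shared edge are retained as
isolated nodes so that every shared gene remains a ranking candidate.
The **genetic regulatory subnetwork** keeps only expression-regulation
edges (`genetic-regulation`, `expression-upregulation`,
`expression-downregulation`) and their incident vertices.

## The ten ranking criteria

Each criterion produces ordinal ranks 1..N over the N candidate genes
(the shared genes). The final score is the arithmetic mean of the ten
ranks.

* **Criteria 1–2** ingest scores from two external gene prioritizers.
  These tools are web services with their own models; the package treats
  their outputs as given rank tables (symbol, score, sort direction) and
  reports candidates they failed to score (such candidates get rank N).
* **Criterion 3** counts, for each gene, the enriched GO biological
  processes of the complete network and of the regulatory network whose
  annotation set contains the gene (N1 + N2), ranking descending.
* **Criteria 4–5** rank descending by mean3 = (DC + CC + BC)/3 on the
  complete and regulatory networks respectively.
* **Criterion 6** measures the specificity of each gene's association
  with the "test" processes (those linked to both diseases) against the
  "control" processes (all others): Welch's unequal-variance t-test
  comparing the gene's 0/1 link indicator across the two process sets,
  Bonferroni-corrected over candidates.
* **Criteria 7–10** are binary. "List Y" holds, per gene, the SNPs that
  are whole-blood eQTLs with mean minor allele frequency of at least 5%
  across the four European reference populations (CEU, GBR, IBS, TSI;
  missing populations are ignored in the mean; the threshold is
  inclusive, "at least 5%"). A gene ranks 1 under criterion 7 if it has
  any list-Y SNP; under 8 if some list-Y SNP is associated with either
  primary disease; under 9 with a disease comorbid to either; under 10
  with any other disease. Otherwise the gene receives the maximal rank
  N. The binary design intentionally gives the SNP criteria more weight
  than the graded ones: a known common regulatory polymorphism is
  directly actionable for genotyping.

### Design choices where the procedure was open

* **Tie-breaking.** Ordinal ranks need a total order; ties in any score
  are broken lexicographically by gene symbol. This is the simplest
  deterministic rule and makes every run reproducible.
* **Missing genes.** Candidates absent from an external rank table, from
  the regulatory network, or from the SNP tables receive rank N rather
  than being dropped, keeping the final mean defined over exactly ten
  ranks for every candidate — the same convention the binary criteria
  use.
* **Criterion 6 direction.** "Specifically associated" is interpreted as
  *higher* test-set link rate: genes with test mean > control mean are
  ranked first (ascending adjusted p), all others after them under the
  same ordering rule. A gene strongly linked to control processes only is
  not "specific" however small its p-value.
* **Criterion 10 exclusion.** "Any other disease" excludes the primary
  diseases and the comorbid list; a single gene may still satisfy
  criteria 8, 9 and 10 simultaneously through different SNP-disease
  links.
* **Centrality aggregation.** Centralities are computed on the simple
  undirected projection with gene and protein vertices kept distinct
  (cycles demonstrably traverse both forms), then aggregated per symbol
  by the maximum over the symbol's forms. The alternative — merging
  forms before computing — changes path structure; taking the maximum
  preserves "the symbol is central in at least one form".
* **mean3 on raw values.** DC, CC and BC live on quite different scales
  (BC is typically an order of magnitude smaller), so the raw mean is
  dominated by DC and CC. It is used regardless because the criterion is
  defined as the average of the three values, not of their ranks.

## Graph measures

All measures operate on the simple undirected projection: parallel edges
of different types collapse, antiparallel directed edges merge, and
self-loops vanish.

* DC(v) = deg(v)/(n−1).
* CC(v) uses the reachable-set scaling convention for disconnected
  graphs: with R(v) the set reachable from v (including v),
  CC(v) = ((|R|−1)/Σ d(v,u)) · ((|R|−1)/(n−1)); isolated vertices get 0.
  On a connected graph this reduces to the classical (n−1)/Σ d.
* BC(v) sums σ_st(v)/σ_st over unordered pairs s ≠ v ≠ t and is
  normalized by 2/((n−1)(n−2)); graphs with fewer than three vertices
  get an all-zero profile.

The **fundamental cycle basis** is built from a spanning forest grown by
breadth-first search, rooted at the lexicographically smallest vertex of
each component with neighbors visited in lexicographic order. Each
non-forest edge closes exactly one cycle with the forest path between its
endpoints; the basis size is |E| − |V| + (number of components).
Fundamental bases are not unique — they depend on the spanning forest —
so the *count* of basis cycles is graph-invariant while per-subset counts
(cycles containing, or consisting solely of, subset genes) can vary
between basis choices. The deterministic BFS order pins down one
reproducible basis. Subset membership is tested by symbol: the gene and
protein forms of a subset gene both count.

## Enrichment statistics

Over-representation of an annotation term in a study set uses the
hypergeometric upper tail P(X ≥ k) for k study genes among K term genes
in a population of N, or its conservative EASE variant (k replaced by
max(k−1, 0)), with Benjamini–Hochberg control and an adjusted-p threshold
of 0.01. This is an in-package stand-in for web-based enrichment
services, whose exact backgrounds and term-clustering heuristics are not
reproducible offline; the default population is every gene carried by
any annotation term, and the default statistic is EASE, the conservative
choice those services popularized. Annotations are taken as given — no
ontology-graph propagation is performed.

## Subset and literature analyses

Subset-vs-rest comparisons (centralities of apoptosis-like or CNS-like
genes, final scores of a subset) use Welch's t-test, consistent with the
specificity criterion. Two numerical guards make degenerate synthetic
cases testable: when both groups are constant and equal the result is
t = 0, p = 1; when constant but different, an epsilon variance floor
(1e−12) yields the appropriately extreme p-value instead of a failure.
The top-list co-mention analysis compares F = n_comorbid/n_total between
the top genes and the full candidate list with the Mann–Whitney U test
(exact for small untied samples, normal approximation with tie
correction otherwise; all-tied input returns the null U = n1·n2/2 with
p = 1). Genes never mentioned in the literature (n_total = 0) have
undefined F and are excluded from the test. The unnamed test behind the
subset average-rank comparison is taken to be Welch's t, for consistency
with every other subset comparison in the package.

## The synthetic knowledgebase

`generate_synthetic_dataset()` produces every input the pipeline
consumes. The default (`"full"`) profile fixes the study conditions at
knowledgebase scale: 755 and 713 disease genes with 205 shared, 9638
shared typed interactions whose type mix follows the per-type counts
observed in a real two-disease intersection (associative edges dominate
at ~83%; the regulatory types contribute ≈345 edges so the regulatory
subnetwork has realistic size), 118 test vs 13,538 control processes,
30 SNP-carrying genes, external-prioritizer noise with standard
deviation 15 on the rank scale, and co-mention rates of 0.023 (planted)
vs 0.006 (background) — the magnitudes reported for real top-10 vs
overall candidate gene lists. Ten planted "true comorbidity genes"
receive elevated endpoint weight in the shared core (boost 6), membership
in shared-gene-biased annotation terms, excess test-process link
probability (0.35 vs 0.03), three guaranteed qualifying SNPs linked to a
primary disease, a comorbid disease and an unrelated disease, favorable
external scores, and elevated co-mention counts. Each artifact draws from
its own seeded RNG stream, so sub-components are independently
reproducible and identical seeds give byte-identical output files.

What the generator does *not* emulate: text-mining noise and confidence
scores, correlated annotation structure (GO term nesting), linkage
disequilibrium between SNPs, or gene-name ambiguity in abstracts.
Passing recovery tests therefore demonstrate that the pipeline's
plumbing, statistics and aggregation faithfully propagate a planted
multi-modal signal at realistic scale — not that the criteria would
identify true comorbidity genes from noisy real-world knowledgebases.

The `"tiny"` profile (20 shared genes, 4 planted, 10/60 processes,
stronger per-term signal so that enrichment remains detectable at small
N) is the unit-test default; the test suite exercises the full profile
in the planted-recovery acceptance check (20 replicate seeds) and the
acceptance script uses the same conditions. Property-based graph checks
run on random graphs of up to 30 vertices, with exhaustive shortest-path
oracles on up to 8 vertices — sizes at which brute-force enumeration is
itself trustworthy.

## Known limitations

* Criteria 1–2 depend on external prioritizer outputs; the package
  ingests but cannot regenerate them.
* Enrichment is a desk-scale hypergeometric/EASE stand-in, not a
  re-implementation of any specific web service.
* Fundamental-cycle subset counts are basis-dependent (see above);
  comparisons across implementations should compare basis sizes, not
  per-subset counts.
* The pipeline recomputes every stage on each run; the manifest records
  input and output digests for audit, but no stage caching is attempted.
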