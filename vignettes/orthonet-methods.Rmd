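---
title: "orthonet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthonet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthonet)
```

# The multilevel model

`orthonet` infers homology between two species from three independent
reciprocal comparisons of every gene locus: the genomic sequence (exons
plus introns), the spliced transcript, and the protein. The working
assumptions are:

* a bit-score-maximal reciprocal hit (Bidirectional Best Hit, BBH) is a
  reasonable one-to-one ortholog call when genomes have not undergone
  recent lineage-specific whole-genome duplication on both sides;
* the three levels fail independently — intron turnover degrades
  gene-level alignments, mis-annotated coding regions degrade protein
  alignments — so agreement across levels is evidence of a real
  relationship, and the three-level consensus is the high-confidence
  core;
* within a species, a sufficiently extreme alignment e-value is an
  acceptable proxy for common descent by duplication, with the caveat
  that no single cutoff separates gene families cleanly.

The pipeline is deliberately not tree-based: no gene trees, no
duplication/speciation reconciliation, no inparalog/outparalog
distinction. Those methods resolve more relationship structure but do
not scale to routine whole-annotation comparisons, which is the use case
here.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| ortholog e-value cutoff | 1e-3 | e-value | inclusive pre-filter so best-hit selection, not the filter, decides orthology |
| stringent paralog cutoff | 1e-50 | e-value | maximises the number of distinct paralog networks; higher cutoffs collapse families into few giant components, lower ones fragment them |
| loose paralog cutoff | 1e-3 | e-value | vetoes species specificity: a gene with even weak similarity to an ortholog is not species-specific |
| annotation transfer gate | 90 / 90 | % identity / % query coverage | description and EC transfer only from near-complete, near-identical matches |
| not-expressed threshold | 1 | RPKM | below this a gene is treated as silent in that stage |
| K-means restarts | 10 | — | correlation-distance K-means has many local optima at these sizes |
| FOM elbow tolerance | 0.05 | relative decrease | smallest k after which one more cluster improves the FOM by <5% |

Best-hit ranking uses the **bit score of the best single HSP** per gene
pair, not the e-value: scores are comparable across queries while
e-values saturate at zero for strong alignments (double-precision
underflow), which would make ties meaningless. Score ties are never
broken: all tied subjects are retained as multiple relationships, so the
output is deterministic without an arbitrary secondary criterion.

# Interval and isoform conventions

Coverage of a (query, subject) pair is computed on the union of its HSP
intervals (1-based, closed, minus-strand subject coordinates normalised
by swapping), so split alignments are counted once. Multi-isoform loci
are handled by mapping *all* isoforms through the locus map and taking
the per-gene-pair maximum score; selecting one representative isoform
(e.g. the longest) would silently discard the best-aligning one. The
90/90 annotation gate applies identity and *query* (transcript)
coverage, because the transfer search runs transcripts against reference
proteins and the transcript is the annotated object.

# Description similarity

Functional descriptions are compared character-wise: after case folding
and whitespace normalisation, the score is
`100 · LCS(a, b) / mean(|a|, |b|)` with a character-level longest common
subsequence. Character (not token) matching is used because curated
description pairs differing by qualifiers — `"...RING1"` vs
`"...RING1-like"`, `"Probable pectate lyase P59"` vs `"Pectate lyase"` —
land in the intuitive 80–99 and 60–79 bands, whereas token matching
scores them erratically. Qualifier words (`putative`, `-like`) are *not*
stripped; the metric is pluggable if a consumer wants that. 100 is
attained exactly when the folded strings are equal. Pairs with a missing
description on either side are counted separately as skipped, never
binned.

# Clustering

Ortholog-pair profiles are the concatenated log₂(RPKM+1) values of the
two genes across their species' three stages (six values, fixed order,
no per-species rescaling — cross-species level differences are part of
the signal). The +1 pseudocount anchors silent genes at exactly 0.

K-means uses the Pearson correlation distance `1 − r` (range [0, 2]),
arithmetic-mean centroids, and assignment ties resolved to the lowest
cluster id. Initial centroids are k profiles sampled without
replacement under the given seed; the best of `nstart` restarts wins.
The reported objective is the partition cost (sum of member-to-own-mean
correlation distances). Because the arithmetic mean is not the exact
minimiser of summed correlation distances, a Lloyd step is not
guaranteed to lower this cost; an iteration that fails to improve it
stops the run at the previous state, so the objective trace is
non-increasing by construction and termination is guaranteed. Constant
(zero-variance) profiles have no defined correlation and are excluded
with a warning (`dropConstant = TRUE`) or rejected. A centroid that
degenerates to a constant vector is handled by defining its correlation
to any profile as 0, i.e. distance 1.

The Figure of Merit leaves out one stage at a time, clusters on the
remaining stages, and scores the root-mean-square deviation of the
held-out stage around its cluster means, summed over stages. Profiles
that become constant after removing a stage are excluded from that
stage's term. The elbow is the smallest k after which the relative FOM
decrease falls below 5% — an explicit rule in place of the visual
inspection such curves are usually read by; both the curve and the rule's
tolerance are exposed so a user can override the choice.

Hierarchical sub-clustering within a cluster is UPGMA on Euclidean
distances (`stats::hclust`); enrichment uses the hypergeometric upper
tail (`stats::phyper`) with Hochberg adjustment (`stats::p.adjust`),
with unannotated genes kept in the universe.

# What the fixture generator emulates — and what it does not

`generateFixture()` plants, per species: consensus ortholog pairs whose
cross-species scores dominate low-score decoy alignments;
ortholog-anchored paralog families whose internal hits pass the
stringent threshold (more families in species A, mirroring the
asymmetric duplication history of a tomato-vs-grapevine comparison);
genes tied to an ortholog only between the loose and stringent
thresholds; species-specific families and singletons with no
cross-species hits at all; multi-isoform loci; reference annotations
with identical/variant/divergent description pairs and partial EC
coverage; domain profiles in roughly 82/15/3 all/some/none-shared
proportions; three fruit stages per species with planted co-expression
templates, a planted silent pair set, and one GO term attached exactly
to one cluster's genes. Defaults are desk-scale (40 ortholog pairs,
~140 genes in total, noise SD 0.15 log₂ units); emission is sorted and
byte-deterministic for a fixed seed. `corruptLevel()` strips one
sequence level from a chosen fraction of pairs to create partially
confirmed relationships with bookkept truth.

What it does **not** emulate: realistic sequence evolution (scores are
drawn, not aligned), inclusive e-value gradients inside families,
overlapping paralog families, one-to-many orthology beyond score ties,
annotation noise (wrong descriptions on true orthologs), or library-size
imbalance across stages. Passing the fixture suite therefore shows the
*inference logic* is correct under its stated assumptions, not that the
thresholds are optimal for any particular genome pair.

# Degenerate inputs and numerical notes

* Empty similarity files parse to empty hit sets; an empty orthology set
  propagates to all-zero reports without error.
* A missing level runs in degraded mode with a warning; consensus is
  then unreachable by construction.
* Duplicate rows for a gene pair are collapsed by maximum score;
  self-pairs are dropped after locus collapsing.
* Comparisons in tests use absolute tolerances of 1e-8–1e-12; the
  objective-improvement guard uses 1e-12.
* All output tables are sorted on stable keys, so identical inputs give
  byte-identical outputs.

# Known limitations

* BBH cannot represent many-to-many orthology except through exact score
  ties; recent polyploids will be under-connected.
* The specificity classes depend on the loose threshold transitively: a
  single spurious 1e-3 hit chains a gene out of the species-specific
  set. This matches the network-complement definition of specificity but
  makes the class sensitive to low-complexity alignments, which real
  pipelines mask upstream.
* The FOM scan re-clusters per held-out stage, so its cost grows
  linearly in stages × k values; with six stages this is negligible, but
  for dense stage series a sampled scan would be needed.
* Domain comparison is set-based; copy-number changes of a shared domain
  are invisible.
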