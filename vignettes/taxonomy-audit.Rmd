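---
title: "Auditing prokaryotic taxonomy with genome-scale distances and G+C content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing prokaryotic taxonomy with genome-scale distances and G+C content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxaudit)
```

## The problem

Prokaryotic classification predates genome sequencing: genera and
families were circumscribed from morphology, chemotaxonomy, 16S rRNA
genes, and G+C content measured by melting-point or chromatographic
methods. Type-strain genome sequences make two kinds of audit possible.
First, a genome-scale phylogeny can be confronted with the existing
classification taxon by taxon: is each genus or family a clade, and if
not, how strongly does the data contradict it? Second, the genomic G+C
content — a trivial computation on the assembly — can be compared with
the value printed in each species description; conventionally determined
values are often off by several mol%, while true within-species variation
is at most about one percentage point when measured from genomes. This
package implements both audits plus the supporting machinery, and a
synthetic-data generator rich enough to validate every stage without
external data.

## Intergenomic distances

Distances are computed from tabular local-alignment hits (BLAST
outfmt 6) between genome pairs; the package does not run the search
itself.

**Greedy-with-trimming.** Paralogous and repeated matches inflate
identity sums. HSPs of one ordered pair are therefore accepted greedily
in decreasing bit score (ties: decreasing identities, then input order);
an accepted HSP reserves its query and subject intervals, and later HSPs
lose the alignment columns that fall into reserved regions on either
genome. Tabular output has no per-column coordinates, so columns are
mapped linearly between the query and subject spans, and identities are
reduced proportionally to the retained columns (rounded half-up);
fragments retaining less than one column are dropped, all others kept —
no minimum-length cutoff is applied. Reservation uses the retained
(post-trim) intervals, so the output's reserved regions are pairwise
disjoint on both genomes and the summed alignment length can only
shrink.

**Formula d5.** Per direction, \(r = \sum \mathrm{identities} / \sum
\mathrm{length}\) over the trimmed HSPs, and \(d = 1 - r\); the two
directions are averaged. The verbal definition of this distance family
fixes the ratio but not the transform; we take the bounded \(1-r\) form
as the default and provide \(-\log r\) behind a `formula = "logd5"` flag
(the log form is exactly additive when identity ratios decay
exponentially with evolutionary distance). If one direction has no HSPs
the other is used alone; if neither has any, the maximal distance 1 is
returned with a warning — never a silent `NA`. Directions are trimmed
separately, not pooled.

**Pseudo-bootstrap.** The resampling unit is the trimmed HSP, not the
alignment column: per replicate, every ordered pair's trimmed HSP list
is independently resampled with replacement at its original cardinality
and d5 recomputed. This is closer to a partition (gene-level) bootstrap
than to a site bootstrap, and is deterministic given the seed. The
default of 100 replicates matches standard practice for this distance
family.

**Trees.** Main and replicate matrices are turned into unrooted binary
trees by neighbour joining (`ape::nj`) or BIONJ; negative estimated
branch lengths are clamped to zero with a warning. A PHYLIP matrix
writer is provided for users who prefer an external
(balanced-minimum-evolution) tree program; any externally produced
Newick tree can be fed back into the later stages. Support values are
mapped by counting, for each internal edge of the main tree, the
fraction of replicates containing the same unrooted bipartition; trivial
splits count as present in every tree, which makes the mapping invariant
to the rooting of the replicates.

## Monophyly and signed support

Given a rooted tree (root with an outgroup first;
`root_with_outgroup()` treats support labels as edge annotations so they
follow their bipartition through rerooting) and a taxonomy table, each
taxon is classified:

- **monophyletic** if some edge's subtree contains exactly its members;
  the support of that edge is the *support for* the taxon (reported as
  unknown when the edge has none);
- otherwise the **conflicting edges** are those whose subtree contains
  at least one member, misses at least one member, and contains at least
  one non-member; the maximum support among them is the *support
  against* (displayable as negative support). Edges without a support
  value contribute nothing to the maximum — absence of evidence is not
  treated as 0 or as 100. Pendant edges never qualify (a single tip
  cannot mix members and non-members), matching trees whose pendant
  edges carry no support anyway.

**Paraphyly vs polyphyly.** The classical distinction is the number of
independent origins of membership. We operationalize it as: fix the root
state to non-member (trees here are outgroup-rooted, and no ingroup
taxon contains the universal ancestor), take all minimum-change
reconstructions of the binary membership character, and among them the
minimum number of non-member-to-member transitions; one origin is
paraphyly, two or more polyphyly. The dynamic program minimizes
(changes, origins) lexicographically, which is exact, and is verified in
the test suite against exhaustive enumeration over all internal-node
state assignments on trees of up to 10 tips — every one of the
\(2^n-2\) candidate member sets per tree. Ties between reconstructions
are thus always broken toward fewer origins; other conventions exist,
and this one is documented rather than asserted to be universal.

Taxa with one member, or containing every tip, are *trivial*. Tips
lacking an assignment at a rank are non-members of every taxon at that
rank.

## The G+C audit

`gc_content()` computes \(100\,(G+C+S)/(A+C+G+T+S+W)\) pooled over all
records. The two-fold ambiguity codes are kept on their unambiguous
side (S is G-or-C, W is A-or-T); every other IUPAC code, N and gaps are
excluded from numerator and denominator alike, which is unbiased under
symmetric ambiguity. Reported and compared values are rounded to one
decimal place, half away from zero; the incomplete-sequencing simulation
below justifies that precision.

Classification is by precedence: **missing** (no published value), then
**deviating** (published point more than `tolerance` from the rounded
genomic value, or genomic value more than `tolerance` outside the
published range), then **restricted** (range wider than `max_range`),
else **confirmed**. Both thresholds default to 1 percentage point — the
1% rule. The precedence means a range that is both too broad and
inaccurate counts as deviating; the four categories are disjoint and
exhaustive by construction. Published values are parsed from a small
grammar (`"41"`, `"41.2"`, `"40-42"`, `"40–42"`). Non-confirmed species
receive a machine-readable emendation stub of the form "The genomic G+C
content of the type strain is 45.3%." — input curation (choosing the
most recent emendation per species) remains the caller's responsibility.

## Continuous-character parsimony fit

Whether genome-derived G+C values fit the phylogeny better than
published ones is tested by scoring both as a single continuous
character under Farris-interval (linear) parsimony: the down-pass
assigns each internal node the intersection of its children's intervals
when nonempty, else the gap interval between them, adding the gap width
to the score. This equals the minimum of \(\sum |x_{parent} -
x_{child}|\) over internal assignments (verified in the tests against a
grid dynamic program and full enumeration) and does not depend on the
rooting.

Conventions, each of which matters for comparability:

- **Joint rescaling.** Scores are compared only after both value sets
  are mapped by one shared affine transform onto [0, 65] (the range
  conventionally required when exporting continuous characters to
  parsimony software); independent rescaling would distort the
  difference. The target range is configurable; the scale factor only
  multiplies scores, so test conclusions do not depend on it.
- **Deactivation.** Species without a published value are deactivated —
  pruned from the tree before scoring — in both value sets, so both
  scores refer to the same tip set.
- **Range variants.** Published ranges enter as minima, averages or
  maxima (all three reported, as no single choice is canonical), or as
  genuine intervals (`pub-as-range`); interval leaves can only lower a
  score relative to any point selection.
- **Full precision.** No discretization is applied; integer precision in
  parsimony programs is an artifact of those programs, not of the
  method.

The per-replicate-tree differences (published − genomic) are tested
against zero with a two-sided one-sample t-test and a Wilcoxon
signed-rank test. Replicate trees are pseudo-bootstrap trees, so the
test addresses phylogenetic uncertainty; a degenerate difference vector
(identical across replicates) admits no distributional test and is
reported as `NA`.

## The synthetic-data generator

Every input has a seeded generator, so the pipeline's claims are
testable end-to-end:

- `sim_tree()` — Yule trees, rescaled to unit height so rates and
  distance transforms mean the same thing at any tip count.
- `sim_taxonomy()` — family and genus labels cut from nested clades, so
  all taxa are monophyletic unless a violation is planted. Paraphyly is
  planted by relabelling a subclade nested strictly inside a genus (not
  a direct child of the genus root, so the remainder is not a clade) to
  a new genus name. Polyphyly is planted by relabelling one whole genus
  clade to the name of a genus on the other side of the root: with the
  root fixed to non-member a single origin is then impossible, so
  exactly the target genus becomes polyphyletic. (A literal swap of two
  nested subclades would make two taxa non-monophyletic at once.)
- `sim_gc()` — Brownian motion along branches from a root value
  (default 50 mol%, rate 25 mol%² per unit height, clamped to
  [20, 80] — giving tip spreads comparable to the 27–66 mol% range seen
  across a bacterial phylum); `sim_published_gc()` adds observation
  noise (default sd 2 points), converts some values to ranges and drops
  some, mimicking literature heterogeneity.
- `sim_genome()` / `sim_draft()` — i.i.d. bases at a target G+C;
  drafts retain a completeness fraction as n random non-overlapping
  contigs (uniform placement via random compositions of retained and
  gap lengths).
- `sim_hsp_table()` — per pair, target ratio \(r = e^{-d}\) of the
  patristic distance (any monotone map suffices for topology-recovery
  testing; this one keeps \(r \in (0,1]\)), optionally perturbed by
  truncated Gaussian noise; k HSPs per direction realize the ratio up to
  rounding, with mean-centred per-HSP jitter so bootstrap resampling has
  variance. Coordinates are non-overlapping unless overlap injection is
  switched on to exercise the trimmer.

What the generator does *not* emulate: gene content and synteny, codon
structure, rearrangements, alignment-tool idiosyncrasies, and
read-level sequencing error. Passing recovery tests therefore shows the
distance/tree/support machinery is internally correct, not that real
proteome BLAST data meet the generator's assumptions.

## Validation and problem sizes

The test suite validates, among others (sizes chosen to keep the whole
suite in a few minutes on one core):

- monophyly classification against exhaustive enumeration — 200 random
  rooted trees of 4–10 tips, every candidate member set (about 57,000
  taxa);
- Farris scores against grid dynamic programming (200 random trees of
  up to 8 tips, integer leaf values in [0, 20]) with rerooting
  invariance, the grid DP itself against full enumeration on 4-tip
  trees;
- neighbour joining on 100 random additive matrices (up to 12 taxa):
  exact topology and branch-length recovery;
- end-to-end recovery: noise-free synthetic HSP tables reproduce the
  generating topology at 20 tips with 100% support on every edge;
- fit-test power: with 40 tips, published = truth + noise (sd 2) and 50
  pseudo-bootstrap replicate trees, the mean difference is positive with
  both tests significant in at least 18 of 20 seeded repetitions;
- incomplete-sequencing bound: drafts of 5 Mb genomes at 90%
  completeness in 200 contigs deviate from the true G+C by less than
  0.1 percentage points on average — the basis for reporting G+C to one
  decimal. `scripts/acceptance.R` recomputes this bound at 50 genomes.

## Numerical conventions and degenerate inputs

- Rounding of G+C values and trimmed identities is half away from zero
  (R's own `round()` rounds half to even).
- Missing genome pairs get distance 1 with a warning; empty HSP lists in
  one direction fall back to the other direction.
- Support values must lie in [0, 100]; non-numeric internal node labels
  are names, not supports; supports live on bipartitions and survive
  rerooting.
- Polytomies are accepted everywhere except Farris scoring, which
  requires binary trees after pruning and says so rather than resolving
  arbitrarily.
- Zero-range value sets cannot be rescaled (error); constant-difference
  vectors yield `NA` tests; bootstrap with a single HSP per pair
  degenerates to the original matrix, by design.

## Limitations

- NJ/BIONJ stands in for balanced-minimum-evolution tree search; for
  publication-grade trees, export the PHYLIP matrices and use a
  dedicated program, then feed the tree back in.
- The paraphyly/polyphyly tie-break (minimum origins among
  minimum-change reconstructions) is one defensible convention; borderline
  taxa near reconstruction ties can be labelled differently under other
  conventions.
- The audit trusts its input table: deciding which literature emendation
  is current, and matching strain identities, are curation tasks outside
  the package.
- d5 here is one member of a larger distance family; only d5 and its log
  variant are implemented.
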