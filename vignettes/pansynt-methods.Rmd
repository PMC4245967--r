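---
title: "Methods: pairwise synteny detection, pangenome profiles and annotation comparison"
author: "pansynt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise synteny detection, pangenome profiles and annotation comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pansynt is the computational back end for pairwise comparative genomics of
bacteria and archaea: it infers orthologs from all-vs-all protein hit
tables, detects collinear and inverted synteny blocks over gene orders,
segments each comparison into an alternating chain of conserved and
genome-specific regions, and supports pangenome profiling, functional
annotation comparison and binomial enrichment statistics on top of those
primitives. This vignette describes the models and the numerical choices;
the README shows the surface-level workflow.

```{r setup}
library(pansynt)
```

## Data model

A genome is a **catalog**: one record per protein-coding gene (CDS), with
1-based inclusive coordinates taken directly from the annotation source
(GenBank native convention — no half-open conversion anywhere in the
package), a strand, per-namespace GO terms, EC numbers and databank
cross-references. Replicons (chromosome, then plasmids) are kept in file
order and concatenated, so every gene carries a genome-wide *rank* in
0..N−1; all order-based computation works on ranks, all display-oriented
spans on base pairs. One protein product per gene is assumed, which is why
the package targets prokaryotes only. Pseudogenes and partial CDS are
skipped with a logged warning; a gene annotated across the origin of a
circular replicon keeps its annotated start, is extended to the replicon
end, and therefore ranks last — an explicitly arbitrary but deterministic
placement.

## Homology and orthology

Hit tables are the standard 12-column tabular protein-comparison format.
Two filters are applied at parse time: hits with e-value ≥ 0.01 are never
stored (the threshold is strict and configurable), and same-genome hits
are dropped. Multiple HSPs for one gene pair collapse to the best HSP
(lowest e-value, then highest bit score). Query coverage is derived as
100·(qend − qstart + 1)/protein length, since the tabular format does not
carry it directly.

Two genes are **orthologs** iff they form a bidirectional best hit (BDBH):
each is the other's best subject, with best defined by lowest e-value,
ties broken by highest bit score and then by lexicographically smallest
subject id. The last tie-break has no biological content; it exists solely
to make the call deterministic. E-value is the primary criterion (bit
score primary would be an equally defensible convention; the choice is
isolated in one comparator function). Every stored cross-genome pair that
is not a BDBH is a plain **homolog** relation. Within-genome paralogy is
never computed: paralogy manifests as one reference gene having several
cross-genome homologs.

## Synteny blocks

### Scoring model

A synteny chain is a sequence of *anchors* — homologous gene pairs whose
ranks strictly increase on the reference and strictly increase (forward)
or strictly decrease (reversed) on the compared genome. Default scores:

| parameter         | value | meaning                                    |
|-------------------|------:|--------------------------------------------|
| ortholog          |    +4 | aligning a BDBH pair                        |
| homolog           |    +2 | aligning a non-BDBH pair                    |
| mismatch          |    −4 | aligning two unrelated genes                |
| gap creation      |    −8 | first skipped gene of a run                 |
| gap extension     |    −2 | each further skipped gene                   |
| minimum size      |     1 | anchors per reported chain                  |
| minimum score     |     2 | so a single homolog anchor is reportable    |
| maximum gap       |     2 | skipped genes per genome between anchors    |

A maximal run of k skipped genes on one genome costs gap_open +
(k−1)·gap_extend, i.e. creation covers the first skipped gene. This
composition keeps single-gene gaps cheapest; the alternative
gap_open + k·gap_extend is available as `gap_model =
"open_plus_per_gene"`. "Minimum size" is read as anchor count (not bp):
size 1 must admit a single homologous pair, and only that reading does.
Between two consecutive anchors, facing skipped genes may be paired up as
mismatch columns when that is cheaper than two gaps (one mismatch, −4,
beats −8 −8); the inter-anchor cost used by the chain scorer and the DP is
the maximum over all such pairings. Gene strand is ignored: collinearity
is about locus order, the orientation label belongs to the whole chain.

The **maximum gap** bounds how many genes may be skipped on either genome
between two consecutive anchors. It implements "small gaps are allowed"
literally: without a bound, a local alignment with affine gaps happily
bridges arbitrarily long idiosyncratic regions whenever both flanks are
strong, so a five-gene island inserted into a long conserved run would be
swallowed into one block instead of splitting it — the opposite of the
segmentation the event chain needs. With the default of 2, gaps of up to
two genes (typical small losses) are bridged and any run of three or more
unrelated genes breaks the chain and becomes a genome-specific region.

### Dynamic programming and extraction

Because chains start and end on anchors, the optimum over column-style
local alignment is attained on the sparse graph of anchors, and the
package computes it by anchor chaining (the approach of the DAGchainer
family): for each anchor, the best chain ending there is its own score
plus the best over predecessors inside the (max_gap+1)² window, or zero
(chain start). Exactness of this reformulation against exhaustive
enumeration of all terminally anchored collinear chains is a standing
property test (200 random instances of ≤ 8 genes per run). Co-optimal
predecessors are resolved toward the nearest one (smallest rank deltas),
and co-optimal chain ends toward the smallest reference rank — again pure
determinism devices.

Suboptimal chains are extracted iteratively in the Waterman–Eggert style:
take the best chain, mask its anchors, recompute, stop when the best
remaining chain falls below the minimum score. This runs per replicon
pair and per orientation (the compared gene order as-is and reversed; a
block never spans a replicon boundary, as replicons are distinct
molecules and their concatenation is display-only).

### Merging orientations and offshoots

Candidates from both orientations are then ranked by score (ties: forward
preferred, then smaller reference start) and resolved greedily:

* a candidate whose reference rank interval is disjoint from all accepted
  primary blocks, and whose compared genes are unclaimed, becomes
  **primary**;
* a candidate overlapping a primary on the reference, or reusing claimed
  compared genes, is demoted to an **offshoot** — the alternative
  homologous copy produced by duplications and paralogy;
* a candidate lying entirely inside already-covered territory on *both*
  genomes is a fragment of accepted blocks (typically the anti-diagonal
  shadow of a conserved run seen by the opposite orientation) and is
  dropped.

Overlap is judged on reference rank intervals, not anchor sets, which
makes primary blocks interval-disjoint and the event partition below
total by construction. One known consequence of the scoring model is that
inversions short enough to be stepped across within the gap window
(roughly ≤ 2·(max_gap+1) genes when both flanks are long) can be absorbed
as mismatch/gap columns of a flanking forward chain; strand-agnostic
chaining tools share this behavior, and the simulator's default inversion
size (6) sits just beyond it.

## Annotation events

Primary blocks sorted by reference start alternate with **reference-
specific** regions: each maximal inter-block interval on a replicon
becomes one event carrying the genes it contains (possibly none — a bare
intergenic region between two adjacent blocks is a gene-less event, drawn
as a line). Leading/trailing gene-less termini are not emitted. Every
reference gene thus belongs to exactly one non-offshoot event — genes
inside a block's span that are not anchors (gap and mismatch genes)
belong to that block's event. Compared-genome regions covered by no block
at all become **compared-specific** events, attached to the nearest
flanking block to their left in the compared genome's concatenated gene
order (the right flank, or nothing, when no left flank exists); they are
spliced into the chain right after the event they attach to and are
rendered at half scale.

## Profiles, filters, core/dispensable

The presence profile labels each (reference gene, compared genome) cell
`ortholog` (a BDBH exists), `homolog_only` (≥ 1 relation, none BDBH) or
`absent`; all supporting relations are kept per cell so stacked homologies
(duplications, paralogs) can be browsed. Filters form an algebra: leaf
predicates (location, id, annotation text, GO term, EC number,
cross-reference, motif-in-text, presence, absence) combined by AND
(intersection) and OR (union) nodes, with the empty AND defined as the
whole gene set (identity of intersection) and the empty OR as the empty
set. A presence leaf requires its predicate in *every* listed genome and
an absence leaf in none; "B and/or C" questions are therefore spelled as
OR over single-genome leaves, which also sidesteps any precedence
question — the tree is explicit. `domain_motif` matches annotation text
only: the pipeline stores annotations, not sequence scans. The core set
under a predicate contains the genes satisfying it in every genome of the
chosen subset; the dispensable set is the complement, so the two always
partition the reference gene set. The default predicate is BDBH
orthology, with `any_homolog` exposed alongside.

## Annotations comparator

For one reference gene and the homologs admitted by the active filter
(maximum e-value, minimum % identity, minimum % query alignment length,
optionally BDBH only), annotations in each class (GO molecular function /
biological process / cellular component, EC number) are classified as
**shared** (on the gene and ≥ 1 admitted homolog), **unique** (on the
gene only) and **missing** (on ≥ 1 admitted homolog only). Counting is
per organism — any admitted homolog in an organism suffices — and the
reported ratio divides by the number of organisms compared. Annotation
identity is exact identifier equality; no ontology-graph expansion is
attempted (a possible extension, but one that would make the three-way
partition depend on a GO release). Free-text product fields are excluded
by default as too heterogeneous; GO terms whose namespace is unknown go
to an `unspecified` bucket that the comparator ignores.

## Binomial statistics

`binomial_pvalue()` computes the point probability P(X = k) and upper
tail P(X ≥ k) of a Binomial(n, p) count in log space (`dbinom`/`pbinom`
with `log = TRUE`), and `locus_overlap_test()` applies it to gene-set/
locus enrichment with n = |gene set|, k = members inside the loci union
and p = the loci's share of the genome's genes. The reported default is
the **point** probability: for the two pathogen-enrichment worked
examples shipped in the tests (k = 24, n = 24 and k = 35, n = 40 at
p = 0.54), the point probabilities reproduce the published two-significant-
figure values (3.8·10⁻⁷ and 5.8·10⁻⁶) while the tail of the second case
is 6.9·10⁻⁶ — direct summation in the test suite confirms the convention.
Both quantities are always returned and printed.

## The simulator

`simulate_genomes()` generates the study conditions for every other
module: an ancestor gene order, descendant genomes derived by planted
inversions, translocations, segmental duplications, gene gains (islands),
and losses, emitted as GenBank-dialect flat files with matching two-way
hit tables and a truth JSON (planted ortholog pairs, expected blocks with
orientation and offshoot status, genome-specific gene sets). Every draw
flows from one seed through an isolated RNG, so identical seeds give
byte-identical files.

The generator enforces its own detectability regime, chosen to match the
chaining defaults: event segments are separated by at least 3 conserved
genes (and kept 3 genes from replicon ends), losses are single genes so
planted gaps are ≤ 2, insertions (islands, gains, duplication copies) are
at least 3 genes so they always split their host run, and inversions
default to 6 genes so they cannot be stepped across. Duplication copies
hit the same reference genes with e-values from a strictly weaker range
than planted orthologs, so BDBH calls stay unambiguous; decoy hits
(spurious weak similarities) are only planted outside the chaining window
of every true anchor, so they can never reroute or extend a chain.
Within that regime, recovery is exact and asserted as identity, not
similarity. Features of real data deliberately *not* emulated: sequence
evolution (e-values, identities and bit scores are synthesized, protein
sequences are arbitrary residue strings), overlapping or nested
rearrangements, gene fusion/fission (unrepresentable under one protein
per gene), mobile elements with internal structure, and biased gene
order. Passing the recovery tests therefore demonstrates correctness of
the chaining and bookkeeping under clean planted signal, not performance
on the tangled event histories of real genomes.

Default problem sizes — 30–80 ancestor genes, 2–3 genomes — keep each
simulated comparison in the sub-second range; the full suite runs a few
hundred such fixtures. These sizes are the package's chosen test scale:
the algorithms themselves are quadratic in genes per replicon pair at
worst and handle complete bacterial genomes.

## Known limitations

* BDBH is a per-pair orthology call; no clustering across > 2 genomes, so
  profile rows are independent pairwise comparisons.
* Short inversions inside long conserved runs can be absorbed into a
  forward block (see above); lowering `max_gap` trades this against
  robustness to small losses.
* The comparator treats annotations as opaque identifiers; incomplete
  annotation in one genome shows up as "missing"/"unique" signal.
* The SVG view is a static rendering of one comparison with fixed glyph
  geometry; zooming is the `window` argument, and interactivity is out of
  scope.
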