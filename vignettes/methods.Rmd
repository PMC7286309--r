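---
title: "Genomic-block painting and rearrangement phylogenetics: methods"
author: "ackpaint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic-block painting and rearrangement phylogenetics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ackpaint)
```

## The problem

Comparative genomics in the Brassicaceae is organised around the ancestral
crucifer karyotype (ACK): a hypothetical eight-chromosome genome (AK1–AK8)
carrying 22 conserved genomic blocks (GBs, letters A–X with K-L and M-N
merged) in a fixed order. A new crucifer genome is interpreted by
*painting* it with these blocks: find the regions syntenic to the
reference genome that defines the block borders, decide which of those
regions are true orthologous counterparts and which are leftovers of the
At-α whole-genome duplication (WGD) shared by the whole family, and then
describe the genome as an arrangement of lettered sub-blocks, numbered
along the ACK and flagged when inverted. Non-ancestral block adjacencies
that recur across genomes are then usable as rare genomic characters for
the parts of the backbone phylogeny that sequence data have not resolved.

`ackpaint` implements that whole chain as testable code — synteny
chaining, Ks-based block classification, karyotype painting, adjacency
characters and Fitch parsimony scoring — together with a genome-evolution
simulator that generates data with the same statistical structure plus
complete ground truth, so every stage can be benchmarked.

All genomic distances in the pipeline are measured in **gene-rank units**:
within each chromosome genes are numbered 0..n−1 in start order, and every
"distance" parameter below counts genes, not base pairs. This matches the
relative-gene-order mode of the SynMap/DAGchainer tool family; the
original analyses do not state the unit explicitly for every run, and
gene ranks are the interpretation adopted here (bp-based gaps would make
the thresholds depend on gene density). Coordinates are stored 0-based
half-open; GFF3 input is converted on read, BED is native.

## Synteny chaining

Anchor pairs (homologous gene pairs, optionally with a Ks value) are
chained into collinear blocks by dynamic programming over the DAG of
anchors in rank space, separately per chromosome pair and orientation:

* an anchor can follow another when both rank coordinates advance by at
  least 1 and at most `max_gap` (default **25** genes, the maximum match
  distance of the original DAGchainer runs);
* chain score is `sum(anchor weights) − gap_penalty · sum(gap lengths)`
  with per-step gap length `max(Δrank_a, Δrank_b) − 1`, anchor weight 1
  unless a score column is supplied, and `gap_penalty = 0.2`. The original
  pipeline does not publish its gap penalties; 0.2 is declared, not
  inferred, and was chosen so that the largest permitted jump (25 ranks)
  costs 4.8 — less than the 20-pair block floor, so a long chain is never
  broken up merely to avoid one wide gap. The brute-force oracle used in
  the tests applies the same scoring function, so the exactness check does
  not depend on this convention;
* the best chain is extracted, its anchors removed, and the search
  repeated (DAGchainer's behaviour); ties are broken toward the smaller
  start rank for determinism. Each anchor therefore belongs to at most one
  block, which is also how one-to-many homologies are resolved;
* blocks with fewer than `min_pairs` anchors (default **20**) are
  discarded at the end, so the stopping rule cannot change which large
  blocks exist.

Blocks are then merged, quota-align style: same chromosome pair, same
orientation, rank separation at most `merge_dist` (default **50** genes)
on both genomes, and the pooled anchors must remain strictly collinear.
Merging repeats to fixpoint from a canonical ordering, so the result is
independent of input order. `manual_merge()` reproduces the hand-curation
step for same-block fragments further apart than the automatic limit: no
distance check, but collinearity is still enforced.

## Ks classification

Synteny alone cannot tell an orthologous region from an At-α-derived
paralogous one; their median Ks can. Ks values of 2 and above are excluded
everywhere (Ks is only approximately linear with time below 2). Per-block
medians are used rather than means because single stray paralog anchors
inside an ortholog block should not move the statistic; the mean is
reported alongside for diagnostics.

`estimate_ks_modes()` locates the ortholog and WGD modes as the two
highest local maxima of a Gaussian kernel density (Silverman's
rule-of-thumb bandwidth, configurable) on the usable Ks values, and places
the classification cut at the density minimum between them. Local maxima
below 5% of the dominant peak are treated as shoulder ripples, and a
near-constant sample (sd < 10⁻³) is declared unimodal outright; in the
unimodal case the cut is reported as undefined and the caller must supply
one — guessing a boundary silently would be worse. Classification assigns
`median < cut` to orthologs and the boundary itself to the paralog side,
the conservative choice for painting (a block is only painted when the
evidence says ortholog). On 5,000 draws from a log-normal mixture with
modes 0.77/1.37 (log-sd 0.2, the Aethionema–Arabidopsis configuration)
the estimator recovers both modes within ±0.05 under the seeds used in
the test suite; across arbitrary seeds the WGD-mode estimate scatters
somewhat more (±0.1) because the upper component's peak is flat. Block
classification is far more stable than the mode locations: with ≥ 20
anchors per block, misclassification stays below 1%.

Redundant coverage — several ortholog-classified blocks claiming the same
ancestral region — is resolved by keeping the lowest-median-Ks block.
"Same region" is measured as the fraction of the smaller block's
**reference genes** shared with the other block (threshold 0.5; the
original description gives no number). Shared genes rather than span
overlap is deliberate: the chain of a within-block inversion lies entirely
inside its flanking chain's reference span while covering disjoint genes,
and a span criterion would discard it as a duplicate. Genuine duplicates
reuse the same reference genes and are caught either way. The survivor
set equals the closure of the pairwise lower-Ks rule and does not depend
on input order.

## Painting the karyotype

Each retained ortholog block is cut at every GB interval boundary its
reference span crosses; each piece takes its interval's label. Pieces
with fewer than `min_subblock` anchors (default 20, reusing the chaining
floor) are dropped unless their label is in `allow_small` (default
`{G}`: block G is a six-gene block detectable only below any reasonable
threshold, and is carried for consistency, exactly as the original
analysis treated it).

A fragment's inversion flag is the sign of the Spearman correlation
between its query and reference ranks — the majority orientation of its
anchors. Fragments with |ρ| < 0.5 are flagged ambiguous and reported
not inverted. Fragment extents are the ranges of their anchors, which is
what an interval-intersection oracle reproduces in the tests.

Assembling fragments into the painted map deals with two kinds of
query-side overlap. *Double painting* — two fragments whose anchors
occupy the same interval (each with > 25% of its anchors inside the
shared region) — keeps the larger fragment and logs the conflict.
*Bracketing* — one fragment's span enclosing another's without occupying
it — is the signature of a within-block inversion, whose antisense chain
sits inside a gap of the flanking chain (the flanking chain may even
tunnel a stray anchor or two through the inverted region); here the outer
fragment is split around the inner one, so the painted chromosome is a
tiling. Finally the fragments of each GB are numbered 1..k by their
reference start positions, which reproduces ACK-relative labels such as
F4; merged labels (K-L) are single intervals, and a separated small piece
of one simply becomes an extra indexed fragment.

## Adjacency characters and parsimony

Consecutive sub-blocks on a chromosome separated by at most
`max_gap_genes` unassigned genes (default 50, reusing the merge distance)
contribute one adjacency joining the facing block extremities: a
non-inverted fragment exposes its ancestral *tail* rightward, an inverted
one its *head*, and tokens are normalised so each adjacency has a unique
key. The default (*lenient*) mode compares adjacencies at GB-extremity
resolution, ignoring fragment indices; *strict* mode keeps the indices,
so associations built from different pieces of the same blocks — which
can have independent origins — are distinguished. Both modes are provided
because the verbal argument being formalised does not pin down one
character definition.

Shared derived associations are those present in at least two painted
genomes but absent from the identity painting of the GB table itself
(`gb_reference_map()` — its adjacency set is exactly the
within-chromosome consecutive GB pairs). They become binary presence
characters; a cell can be down-coded to `NA` when a fragmentary assembly
makes the adjacency unobservable, and the Fitch scorer treats `NA` as
free. `fitch_score()` is an own implementation of the set-intersection
algorithm (binary trees; unrooted inputs are rooted at a leaf first, and
the score is re-rooting invariant); the test suite checks it against both
exhaustive enumeration of internal states and an independent library
implementation. `rank_topologies()` orders candidate topologies by score,
reporting ties in input order.

## The simulator

`sim_config()` encodes the study conditions; its defaults are the
conditions under which the package's claims are tested, chosen once:

* **Karyotype**: the 22 ACK blocks on AK1–AK8 in ancestral order, 100
  genes per block (2,200 genes — about a fifth of a real crucifer genome,
  enough for every structural property at a fraction of the runtime).
  One gene per 30 kb, so even a two-block chromosome (6 Mb) passes the
  5 Mb chromosome filter at full gene complement.
* **WGD and Ks**: one WGD shared by all taxa (nested mesopolyploidy is out
  of scope), duplicating every chromosome into a second subgenome. Ks for
  a gene pair is log-normal (log-sd 0.2) around a mode that grows with
  divergence: `ks_rate` (0.385 per unit path length) times the tree path
  between the genomes for orthologs, plus `wgd_ks_excess` (0.6) for
  paralog pairs. The additive form reproduces the observed pairwise
  ortholog/paralog modes (0.77/1.37 for the more divergent comparison,
  0.41/1.01 for the less divergent one) with a single parameter; a fixed
  paralog mode could not reproduce both.
* **Fractionation**: at each leaf, a duplicated pair loses one copy with
  probability 0.7 (post-α Brassicaceae retain only a minority of
  duplicates; no quantitative family-wide rate is published, so this is a
  free parameter, not an estimate). The lost copy is the lineage's
  non-dominant subgenome copy with probability `copy_bias` = 0.7, and the
  dominant subgenome alternates across leaves. Anti-correlated dominance
  is what makes cross-subgenome (paralog) anchor pairs denser than
  same-subgenome (ortholog) pairs between two lineages — the simulated
  counterpart of paralogous blocks containing more syntenic genes than
  orthologous ones under unequal fractionation.
* **Rearrangements**: inversions, translocations, fissions and fusions,
  with breakpoints uniform in rank space (chromosomes weighted by gene
  count). Counts are configured per branch; explicit events with fixed
  coordinates can also be planted, including on the root stem to shape
  the family-ancestral state. A breakpoint-reuse bias is deliberately
  absent by default — reuse is the rival hypothesis to ancestral
  retention, and the scenario analysis must not bake it in. All
  randomness derives from one master seed through per-branch substreams
  keyed by branch names, so outputs are byte-identical for a fixed seed.
* **Gene loss does not shrink chromosomes**: emitted chromosome lengths
  reflect the pre-fractionation gene complement, as intergenic DNA
  persists in real genomes. Chromosomes can still drop below the 5 Mb
  filter by *donating* a translocated segment — which the filter then
  removes, as it would in the real pipeline.

The reference genome emitted as `REF` is the unevolved ancestor itself
(the GB table is defined by its gene ids), standing in for an ACK-like
reference genome. With the WGD enabled, `REF` plays the role of subgenome
1, so leaf-subgenome-1 genes pair with it as orthologs and subgenome-2
genes as paralogs.

What the simulator does **not** emulate: nucleotide sequences (Ks is
drawn, not computed from codon alignments), gene-family turnover other
than post-WGD loss, tandem duplications, rate heterogeneity across genes
beyond the log-sd, segmental duplications, and assembly artefacts.
Passing the benchmarks therefore shows that the pipeline's logic is
correct under its own model assumptions — not that a real anchor table
from a noisy assembly would behave as cleanly.

## Ground truth and benchmark resolution

`true_gb_map()` reads the true sub-block structure off the simulated gene
order: maximal runs of constant GB label, constant subgenome and
consistent ancestral-rank direction (steps larger than 25 ranks mark true
breakpoints), with a descending run being a true inversion. By default
the truth covers subgenome 1, the copy the Ks filter retains.

Recovery benchmarks compare detection and truth **at the method's own
resolution**, the way structural-variant benchmarks apply size floors:

* truth fragments below 20 genes are dropped, and — because a sub-floor
  fragment can never be chained on its own at a 20-pair floor (the
  original analysis could only find the six-gene block G by lifting the
  threshold) — the G exemption is disabled on *both* sides for the
  recovery runs;
* breaks the detector deliberately bridges are collapsed in the floored
  truth: two same-label, same-direction runs separated only by a dropped
  sub-floor fragment, or by an ancestral-rank jump within the 50-gene
  merge distance, are rejoined, exactly as chaining plus merging rejoins
  them.

At full resolution (`min_fragment = 1`) every true breakpoint is
reported, and the event log records every planted event besides. Under
the default conditions with 10 inversions + 3 translocations on one
branch, the pipeline recovers ≥ 95% of floored-truth boundaries within
±25 genes (typically 98–100%), all truth adjacencies, and every
inversion flag; this held on every seed of a 20-seed sweep during
development.

## The backbone scenario

`scenario_dataset()` builds the package's worked example of the
phylogenetic argument. Three block associations (A–W–B, I–U–J, D–R–E)
are made family-ancestral by planting translocations on the root stem;
the analogues of Aethionema and Arabis retain them, while the analogues
of lineages III/E, I/A and II/B each move the inserted segments to
lineage-specific positions — independent losses. The painted maps then
show six derived adjacency characters present exactly in {Aeth, Arab}
(two extremity characters per association), plus one shared by all taxa
(the reunion of the donor chromosome's flanks). On these characters the
topology with the Arabideae analogue branching immediately after
Aethionema costs one change per {Aeth, Arab} character, while the
topology nesting Arabideae inside lineage II costs two: 8 versus 16
changes in total, the "fewer changes" reading of the ancestral-state
interpretation. The scenario plants losses as explicit events rather
than random ones so that the character pattern is guaranteed, whatever
the seed; the Fitch comparison itself is still computed, not asserted.

## Numerical and degenerate-input choices

* Chaining tie-breaks: equal-score chains resolve to the smaller start
  rank (then chromosome pair, then forward orientation), making
  extraction deterministic.
* `merge_blocks` sorts canonically before merging; the fixpoint is
  therefore permutation-invariant, and `deduplicate_blocks` breaks exact
  median ties by block id for the same reason.
* Fragments with a single anchor take their block's orientation (a
  one-point correlation is undefined).
* Empty anchor sets chain to an empty block list, not an error; an
  all-missing-Ks block stays unclassified and is retained but never
  painted.
* Unresolvable anchor rows are skipped with a counted warning;
  duplicate gene ids and overlapping GB intervals are hard errors naming
  the offender.
* The pipeline (`run_pipeline()`) is a pure function of inputs and
  configuration — no stage draws random numbers — and echoes its
  effective configuration into every output directory. Configuration
  files are YAML (the R ecosystem's norm; the `yaml` package is the
  standard reader, and no TOML parser is part of this stack).

## Problem sizes used by the checks

The test suite and the acceptance script size their simulations to the
statistical need of each claim: chaining exactness uses 200 instances of
≤ 12 anchors against exhaustive enumeration (the enumeration, not the
DP, is the constraint); Ks claims use 5,000 draws and 200 blocks of 25
anchors; structural recovery uses the full 22-block, 100-genes-per-block
karyotype; the Fitch oracle enumerates all 15 unrooted five-taxon
topologies. These sizes are the package's own choices for a complete
check of each property.

## Known limitations

* Quota/depth constraints (coverage ratios) of quota-alignment are not
  enforced; only the merge step is reproduced, as specified.
* A third, older WGD mode (At-β-like) is not classified separately: any
  block with median Ks above the cut falls into the single WGD-paralog
  class.
* The Fitch scorer requires binary topologies (after rooting) and binary
  characters; generalised multifurcation parsimony is out of scope.
* Adjacency characters are presence-coded; absence is either real or
  down-coded to missing by the user — the package does not infer
  assembly completeness.
* Sub-floor rearrangement fragments are invisible to the detector by
  construction; claims about them are restricted to the full-resolution
  ground truth.
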