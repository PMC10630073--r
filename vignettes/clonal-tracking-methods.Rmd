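---
title: "Methods: incremental graph-based clonal tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: incremental graph-based clonal tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The tracking problem

Integration-site (IS) analysis identifies, per sample, clusters of
sequencing reads supporting one putative vector integration ("subg"),
each annotated with the genomic positions its consensus aligns to, the
alignment scores, repeat labels when the consensus lands in repetitive
or low-complexity regions, and four abundance quantifications: `weight`
(reads), `shear` (distinct sonication fragment lengths), `tag` (distinct
UMIs) and `combo` (distinct UMI–fragment pairs). Clonal tracking is the
step that decides which clusters, across samples, are the same clone.

`clonetracker` models this as a typed property graph. Every cluster
becomes a `subg` node connected to exactly one `sample` node, to one
`pos` node per alignment (`insertion` edges, plus one `main_insertion`
edge when a dominant alignment exists) and to one `label` node per
repeat annotation (`repeat` edges). Positions are identified exactly by
(chromosome, 1-based coordinate, strand); the strand-less
`chrom_coordinate` string (the `searchlabel`) is kept as a query key.
Because candidate mates must share at least one position or label, the
per-position and per-label indexes retrieve, for a newly inserted
cluster, exactly the clusters that could possibly match — never fewer —
and only those pairs are scored. This is what turns the quadratic
all-versus-all comparison into work proportional to actual locus
sharing.

## Matching rules and their edge cases

Two clusters of *distinct* samples are the same clone iff one of four
rules fires (evaluated 1→4; the first hit is stored on the `gtris` edge
as an audit trail — the rules are a disjunction, so evaluation order
never affects connectivity):

1. both clusters have a single, identical position;
2. the shared-position fraction is at least 50%;
3. at least one shared label *and* at least one shared position;
4. the top-scoring positions coincide.

Decisions taken where the rule statements leave room:

* **Rule 2 denominator.** "Share at least 50% of the genomic positions"
  does not name a denominator. The default is
  `|P_A ∩ P_B| / min(|P_A|, |P_B|) ≥ 0.5`, so a cluster whose position
  list is a subset of a larger repeat family still links; `union`
  (Jaccard-style) and `each` (the fraction must hold for both sides)
  are available via `run_config(rule2_mode = )`.
* **Rule 4 under ties.** If either cluster has an exact tie for its top
  score, "the position having max alignment score" is undefined and
  rule 4 does not fire. No tie-break is invented.
* **Same-sample pairs** are a contract violation, not a non-match:
  the rules are defined across samples only, and `insert_sample()`
  never evaluates within-sample pairs.
* **Label-only clusters** (no positions at all, as produced by the
  sparse-matrix converter for repeat-annotated rows) can never link:
  every rule requires at least one shared position. Such rows therefore
  stay one row per sample in the exported matrix. This is consistent
  with repeat IDs not being comparable across tools or runs; the
  simulator instead emits repeats as multi-target records, which track
  via rule 2.

## Dominant-alignment selection

A multi-mapping cluster receives a `main_insertion` when its top score
dominates: with the two best scores `s1 ≥ s2`, iff
`(s1 − s2)/s1 > threshold`. `threshold` lives in `[0, 1)` and defaults
to 0.3 (a 30% relative gap). The alternative characterization of
dominance as "best at least twice the second" corresponds to
`threshold = 0.5` and is available through the same parameter; the
parameterized relative-gap form was chosen because it is the
implementation-level description and exposes the knob. Single-target
clusters are always dominated by their one target; exact top ties and
empty target lists yield no dominant alignment. Position identity is
exact — no coordinate tolerance window is applied anywhere, since
near-coordinate merging is a property of upstream clustering, not of
tracking.

## From links to the tracking matrix

Rows of the exported matrix are groups of linked clusters. The default
grouping is the connected components of the `gtris` relation
(`max_depth = Inf`), because full transitive closure is the unique
order-invariant choice: any finite propagation depth makes row
membership depend on which cluster seeds the walk. A literal
second-degree propagation (`max_depth = 2`) is available for
comparison; on clean dilution-standard data the two coincide.

Each row is annotated with a representative locus: every member
contributes its single position (if unambiguous) or its
`main_insertion`; the most frequent position wins, ties broken by
summed alignment score, then lexicographically. Pure-repeat groups get
`REPEAT_<hash>` identifiers derived from the sorted member labels and
positions — deterministic content hashes rather than random IDs, so two
exports of the same graph are byte-identical and runs are comparable.
When two unlinked groups elect the same locus, row IDs are
disambiguated deterministically (`#2`, `#3`, ...) and the event is
visible in the output rather than silently merged; splitting a linked
group whose members disagree on their main position is deliberately
*not* done, because pruning would break the equivalence with the
all-versus-all oracle.

`numsubg` is the member count and `numexp` the number of samples with a
non-zero cell — the only readings consistent with their position
between the locus annotation and the member list in the header. Cells
sum the chosen quantification over members per sample, so for `weight`
every column sums exactly to the sample's total read count
(conservation, asserted in the tests). `relative_abundance()` rescales
each column to 100.

## The dilution-standard simulator

The simulator emulates the two validation assay designs shipped as TSV
fixtures: a serial dilution (CEM1, 1 known IS, 70% → 0%; CEM6, 6 known
ISs, constant 30%; random JY background filling the remainder, mixes
L–T) and a clonal-expansion design (lines A–D with 1/3/6/10 known ISs
across 17 mixes). Choices, fixed once:

* **Genome model**: 5 chromosomes × 10 Mb. Tracking depends on
  positions, not sequence; consensus sequences are random strings of
  plausible length.
* **Background inventory**: the random line's IS count is not printed
  in the designs; 500 random ISs is used, consistent with the several
  hundred background ISs expected when the background line approaches
  half the mix. Background loci are drawn uniformly
  (length-weighted chromosomes) without replacement, avoiding known
  loci.
* **Copy number**: a line with VCN > 1 carries multiple known ISs per
  cell (as CEM6 does); per-cell copy number is not stochastic.
  Background clones carry one IS each.
* **Counts**: cells are multinomial over lines; each cell yields one
  sonication fragment per IS; fragment lengths are uniform integers in
  [50, 1200] drawn without replacement within a clone (saturating at
  the 1151-length capacity, as real shear-count quantification
  saturates); UMIs are uniform over 65 536 tags. At default depth each
  fragment yields one read, so `weight` equals the clone's true cell
  count and ground-truth recovery can be asserted exactly;
  `extra_read_rate` adds Poisson amplification reads.
* **Repeats**: a configurable fraction of clones is emitted
  multi-target, with decoy positions and a dominant or non-dominant
  score profile plus a repeat label, all derived deterministically from
  the clone identity so the same clone is emitted identically in every
  sample and replicate.
* **Noise**: spurious singleton clones of weight 1–3 at a configurable
  Poisson rate per sample, emulating the extra low-abundance ISs
  observed even in background-free standards; off by default.
* **Mix percentages**: where the printed design percentages are rounded
  so that columns do not sum exactly to 100, the background percentage
  is stored as the exact complement of the known lines.

What the simulator does **not** model: read-level artifacts (sequencing
error, PCR chimeras), alignment-score distributions of real aligners,
cross-contamination between samples, or collision structure of real
repeat families. Passing recovery tests therefore demonstrates that the
tracking engine is exact on its inputs, not that upstream IS
identification is error-free.

## Validation strategy and problem sizes

Every structural claim is checked against an independent oracle: the
incremental `gtris` edge set against `brute_force_track()` (all
cross-sample pairs, no index), row grouping against union-find over the
oracle pairs (and against an external graph library), candidate
retrieval against a naive full scan, and GraphML round-trips against
the canonical graph serialization. The test suite runs 50 randomized
instances (up to 10 samples and 500 clusters, repeat fraction up to
0.3) for oracle equivalence, 10 random insertion orders for order
invariance, full-assay recovery at 10⁴ cells per sample across the nine
serial-dilution mixes, and round-trips a multi-thousand-node assay
graph — sizes chosen to exercise every rule and edge kind while keeping
the suite quick on a laptop.

## Known limitations

* `match_rule()` is O(candidates) per insertion with exact index
  retrieval, but a cluster mapping to an enormous position set (a deep
  repeat) still retrieves many candidates; the engine does not cap
  candidate lists.
* Whether the 50% of rule 2 should be measured against each side
  separately in the original formulation is unresolved; the choice is
  explicit and configurable.
* The matrix converter's lossy default (`weight = shear = tag = combo =
  cell value`) is only appropriate when the source matrix carries a
  single quantification.
* Graphs are in-memory; persistence is GraphML files, not a database
  server, and no concurrent mutation is supported.
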