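---
title: "Reconstructing ancestral karyotypes from gene-order synteny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral karyotypes from gene-order synteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleosynteny)
library(data.table)
```

## The problem

All flowering-plant genomes descend from repeated cycles of polyploidization
and fractionation. After a whole-genome duplication (WGD) the two (or three)
parental subgenomes erode unevenly: one — the *least fractionated* (LF, also
called dominant) compartment — keeps more of the ancestral gene complement
than the *most fractionated* (MF, sensitive) one. Recurrent WGD makes naive
sequence-similarity searches conflate orthologs (related by speciation) with
paralogs (related by duplication), which in turn corrupts any ancestral-genome
inference built on them.

`paleosynteny` implements a four-step, gene-order-based procedure for
reconstructing an ancestral karyotype — a set of *conserved ancestral
regions* (CARs, protochromosomes) populated by *protogenes* (PGs,
cross-species homology groups) — from two inputs that any comparative
project already has: per-species gene-position tables and an all-vs-all
protein BLAST.

## The four steps

**Step 1 — conserved genes.** Every (query, subject) gene pair's HSPs are
aggregated into the cumulative aligned length $AL = \sum_h L_h$ and two
percentages:

$$\mathrm{CIP} = 100 \cdot \frac{\sum_h \mathrm{id}_h}{AL}, \qquad
  \mathrm{CALP} = 100 \cdot \frac{AL}{L_\text{query}}.$$

A pair is *conserved* when CIP ≥ 50 and CALP ≥ 50 (inclusive). Requiring a
high cumulative identity *over* a high cumulative coverage is what makes the
filter stringent: a short perfect hit fails CALP, a long weak hit fails CIP.
Two deliberate readings are documented here:

* HSP lengths are summed **without overlap trimming** — the definition of
  $AL$ is a plain sum, so CALP can exceed 100 % when HSPs overlap on the
  query. Such values are kept and visible in the Step-1 output.
* The CALP denominator is always the **query's own length**, never
  $\max(L_q, L_s)$, so the two directions of an all-vs-all comparison can
  disagree. By default (`direction = "either"`) a pair is retained when at
  least one direction passes; `direction = "both"` is offered for extra
  stringency (the original pipeline's behaviour on this point is not
  recorded, so both are implemented and the permissive one is the default).

**Step 2 — orthologs.** Tandem-duplicate arrays (genes conserved with each
other, on one chromosome, within `window = 5` intervening gene ranks,
closed transitively) are collapsed to one representative — the member with
the highest summed cross-species score, ties going to the lowest rank then
the smallest gene id. Remaining cross-species pairs pass a *generalized
reciprocal best hit*: with directional multiplicity $n_{AB}$ (how many
partners a gene of A may keep in B, i.e. $n$ for $n$ WGD rounds on the B
lineage), edge $(a, b)$ survives iff $b$ is among $a$'s top-$n_{AB}$
partners **and** $a$ is among $b$'s top-$n_{BA}$ partners, ranked by score.
With all multiplicities 1 this is classical RBH. Genes that lose every
partner are species-specific duplicates; they are reported, not silently
deleted, and remain available to Step 4's back-filling.

**Step 3 — synteny blocks.** Ortholog rows become *anchors* carrying the
gene ranks (0-based order along the chromosome — the method is rank-based
throughout; base-pair coordinates and strand are carried for reporting
only). Within each chromosome-to-chromosome combination, anchors are
grouped by connected components of the *gap-adjacency graph*: two anchors
are adjacent when they differ by at most `max_gap = 15` ranks on **both**
genomes. Components with at least `min_anchors = 6` anchors — blocks must
share *more than five* orthologous genes, read strictly — become synteny
blocks. Setting `max_gap = Inf` turns off the gap constraint and reproduces
the coarse chromosome-pair rule (all shared orthologs of a chromosome pair
in one block); the finite default is this package's refinement, without
which a single rearranged chromosome pair would chain unrelated segments
into one block. Block orientation is reported as `same`/`inverted` when the
Spearman rank correlation of anchor ranks is ≥ +0.5 / ≤ −0.5, else `mixed`;
the threshold is a reporting convention and does not affect chaining.

**Step 4 — CARs.** Protogenes are connected components of the anchor-gene
graph (genes linked by any anchor, merged transitively across species
pairs). CARs are connected components of the block graph, in which two
blocks are linked **when they share at least one protogene**. The
specification of "independent groups of blocks sharing synteny" leaves the
segment-identification rule open; identifying segments by *span overlap*
was rejected because any segment translocated into a chromosome lies inside
the host block's span interval, which would fuse the host's CAR with the
translocated segment's CAR on every tip-branch translocation. Sharing gene
content is the minimal relation that merges exactly the blocks that carry
the same ancestral material — including the two subgenome copies of a
post-WGD genome, which is what lets a duplicated descendant merge back into
a single protochromosome.

Protogene order within a CAR uses a normalized-position rule: each species'
CAR genes are ordered by (chromosome, rank) and scaled to [0, 1]; a
protogene's key is its position in the `reference` species when present
there, otherwise the median of its normalized positions across species
(`reference = "median"` uses the median for everything). Ties break by
protogene id. The original ordering algorithm is unrecorded; this rule is a
package convention, chosen because it is exact on undisturbed data and
degrades gracefully (a protogene absent from the reference with median
position 0.4 lands between neighbours at 0.3 and 0.5).

Finally, Step-1 conserved genes that ended up in no protogene are
*back-filled*: a gene attaches to the protogene of its best-scoring
conserved partner (ties: lowest pg id), at most once, flagged
`backfilled = TRUE` so downstream users can separate 1:1-supported members
from extended ones. Attachment is restricted to existing protogenes and
never changes CAR structure or order. Protogenes are then classified *core*
(members in every investigated species) or *dispensable* (members in at
least two); a single-species protogene is a hard error because it
contradicts the dispensable definition. LF/MF labelling compares, for each
pair of segments descending from one ancestral region through a WGD, the
number of protogenes retaining a member in each segment: more retained =
LF, ties labelled by lexicographic segment id with a `tie` flag.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `cip_min`, `calp_min` | 50, 50 | % | the method's published stringency thresholds, inclusive |
| `direction` | `either` | – | one all-vs-all BLAST gives per-query statistics; `both` offered for stringency |
| `window` (tandem) | 5 | gene ranks | tandem removal is required but no window is recorded; 5 intervening genes is the field's usual tandem-array scale |
| `min_anchors` | 6 | anchors | "more than five orthologous genes", read strictly |
| `max_gap` | 15 | gene ranks | splits chains at rearrangement breakpoints; `Inf` recovers the coarse chromosome-pair rule |
| `reference` | `median` | – | ordering key; pick a well-assembled, slowly evolving genome on real data |
| multiplicity map | all 1 | copies | set `A>B: n` after $n{-}1$ WGDs on the B lineage |

Tie-breaking is deterministic everywhere (score descending, then
lexicographic identifiers), so identical inputs and configuration reproduce
byte-identical outputs; the pipeline manifest records parameters and input
checksums to make that auditable.

## What the simulator emulates

`simulate_synteny_dataset()` evolves an ancestral genome (default 1000
genes on 5 chromosomes) along a rooted species tree (default: ladder with
unit branch lengths) through the classical event vocabulary — inversions,
fusions, fissions, translocations, deletions, tandem duplications, and WGD
with biased fractionation. Event counts per branch are Poisson(rate ×
branch length) with uniformly drawn positions; no stochastic model for
these events is published, so the simplest exchangeable model is used.

Default per-unit-branch rates are inversion 2.5, deletion 1.0, tandem
duplication 0.6, translocation 0.2, fusion 0.1, fission 0.1 — about 4.5
events per branch in total, with interchromosomal events an order of
magnitude rarer than inversions, the ratio observed across plant lineages.
Homolog identities decay linearly with pairwise tree distance (6 %/unit,
Gaussian noise SD 2 %, floor 20 %), so true orthologs stay comfortably
above the CIP ≥ 50 filter at the default tree depths while spurious pairs
(rate 0.05 per gene, identity < 40 %) fall below it by construction.
Post-WGD losses hit the designated MF subgenome with probability
`fractionation_bias = 0.7`, the magnitude of retention bias typically
reported for paleopolyploid plant genomes.

The simulator produces modelled identity numbers, not sequences; it does
not emulate assembly gaps, annotation error, gene conversion between
ohnologs, segmental (non-tandem) duplication, or rate heterogeneity across
genes. A green recovery test therefore establishes that the *inference
logic* is correct under the stated generative model — not that the pipeline
is robust to every artefact of real annotations.

## Degenerate inputs and numerical choices

* Empty gene tables and empty BLAST files are valid and yield empty
  outputs; self-hits are dropped at parse time; `nident > length` and
  `start > end` are hard errors with the offending row named.
* A one-anchor "block" cannot exist (min 6); a block whose ranks admit no
  Spearman correlation (ties everywhere) reports orientation `mixed`.
* CALP > 100 (overlapping HSPs) is legal and preserved.
* Oracle-equivalence tests compare at 1e-9; no other numeric tolerances
  exist — everything else is integer/rank arithmetic.
* The submission workbook's canonical on-disk dialect is one TSV per sheet
  (plus a two-column dataset descriptor); the spreadsheet mirror is omitted
  because no XLSX writer is available in the supported environment, and the
  exchange format explicitly admits a text form. Column headers are this
  package's documented dialect, since the public template's headers are not
  standardized in the literature.

## Known limitations

* Without an explicit parsimony step (out of scope), an interchromosomal
  event on an *internal* branch shared by several species — a fusion or
  translocation present in two genomes and absent from the outgroup — makes
  the affected blocks genuinely share protogenes across two ancestral
  chromosomes, merging their CARs. Recovery tests use the median over
  replicates for exactly this reason; single replicates that drew such an
  event score visibly lower adjusted Rand indices.
* Subgenome labels refer to the most recent WGD on a lineage; nested
  paleopolyploidies are simulated but their older subgenome assignments are
  not tracked.
* Triplication fractionation applies two independent loss rounds with the
  highest-label subgenome as the MF-most target — a documented convention,
  as no per-copy loss model is published.
* Back-filling attaches genes only to existing protogenes (never creates
  new ones, never crosses families through one-to-many links), the
  conservative reading of "conserved genes … can be included in each
  protochromosome".
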