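# paleosynteny

Ancestral karyotype reconstruction from gene-order synteny, for comparative
plant (and other eukaryote) genomics.

All extant plant genomes are ancient polyploids: repeated whole-genome
duplications (WGD) followed by biased fractionation — uneven gene loss
between the least-fractionated (LF, dominant) and most-fractionated (MF,
sensitive) subgenomes — blur the distinction between orthologs and paralogs
and defeat naive similarity searches. `paleosynteny` reconstructs the
karyotype of the common ancestor of a set of sequenced species from two
standard inputs (per-species gene positions and an all-vs-all protein BLAST)
with a four-step, gene-rank-based procedure:

1. **Conserved genes** — per gene pair, HSPs are aggregated into the
   cumulative aligned length AL = Σ<sub>h</sub> L<sub>h</sub> and filtered by

   CIP = 100 · Σ<sub>h</sub> id<sub>h</sub> / AL ≥ 50  and
   CALP = 100 · AL / L<sub>query</sub> ≥ 50

   (cumulative identity percentage / cumulative alignment length
   percentage, inclusive thresholds).
2. **Orthologs** — tandem-duplicate arrays are collapsed to one
   representative, then a generalized reciprocal best hit keeps 1:1
   relationships (1:*n* under *n* WGD rounds, via a per-species-pair
   multiplicity map).
3. **Synteny blocks (SBs)** — ortholog anchors on each chromosome pair are
   chained by connected components of a gap-adjacency graph (≤ 15 ranks on
   both genomes, configurable); a block must share **more than five**
   orthologous genes.
4. **Protochromosomes (CARs)** — blocks sharing protogenes are merged
   transitively into conserved ancestral regions; protogenes are ordered,
   conserved genes beyond 1:1 relations are back-filled, each protogene is
   classified **core** (present in all investigated species) or
   **dispensable** (in ≥ 2), and duplicated descendant segments are
   labelled LF/MF by retained-protogene counts.

A ground-truthed genome-evolution simulator (inversions, fusions, fissions,
translocations, deletions, tandem duplications, WGD with biased
fractionation, identity decay along the species tree) provides testable
inputs, and readers/writers cover the tabular exchange formats involved,
including the four-sheet submission workbook with dataset-consistency
validation. See `vignettes/ancestral-karyotypes.Rmd` for the full model
description and design rationale.

## Worked example

Simulate three species diverging from a 300-gene, 3-chromosome ancestor,
write the dataset to disk, and run the full pipeline on the files:

```r
library(paleosynteny)

cfg <- simulation_config(n_ancestral_chromosomes = 3, n_ancestral_genes = 300,
                         seed = 7)
sim <- simulate_synteny_dataset(cfg)
write_simulation(sim, "demo")

res <- run_pipeline(list(genes = "demo/genes.tsv", blast = "demo/blast.tsv",
                         out_dir = "demo/out", reference = "A"))
#> [io_formats] 894 genes (3 species), 1830 HSPs
#> [homology] 893 conserved pairs
#> [orthology] 886 ortholog relationships
#> [synteny] 23 blocks from 886 anchors
#> [karyotype] 3 CARs, 298 protogenes (294 core)

res$karyotype
#> <ancestral_karyotype> 3 CAR(s), 298 protogene(s), 892 member gene(s), species: A, B, C
res$karyotype$cars
#>    car_id n_pgs n_blocks
#> 1: CAR001   100        7
#> 2: CAR002    99        3
#> 3: CAR003    99       13

truth_metrics(res$karyotype, sim$truth)$ari
#> [1] 1
```

Reading the numbers: the simulation drew 18 events (10 inversions, 6
deletions, 1 fission, 1 tandem duplication) on top of speciation, so the
three species keep 894 of 900 possible gene copies. Step 1 retains 893
conserved pairs (spurious low-identity hits fall below CIP 50 by
construction), Step 2 resolves them to 886 one-to-one orthologs, Step 3
chains these into 23 blocks (inversions longer than `max_gap` split
chains), and Step 4 merges the blocks back into exactly 3 CARs — the true
ancestral chromosome number, with an adjusted Rand index of 1.0 between
inferred CAR membership and the simulated ancestral chromosomes. 294 of
298 protogenes are core; the rest lost a member in one species through
deletion. `demo/out/` holds one TSV per step, the four-sheet submission
workbook, and a manifest with parameters and input checksums.

On real data, start from `read_gene_table()` (TSV or GFF3) and
`read_blast_tabular()` (outfmt 6 + `nident`), and set the multiplicity map
for known WGDs, e.g. `multiplicity = "Athaliana>Zmays:2"`.

There is also a thin CLI over the same API:

```sh
Rscript $(Rscript -e 'cat(system.file("exec", "paleosynteny", package = "paleosynteny"))') \
    run --config pipeline.cfg
```

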