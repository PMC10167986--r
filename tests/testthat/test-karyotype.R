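# helpers building minimal multi-species block sets

three_species_blocks <- function() {
  # chrA1-chrB1 and chrB1-chrC2 linked through shared genes of B
  ab <- data.table(gene_a = sprintf("a%02d", 1:8), gene_b = sprintf("b%02d", 1:8),
                   species_a = "A", species_b = "B", chr_a = "A1", chr_b = "B1",
                   rank_a = 0:7, rank_b = 0:7)
  bc <- data.table(gene_a = sprintf("b%02d", 1:8), gene_b = sprintf("c%02d", 1:8),
                   species_a = "B", species_b = "C", chr_a = "B1", chr_b = "C2",
                   rank_a = 0:7, rank_b = 0:7)
  chain_all_blocks(rbind(ab, bc))
}

test_that("blocks linked through shared genes merge into one CAR, disjoint sets stay apart", {
  kary <- group_blocks_into_cars(three_species_blocks())
  expect_equal(nrow(kary$cars), 1L)
  expect_setequal(kary$segments$chromosome, c("A1", "B1", "C2"))
  expect_equal(nrow(kary$protogenes), 8L)
  # every protogene spans the three species via transitive merging
  expect_equal(kary$members[, uniqueN(species), by = pg_id][, unique(V1)], 3L)

  # disjoint chromosome sets -> two CARs
  ab <- data.table(gene_a = sprintf("a%02d", 1:8), gene_b = sprintf("b%02d", 1:8),
                   species_a = "A", species_b = "B", chr_a = "A1", chr_b = "B1",
                   rank_a = 0:7, rank_b = 0:7)
  ab2 <- data.table(gene_a = sprintf("x%02d", 1:8), gene_b = sprintf("y%02d", 1:8),
                    species_a = "A", species_b = "B", chr_a = "A2", chr_b = "B2",
                    rank_a = 0:7, rank_b = 0:7)
  kary2 <- group_blocks_into_cars(chain_all_blocks(rbind(ab, ab2)))
  expect_equal(nrow(kary2$cars), 2L)
  paleosynteny:::audit_karyotype(kary2)
})

test_that("group_blocks_into_cars equals brute-force transitive closure on small instances", {
  for (seed in 51:54) {
    set.seed(seed)
    cfg <- simulation_config(n_ancestral_chromosomes = 3L,
                             n_ancestral_genes = 48L,
                             rates = list(), spurious_rate = 0, seed = seed)
    sim <- simulate_synteny_dataset(cfg)
    res <- reconstruct_from_simulation(sim)
    kary <- res$karyotype
    # oracle: union-find over anchor gene pairs (transitive closure)
    anc <- res$blocks$anchors[!is.na(block_id)]
    ids <- unique(c(anc$gene_a, anc$gene_b))
    p <- uf_new(length(ids))
    for (i in seq_len(nrow(anc))) {
      p <- uf_union(p, match(anc$gene_a[i], ids), match(anc$gene_b[i], ids))
    }
    roots <- vapply(seq_along(ids), function(i) uf_find(p, i), integer(1))
    expect_equal(nrow(kary$protogenes), length(unique(roots)))
    # same partition of genes into protogenes
    got_part <- split(kary$members$gene_id, kary$members$pg_id)
    exp_part <- split(ids, roots)
    expect_setequal(
      unname(vapply(got_part, function(g) paste(sort(g), collapse = ","), "")),
      unname(vapply(exp_part, function(g) paste(sort(g), collapse = ","), "")))
  }
})

test_that("order_protogenes sorts by reference rank with median insertion fallback", {
  kary <- group_blocks_into_cars(three_species_blocks())
  genes <- rbind(
    data.table(gene_id = sprintf("a%02d", 1:8), species = "A", chromosome = "A1",
               start = c(6, 3, 8, 1, 5, 2, 7, 4) * 100L, end = 0L, strand = "+"),
    data.table(gene_id = sprintf("b%02d", 1:8), species = "B", chromosome = "B1",
               start = (1:8) * 100L, end = 0L, strand = "+"),
    data.table(gene_id = sprintf("c%02d", 1:8), species = "C", chromosome = "C2",
               start = (1:8) * 100L, end = 0L, strand = "+"))
  genes[, end := start + 10L]
  genes <- assign_gene_ranks(genes)
  ordered <- order_protogenes(kary, genes, reference = "A")
  ranks <- merge(ordered$protogenes, kary$members[species == "A"], by = "pg_id")
  # protogene order must follow species-A gene order: a04,a06,a02,a08,a05,a01,a07,a03
  a_order <- genes[species == "A"][order(rank), gene_id]
  expect_equal(ranks[order(ancestral_rank), gene_id], a_order)

  expect_error(order_protogenes(kary, genes, reference = "Z"), "absent")

  # median rule orders consistently when reference bears no pg
  med <- order_protogenes(kary, genes, reference = "median")
  expect_setequal(med$protogenes$ancestral_rank, 0:7)
})

test_that("backfill attaches unassigned conserved genes to one best protogene", {
  kary <- group_blocks_into_cars(three_species_blocks())
  n_pg <- nrow(kary$protogenes)
  n_mem <- nrow(kary$members)
  # gX conserved with a01 (member of some pg) and a stronger link to a02's pg
  extra <- rbind(
    make_pairs("a01", "gX", "A", "A", score = 50),
    make_pairs("a02", "gX", "A", "A", score = 80))
  filled <- backfill_conserved_genes(kary, extra)
  expect_equal(nrow(filled$protogenes), n_pg)  # pg count unchanged
  expect_equal(nrow(filled$members), n_mem + 1L)
  got <- filled$members[gene_id == "gX"]
  expect_true(got$backfilled)
  expect_equal(got$pg_id, kary$members[gene_id == "a02", pg_id])  # best score wins

  # idempotent-ish: gX now assigned, nothing further to add
  expect_equal(nrow(backfill_conserved_genes(filled, extra)$members), n_mem + 1L)
  # member count non-decreasing on fuzzed inputs
  for (seed in 61:63) {
    set.seed(seed)
    fuzz <- make_pairs(sample(c(kary$members$gene_id, paste0("z", 1:5)), 10, TRUE),
                       paste0("w", 1:10), "A", "A", score = runif(10))
    out <- backfill_conserved_genes(kary, fuzz)
    expect_gte(nrow(out$members), n_mem)
    expect_equal(nrow(out$protogenes), n_pg)
    expect_true(!anyDuplicated(out$members$gene_id))
  }
})

test_that("core/dispensable classification counts species presence", {
  kary <- group_blocks_into_cars(three_species_blocks())
  kary <- classify_protogenes(kary)  # all pgs span A, B, C
  expect_true(all(kary$protogenes$status == "core"))
  # against a larger species set they are dispensable (present in 3 of 4)
  kary4 <- classify_protogenes(kary, species = c("A", "B", "C", "D"))
  expect_true(all(kary4$protogenes$status == "dispensable"))
  # counts always add up
  expect_equal(sum(kary$protogenes$status %in% c("core", "dispensable")),
               nrow(kary$protogenes))
  # single-species pg violates the dispensable definition
  broken <- kary
  broken$members <- rbind(broken$members,
                          data.table(pg_id = "PG999999", species = "A",
                                     gene_id = "lone", backfilled = FALSE))
  broken$protogenes <- rbind(broken$protogenes,
                             data.table(pg_id = "PG999999", car_id = NA_character_,
                                        ancestral_rank = NA_integer_,
                                        status = NA_character_))
  expect_error(classify_protogenes(broken), "PG999999")
})

test_that("fractionation labelling compares retained protogene counts", {
  kary <- group_blocks_into_cars(three_species_blocks())
  genes <- rbind(
    data.table(gene_id = sprintf("a%02d", 1:8), species = "A", chromosome = "A1",
               start = (1:8) * 100L, end = (1:8) * 100L + 10L, strand = "+"),
    data.table(gene_id = sprintf("b%02d", 1:8), species = "B", chromosome = "B1",
               start = (1:8) * 100L, end = (1:8) * 100L + 10L, strand = "+"),
    data.table(gene_id = sprintf("c%02d", 1:8), species = "C", chromosome = "C2",
               start = (1:8) * 100L, end = (1:8) * 100L + 10L, strand = "+"))
  genes <- assign_gene_ranks(genes)
  seg <- data.table(pair_id = "p1",
                    segment_id_1 = "segA", species_1 = "A", chromosome_1 = "A1",
                    lo_1 = 0L, hi_1 = 7L,
                    segment_id_2 = "segB", species_2 = "B", chromosome_2 = "B1",
                    lo_2 = 0L, hi_2 = 3L)
  lab <- classify_fractionation(kary, seg, genes)
  expect_equal(lab$lf_segment, "segA")  # 8 pgs vs 4 pgs
  expect_equal(lab$n_lf, 8L)
  expect_equal(lab$n_mf, 4L)
  expect_false(lab$tie)

  tie_seg <- copy(seg)[, `:=`(hi_2 = 7L)]
  lab2 <- classify_fractionation(kary, tie_seg, genes)
  expect_true(lab2$tie)
  expect_equal(lab2$lf_segment, "segA")  # lexicographic tie rule
})
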