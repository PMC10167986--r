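# Fixture builders (everything generated in code; nothing on disk).

library(data.table)

# random multi-HSP table over n_pairs directed gene pairs
random_hsps <- function(n_pairs, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_pairs), function(i) {
    q <- sprintf("q%03d", i)
    s <- sprintf("s%03d", i)
    k <- sample(1:5, 1)
    len <- sample(30:200, k, replace = TRUE)
    nid <- vapply(len, function(l) sample.int(l, 1), integer(1))
    data.table(query_id = q, subject_id = s, hsp_length = len,
               n_identities = nid, query_start = 1L, query_end = len,
               subject_start = 1L, subject_end = len,
               score = round(runif(k, 50, 500), 1))
  })
  rbindlist(rows)
}

random_query_lengths <- function(hsps, seed) {
  set.seed(seed + 1L)
  ids <- unique(hsps$query_id)
  setNames(sample(150:800, length(ids), replace = TRUE), ids)
}

# a small two-species gene layout: one chromosome each, n genes
toy_genes <- function(n = 10, species = c("A", "B")) {
  rbindlist(lapply(species, function(sp) {
    data.table(gene_id = sprintf("%s%02d", tolower(sp), seq_len(n)),
               species = sp, chromosome = "chr1",
               start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 500L,
               strand = "+")
  })) |> assign_gene_ranks()
}

# conserved-pair rows with explicit species
make_pairs <- function(gene_a, gene_b, species_a, species_b, score,
                       CIP = 90, CALP = 90) {
  data.table(gene_a = gene_a, gene_b = gene_b, species_a = species_a,
             species_b = species_b, CIP = CIP, CALP = CALP, score = score)
}

# anchors on one species pair
make_anchors <- function(rank_a, rank_b, chr_a = "c1", chr_b = "c1") {
  n <- length(rank_a)
  data.table(gene_a = sprintf("a%03d", seq_len(n)),
             gene_b = sprintf("b%03d", seq_len(n)),
             species_a = "A", species_b = "B",
             chr_a = chr_a, chr_b = chr_b,
             rank_a = as.integer(rank_a), rank_b = as.integer(rank_b))
}

# tiny valid workbook via a null-model simulation + pipeline
tiny_workbook <- function(seed = 11) {
  cfg <- simulation_config(
    n_ancestral_chromosomes = 2L, n_ancestral_genes = 40L,
    rates = list(), spurious_rate = 0, seed = seed)
  sim <- simulate_synteny_dataset(cfg)
  res <- reconstruct_from_simulation(sim, reference = "A")
  contact <- data.table(name = "Ann Author", email = "ann@example.org",
                        role = "submitter")
  list(wb = build_submission_workbook(res$karyotype, sim$genes, contact,
                                      dataset_name = "toy", version = 1L),
       sim = sim, res = res)
}

# corrupt a workbook in length(kinds) known ways, each planting one distinct
# violation (duplicated gene ids, dangling homology members, unknown
# phylogeny chromosomes)
corrupt_workbook <- function(wb, kinds, seed) {
  set.seed(seed)
  wb <- unserialize(serialize(wb, NULL))  # deep copy
  for (idx in seq_along(kinds)) {
    kind <- kinds[idx]
    if (kind == "dup_gene") {
      wb$genome <- rbind(wb$genome, wb$genome[idx])  # idx-th gene duplicated
    } else if (kind == "dangling_member") {
      i <- 1L + (idx %% nrow(wb$homology))
      wb$homology$members[i] <- paste0(wb$homology$members[i], ",ghost_gene_", idx)
    } else if (kind == "bad_chromosome") {
      wb$phylogeny <- rbind(wb$phylogeny,
                            data.table(species = wb$genome$species[1],
                                       chromosome = paste0("chrX_", idx),
                                       car_id = wb$phylogeny$car_id[1]))
    }
  }
  wb
}
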