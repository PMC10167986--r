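test_that("null model: zero rates give identical genomes and all 1:1 orthologs", {
  cfg <- simulation_config(n_ancestral_chromosomes = 3L, n_ancestral_genes = 60L,
                           rates = list(), spurious_rate = 0, seed = 5)
  sim <- simulate_synteny_dataset(cfg)
  expect_equal(nrow(sim$genes), 3L * 60L)
  per_sp <- split(sim$truth$descent$anc_id, sim$truth$descent$species)
  for (v in per_sp) expect_setequal(v, 1:60)
  # every cross-species gene pair sharing an ancestral gene is a true ortholog
  expect_equal(nrow(sim$truth$true_orthologs), 60L * 3L)  # 3 species pairs
  # chromosome structure identical to the ancestor
  d <- sim$truth$descent
  anc_chr <- setNames(sim$truth$ancestor$chromosome, sim$truth$ancestor$anc_id)
  expect_equal(unname(anc_chr[as.character(d$anc_id)]),
               as.integer(sub("chr", "", d$chromosome)))
})

test_that("WGD doubles gene content; zero loss keeps both copies", {
  cfg <- simulation_config(n_ancestral_chromosomes = 2L, n_ancestral_genes = 40L,
                           species_tree = "(A:1,B:1);", rates = list(),
                           spurious_rate = 0,
                           wgd_events = list(list(branch = "B", type = "duplication",
                                                  loss_rate = 0)),
                           seed = 6)
  sim <- simulate_synteny_dataset(cfg)
  copies <- sim$truth$descent[species == "B", .N, by = anc_id]
  expect_true(all(copies$N == 2L))
  expect_equal(nrow(sim$genes[species == "B"]), 80L)
  expect_equal(length(unique(sim$genes[species == "B", chromosome])), 4L)
})

test_that("unbiased fractionation retains each subgenome near the binomial expectation", {
  cfg <- simulation_config(n_ancestral_chromosomes = 2L, n_ancestral_genes = 1000L,
                           species_tree = "(A:1,B:1);", rates = list(),
                           spurious_rate = 0, fractionation_bias = 0.5,
                           wgd_events = list(list(branch = "B", type = "duplication",
                                                  loss_rate = 0.5)),
                           seed = 7)
  sim <- simulate_synteny_dataset(cfg)
  d <- sim$truth$descent[species == "B"]
  # each subgenome copy survives with prob 1 - 0.5 * 0.5 = 0.75
  p <- 0.75
  se <- sqrt(1000 * p * (1 - p))
  for (sg in 1:2) {
    expect_lt(abs(d[subgenome == sg, .N] - 1000 * p), 3 * se)
  }
})

test_that("simulation is deterministic given seed and conserves gene counts via the ledger", {
  cfg <- simulation_config(n_ancestral_genes = 150L, n_ancestral_chromosomes = 3L,
                           seed = 11)
  s1 <- simulate_synteny_dataset(cfg)
  s2 <- simulate_synteny_dataset(cfg)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$hsps, s2$hsps)
  expect_identical(s1$truth$ledger, s2$truth$ledger)

  # gene-count audit: tip count = ancestral count + sum of ledger deltas on
  # the root-to-tip path
  tree <- s1$truth$tree
  ledger <- s1$truth$ledger
  for (tip in tree$tip.label) {
    node <- which(tree$tip.label == tip)
    path <- character(0)
    repeat {
      lab <- if (node <= length(tree$tip.label)) tree$tip.label[node]
             else tree$node.label[node - length(tree$tip.label)]
      path <- c(path, lab)
      parent <- tree$edge[tree$edge[, 2] == node, 1]
      if (!length(parent)) break
      node <- parent
    }
    delta <- ledger[branch %in% path, sum(delta_genes)]
    expect_equal(nrow(s1$genes[species == tip]), 150L + delta, info = tip)
  }
})

test_that("rearrangement events are recorded and reshape genomes", {
  cfg <- simulation_config(n_ancestral_genes = 120L, n_ancestral_chromosomes = 2L,
                           rates = list(inversion = 3, fission = 1, fusion = 0.5,
                                        translocation = 1, deletion = 2,
                                        tandem_duplication = 2),
                           seed = 13)
  sim <- simulate_synteny_dataset(cfg)
  expect_true(nrow(sim$truth$ledger) > 0)
  expect_true(all(sim$truth$ledger$event %in%
                    c("inversion", "fission", "fusion", "translocation",
                      "deletion", "tandem_duplication")))
  # deletions reduce orthology; duplicated anc genes have several descendants
  expect_true(any(sim$truth$ledger$delta_genes == -1L) ||
                any(sim$truth$ledger$delta_genes == 1L))
})

test_that("identities decay with tree distance and spurious pairs stay below threshold", {
  cfg <- simulation_config(n_ancestral_genes = 100L, n_ancestral_chromosomes = 2L,
                           species_tree = "((A:1,B:1):1,C:3);",
                           rates = list(), spurious_rate = 0.2, noise_sd = 0,
                           seed = 17)
  sim <- simulate_synteny_dataset(cfg)
  h <- sim$hsps
  pid <- 100 * h$n_identities / h$hsp_length
  anc <- setNames(sub("_g.*", "", h$query_id), NULL)
  sp_q <- sub("_g.*", "", h$query_id)
  sp_s <- sub("_g.*", "", h$subject_id)
  close_pairs <- pid[(sp_q == "A" & sp_s == "B") | (sp_q == "B" & sp_s == "A")]
  far_pairs <- pid[(sp_q %in% c("A", "B") & sp_s == "C") |
                     (sp_q == "C" & sp_s %in% c("A", "B"))]
  # true homolog identities dominate each class; A-B closer than A-C
  expect_gt(mean(close_pairs), mean(far_pairs))
  # spurious identities all below the CIP threshold
  spurious <- pid[pid < 50]
  expect_true(length(spurious) > 0)
  expect_true(all(spurious < 50))
})

test_that("multi-HSP emission preserves CIP/CALP aggregation", {
  cfg1 <- simulation_config(n_ancestral_genes = 40L, n_ancestral_chromosomes = 1L,
                            rates = list(), spurious_rate = 0, multi_hsp = TRUE,
                            seed = 19)
  sim <- simulate_synteny_dataset(cfg1)
  expect_true(any(table(paste(sim$hsps$query_id, sim$hsps$subject_id)) > 1))
  s <- summarize_hsps(sim$hsps, sim$query_lengths)
  # full-length coverage regardless of the split
  expect_true(all(abs(s$CALP - 100) < 1e-9))
  res <- reconstruct_from_simulation(sim, reference = "A")
  expect_equal(nrow(res$karyotype$cars), 1L)
})

test_that("truth_metrics: perfect reconstruction scores 1, shuffled orthologs near chance", {
  cfg <- simulation_config(n_ancestral_genes = 80L, n_ancestral_chromosomes = 2L,
                           rates = list(), spurious_rate = 0, seed = 23)
  sim <- simulate_synteny_dataset(cfg)
  res <- reconstruct_from_simulation(sim, reference = "A")
  m <- truth_metrics(res$karyotype, sim$truth, res$orthologs)
  expect_equal(m$ari, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_true(all(m$per_car_tau$tau == 1))

  shuffled <- copy(res$orthologs)
  set.seed(1)
  shuffled[, gene_b := sample(gene_b)]
  m2 <- truth_metrics(res$karyotype, sim$truth, shuffled)
  expect_lt(m2$precision, 0.1)
})

test_that("adjusted_rand_index matches the pair-counting oracle", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    x <- sample(1:4, n, TRUE)
    y <- sample(1:4, n, TRUE)
    expect_equal(adjusted_rand_index(x, y), oracle_ari(x, y), tolerance = 1e-9)
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
})
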