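# Ground-truthed genome-evolution simulator.
#
# An ancestral genome (ordered genes on chromosomes) evolves along a rooted
# species tree through inversions, fusions, fissions, translocations,
# deletions, tandem duplications and whole-genome duplication (WGD) with
# biased fractionation. The simulator emits the exact tabular dialects the
# pipeline consumes (gene tables, HSP tables with identities decaying along
# the tree) plus a ground-truth archive (ancestor order, descent map, event
# ledger, true ortholog pairs) used as the oracle in tests. No sequences are
# simulated: identities are modelled numbers, which suffices for this
# rank-based method.

#' Default balanced species tree with unit branch lengths
#' @param n_species number of tips (2-26; labelled A, B, C, ...).
#' @return Newick string (a ladder with all branch lengths 1).
#' @export
default_species_tree <- function(n_species) {
  stopifnot(n_species >= 2, n_species <= 26)
  tips <- LETTERS[seq_len(n_species)]
  nwk <- sprintf("(%s:1,%s:1)", tips[1], tips[2])
  for (t in tips[-(1:2)]) nwk <- sprintf("(%s:1,%s:1)", nwk, t)
  paste0(nwk, ";")
}

#' Simulation configuration
#'
#' Event rates are expected events per unit branch length (counts drawn
#' Poisson per branch). Defaults emulate moderate plant-genome divergence:
#' intrachromosomal shuffling (inversions) dominates, interchromosomal
#' events (translocations, fusions, fissions) are an order of magnitude
#' rarer, and synthetic HSP identities decay a few percent per unit branch
#' with Gaussian noise, staying well clear of the CIP >= 50 retention
#' threshold for true homologs while spurious hits stay below it.
#'
#' @param n_ancestral_chromosomes,n_ancestral_genes ancestor size.
#' @param species_tree rooted Newick string with branch lengths.
#' @param rates named list: `inversion`, `deletion`, `tandem_duplication`,
#'   `translocation`, `fusion`, `fission` (events per unit branch, >= 0).
#' @param wgd_events list of `list(branch =, type = "duplication" or
#'   "triplication", loss_rate =)`; `branch` names the child node of the
#'   branch carrying the event (tip label or internal node label `N<k>`).
#' @param fractionation_bias probability in \[0.5, 1\] that a post-WGD loss
#'   hits the designated most-fractionated (MF) subgenome.
#' @param identity_decay percent identity lost per unit of pairwise tree
#'   distance.
#' @param noise_sd Gaussian noise (percent) on synthetic identities.
#' @param identity_floor lower bound on emitted identities (percent).
#' @param spurious_rate expected spurious (non-homologous) HSP pairs per
#'   extant gene.
#' @param multi_hsp emit each homolog alignment as 2-4 contiguous HSPs
#'   instead of one full-length HSP (exercises CIP/CALP aggregation).
#' @param seed RNG seed; identical config + seed gives identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_ancestral_chromosomes = 5L,
                              n_ancestral_genes = 1000L,
                              species_tree = default_species_tree(3),
                              rates = list(inversion = 2.5, deletion = 1.0,
                                           tandem_duplication = 0.6,
                                           translocation = 0.2,
                                           fusion = 0.1, fission = 0.1),
                              wgd_events = list(),
                              fractionation_bias = 0.7,
                              identity_decay = 6,
                              noise_sd = 2,
                              identity_floor = 20,
                              spurious_rate = 0.05,
                              multi_hsp = FALSE,
                              seed = 1L) {
  default_rates <- list(inversion = 0, deletion = 0, tandem_duplication = 0,
                        translocation = 0, fusion = 0, fission = 0)
  rates <- utils::modifyList(default_rates, as.list(rates))
  stopifnot(all(unlist(rates) >= 0),
            fractionation_bias >= 0.5, fractionation_bias <= 1,
            n_ancestral_genes >= n_ancestral_chromosomes)
  for (w in wgd_events) {
    stopifnot(!is.null(w$branch), w$type %in% c("duplication", "triplication"))
  }
  cfg <- list(n_ancestral_chromosomes = as.integer(n_ancestral_chromosomes),
              n_ancestral_genes = as.integer(n_ancestral_genes),
              species_tree = species_tree, rates = rates,
              wgd_events = wgd_events,
              fractionation_bias = fractionation_bias,
              identity_decay = identity_decay, noise_sd = noise_sd,
              identity_floor = identity_floor, spurious_rate = spurious_rate,
              multi_hsp = multi_hsp, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# ---------------------------------------------------------------------------
# genome representation: list of chromosomes, each a data.table with columns
# uid, anc_id, strand (+1/-1), subgenome (label wrt most recent WGD; 1 = LF
# side), rows in gene order
# ---------------------------------------------------------------------------

sim_state <- function() {
  env <- new.env(parent = emptyenv())
  env$next_uid <- 1L
  env$ledger <- list()
  env
}

new_uids <- function(st, k) {
  ids <- seq.int(st$next_uid, length.out = k)
  st$next_uid <- st$next_uid + k
  ids
}

log_event <- function(st, branch, event, detail, delta) {
  st$ledger[[length(st$ledger) + 1L]] <-
    data.table(branch = branch, event = event, detail = detail,
               delta_genes = as.integer(delta))
}

drop_empty_chroms <- function(chroms) chroms[vapply(chroms, nrow, integer(1)) > 0L]

apply_inversion <- function(chroms, st, branch) {
  if (!length(chroms)) { log_event(st, branch, "inversion", "skipped: empty genome", 0); return(chroms) }
  ci <- sample.int(length(chroms), 1L)
  n <- nrow(chroms[[ci]])
  ij <- sort(sample.int(n, 2L, replace = TRUE))
  seg <- chroms[[ci]][ij[1]:ij[2]][rev(seq_len(ij[2] - ij[1] + 1L))]
  seg[, strand := -strand]
  chroms[[ci]] <- rbind(if (ij[1] > 1L) chroms[[ci]][1:(ij[1] - 1L)],
                        seg,
                        if (ij[2] < n) chroms[[ci]][(ij[2] + 1L):n])
  log_event(st, branch, "inversion", sprintf("chrom %d ranks %d-%d", ci, ij[1], ij[2]), 0)
  chroms
}

apply_fission <- function(chroms, st, branch) {
  ok <- which(vapply(chroms, nrow, integer(1)) >= 2L)
  if (!length(ok)) { log_event(st, branch, "fission", "skipped: no splittable chromosome", 0); return(chroms) }
  ci <- ok[sample.int(length(ok), 1L)]
  n <- nrow(chroms[[ci]])
  b <- sample.int(n - 1L, 1L)
  left <- chroms[[ci]][1:b]
  right <- chroms[[ci]][(b + 1L):n]
  chroms[[ci]] <- left
  chroms[[length(chroms) + 1L]] <- right
  log_event(st, branch, "fission", sprintf("chrom %d split after rank %d", ci, b), 0)
  chroms
}

apply_fusion <- function(chroms, st, branch) {
  if (length(chroms) < 2L) { log_event(st, branch, "fusion", "skipped: one chromosome left", 0); return(chroms) }
  cij <- sample.int(length(chroms), 2L)
  chroms[[cij[1]]] <- rbind(chroms[[cij[1]]], chroms[[cij[2]]])
  chroms <- chroms[-cij[2]]
  log_event(st, branch, "fusion", sprintf("chroms %d+%d", cij[1], cij[2]), 0)
  chroms
}

apply_translocation <- function(chroms, st, branch) {
  if (length(chroms) < 2L) { log_event(st, branch, "translocation", "skipped: one chromosome left", 0); return(chroms) }
  cij <- sample.int(length(chroms), 2L)
  donor <- cij[1]; recip <- cij[2]
  n <- nrow(chroms[[donor]])
  if (n == 0L) { log_event(st, branch, "translocation", "skipped: empty donor", 0); return(chroms) }
  ij <- sort(sample.int(n, 2L, replace = TRUE))
  seg <- chroms[[donor]][ij[1]:ij[2]]
  rest <- chroms[[donor]][setdiff(seq_len(n), ij[1]:ij[2])]
  m <- nrow(chroms[[recip]])
  p <- sample.int(m + 1L, 1L) - 1L  # insert after position p (0 = front)
  chroms[[recip]] <- rbind(if (p > 0L) chroms[[recip]][1:p], seg,
                           if (p < m) chroms[[recip]][(p + 1L):m])
  chroms[[donor]] <- rest
  log_event(st, branch, "translocation",
            sprintf("chrom %d ranks %d-%d -> chrom %d pos %d", donor, ij[1], ij[2], recip, p), 0)
  drop_empty_chroms(chroms)
}

apply_deletion <- function(chroms, st, branch) {
  sizes <- vapply(chroms, nrow, integer(1))
  total <- sum(sizes)
  if (total == 0L) { log_event(st, branch, "deletion", "skipped: empty genome", 0); return(chroms) }
  g <- sample.int(total, 1L)
  ci <- findInterval(g, cumsum(sizes), left.open = TRUE) + 1L
  pos <- g - c(0L, cumsum(sizes))[ci]
  chroms[[ci]] <- chroms[[ci]][-pos]
  log_event(st, branch, "deletion", sprintf("chrom %d rank %d", ci, pos), -1L)
  drop_empty_chroms(chroms)
}

apply_tandem_duplication <- function(chroms, st, branch) {
  sizes <- vapply(chroms, nrow, integer(1))
  total <- sum(sizes)
  if (total == 0L) { log_event(st, branch, "tandem_duplication", "skipped: empty genome", 0); return(chroms) }
  g <- sample.int(total, 1L)
  ci <- findInterval(g, cumsum(sizes), left.open = TRUE) + 1L
  pos <- g - c(0L, cumsum(sizes))[ci]
  copy_row <- copy(chroms[[ci]][pos])
  copy_row[, uid := new_uids(st, 1L)]
  n <- nrow(chroms[[ci]])
  chroms[[ci]] <- rbind(chroms[[ci]][1:pos], copy_row,
                        if (pos < n) chroms[[ci]][(pos + 1L):n])
  log_event(st, branch, "tandem_duplication", sprintf("chrom %d rank %d", ci, pos), 1L)
  chroms
}

apply_wgd <- function(chroms, st, branch, type, loss_rate, bias) {
  n_copies <- if (type == "triplication") 3L else 2L
  base <- rbindlist(chroms)
  n0 <- nrow(base)
  out <- lapply(chroms, function(ch) { ch <- copy(ch); ch[, subgenome := 1L]; ch })
  for (k in 2:n_copies) {
    copies <- lapply(chroms, function(ch) {
      ch <- copy(ch)
      ch[, uid := new_uids(st, .N)]
      ch[, subgenome := k]
      ch
    })
    out <- c(out, copies)
  }
  log_event(st, branch, paste0("wgd_", type),
            sprintf("%d chromosomes x%d, MF subgenome = %d", length(chroms), n_copies, n_copies),
            (n_copies - 1L) * n0)
  # biased fractionation: per duplicate set, each loss round removes one
  # surviving copy with probability loss_rate, hitting the highest-subgenome
  # (MF-most) surviving copy with probability `bias`; copies were made in the
  # same row order, so copy k of gene (ci0, r) sits at out[[ci0+(k-1)*n_chr]][r]
  n_chr <- length(chroms)
  lost <- 0L
  remove <- vector("list", length(out))
  for (ci0 in seq_len(n_chr)) {
    nrows <- nrow(chroms[[ci0]])
    if (nrows == 0L) next
    for (r in seq_len(nrows)) {
      surviving <- seq_len(n_copies)  # copy index k -> chromosome ci0 + (k-1)*n_chr
      for (round in seq_len(n_copies - 1L)) {
        if (length(surviving) < 2L) break
        if (runif(1) < loss_rate) {
          hit_mf <- runif(1) < bias
          victim <- if (hit_mf) max(surviving) else min(surviving)
          ci <- ci0 + (victim - 1L) * n_chr
          remove[[ci]] <- c(remove[[ci]], r)
          surviving <- setdiff(surviving, victim)
          lost <- lost + 1L
        }
      }
    }
  }
  for (ci in seq_along(out)) {
    if (length(remove[[ci]])) out[[ci]] <- out[[ci]][-remove[[ci]]]
  }
  if (lost > 0L) log_event(st, branch, "fractionation",
                           sprintf("%d duplicated copies lost (bias %.2f)", lost, bias), -lost)
  drop_empty_chroms(out)
}

evolve_branch <- function(chroms, st, branch, length, cfg) {
  for (w in cfg$wgd_events) {
    if (identical(w$branch, branch)) {
      loss <- if (is.null(w$loss_rate)) 0.5 else w$loss_rate
      chroms <- apply_wgd(chroms, st, branch, w$type, loss, cfg$fractionation_bias)
    }
  }
  counts <- vapply(cfg$rates, function(r) rpois(1L, r * length), integer(1))
  events <- rep(names(counts), counts)
  if (length(events)) events <- sample(events)
  for (ev in events) {
    chroms <- switch(ev,
      inversion = apply_inversion(chroms, st, branch),
      deletion = apply_deletion(chroms, st, branch),
      tandem_duplication = apply_tandem_duplication(chroms, st, branch),
      translocation = apply_translocation(chroms, st, branch),
      fusion = apply_fusion(chroms, st, branch),
      fission = apply_fission(chroms, st, branch))
  }
  chroms
}

#' Simulate a ground-truthed comparative-genomics dataset
#'
#' Evolves an ancestral genome along the configured species tree and emits
#' (i) a gene table for all extant species (with `protein_length`), (ii) a
#' synthetic HSP table in the layout produced by [read_blast_tabular()]
#' (both directions per homolog pair, plus spurious low-identity pairs), and
#' (iii) the ground truth: ancestor gene order, descent map with subgenome
#' labels, event ledger, and all true cross-species ortholog pairs.
#'
#' @param config a [simulation_config()].
#' @return list with `genes`, `hsps`, `query_lengths` (named vector) and
#'   `truth` (list: `ancestor`, `descent`, `ledger`, `true_orthologs`,
#'   `tree`, `config`).
#' @export
simulate_synteny_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tree <- ape::read.tree(text = config$species_tree)
  if (is.null(tree$node.label) || !all(nzchar(tree$node.label))) {
    tree$node.label <- paste0("N", seq_len(tree$Nnode))
  }
  label_of <- function(node) {
    if (node <= length(tree$tip.label)) tree$tip.label[node]
    else tree$node.label[node - length(tree$tip.label)]
  }
  st <- sim_state()

  # ancestor: genes distributed round-robin across chromosomes, then
  # contiguous blocks (chromosome sizes as equal as possible)
  G <- config$n_ancestral_genes
  C <- config$n_ancestral_chromosomes
  sizes <- diff(round(seq(0, G, length.out = C + 1L)))
  uids <- new_uids(st, G)
  bounds <- cumsum(c(0L, sizes))
  ancestor_chroms <- lapply(seq_len(C), function(i) {
    data.table(uid = uids[(bounds[i] + 1L):bounds[i + 1L]],
               anc_id = uids[(bounds[i] + 1L):bounds[i + 1L]],
               strand = 1L, subgenome = 1L)
  })
  ancestor <- rbindlist(lapply(seq_len(C), function(i) {
    data.table(chromosome = i, position = seq_len(sizes[i]) - 1L,
               anc_id = ancestor_chroms[[i]]$anc_id)
  }))
  protein_lengths <- sample(100:600, G, replace = TRUE)  # aa, indexed by anc_id

  # preorder traversal
  genomes <- list()
  recurse <- function(node, chroms) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (!length(kids)) {
      genomes[[label_of(node)]] <<- chroms
      return(invisible(NULL))
    }
    for (kid in kids) {
      len <- tree$edge.length[which(tree$edge[, 1] == node & tree$edge[, 2] == kid)]
      kc <- evolve_branch(lapply(chroms, copy), st, label_of(kid), len, config)
      recurse(kid, kc)
    }
  }
  root <- length(tree$tip.label) + 1L
  recurse(root, ancestor_chroms)

  # extant gene tables
  gene_rows <- rbindlist(lapply(names(genomes), function(sp) {
    chroms <- genomes[[sp]]
    rbindlist(lapply(seq_along(chroms), function(ci) {
      ch <- chroms[[ci]]
      n <- nrow(ch)
      starts <- (seq_len(n) - 1L) * 2000L + 1L
      plen <- protein_lengths[ch$anc_id]
      data.table(gene_id = paste0(sp, "_g", sprintf("%06d", ch$uid)),
                 species = sp, chromosome = paste0("chr", ci),
                 start = starts, end = starts + 3L * plen - 1L,
                 strand = ifelse(ch$strand > 0, "+", "-"),
                 protein_length = plen, anc_id = ch$anc_id,
                 subgenome = ch$subgenome)
    }))
  }))
  genes <- assign_gene_ranks(gene_rows[, .(gene_id, species, chromosome, start,
                                           end, strand, protein_length)])
  descent <- merge(gene_rows[, .(gene_id, species, anc_id, subgenome)],
                   genes[, .(gene_id, chromosome, rank)], by = "gene_id")
  setorder(descent, anc_id, species, gene_id)

  query_lengths <- setNames(as.numeric(genes$protein_length), genes$gene_id)

  # homolog pairs and synthetic HSPs
  dmat <- ape::cophenetic.phylo(tree)
  dx <- merge(descent[, .(anc_id, gene_id, species)],
              descent[, .(anc_id, gene_id, species)],
              by = "anc_id", allow.cartesian = TRUE, suffixes = c("_1", "_2"))
  dx <- dx[gene_id_1 < gene_id_2]
  hsps <- data.table()
  true_orth <- data.table(gene_a = character(0), gene_b = character(0))
  if (nrow(dx)) {
    d <- ifelse(dx$species_1 == dx$species_2, 0,
                dmat[cbind(dx$species_1, dx$species_2)])
    identity <- pmin(100, pmax(config$identity_floor,
                               100 - config$identity_decay * d +
                                 rnorm(nrow(dx), 0, config$noise_sd)))
    plen <- protein_lengths[dx$anc_id]
    hsps <- make_hsp_rows(dx$gene_id_1, dx$gene_id_2, plen, identity,
                          config$multi_hsp)
    true_orth <- dx[species_1 != species_2,
                    .(gene_a = pmin(gene_id_1, gene_id_2),
                      gene_b = pmax(gene_id_1, gene_id_2))]
    setorder(true_orth, gene_a, gene_b)
  }

  # spurious low-identity pairs
  n_spur <- rpois(1L, config$spurious_rate * nrow(genes))
  if (n_spur > 0L && nrow(genes) >= 2L) {
    i <- sample.int(nrow(genes), n_spur, replace = TRUE)
    j <- sample.int(nrow(genes), n_spur, replace = TRUE)
    keep <- i != j
    sp_dt <- data.table(g1 = genes$gene_id[i[keep]], g2 = genes$gene_id[j[keep]])
    anc_of <- setNames(gene_rows$anc_id, gene_rows$gene_id)
    sp_dt <- sp_dt[anc_of[g1] != anc_of[g2]]
    if (nrow(sp_dt)) {
      id_sp <- runif(nrow(sp_dt), config$identity_floor, 40)
      l1 <- query_lengths[sp_dt$g1]; l2 <- query_lengths[sp_dt$g2]
      L <- pmax(10L, round(runif(nrow(sp_dt), 0.2, 0.5) * pmin(l1, l2)))
      nid <- pmin(L, round(id_sp * L / 100))
      spur <- data.table(query_id = sp_dt$g1, subject_id = sp_dt$g2,
                         hsp_length = as.integer(L), n_identities = as.integer(nid),
                         query_start = 1L, query_end = as.integer(L),
                         subject_start = 1L, subject_end = as.integer(L),
                         score = round(2 * nid + 10, 1))
      hsps <- rbind(hsps, spur)
    }
  }
  setorder(hsps, query_id, subject_id, query_start)

  ledger <- if (length(st$ledger)) rbindlist(st$ledger) else
    data.table(branch = character(0), event = character(0),
               detail = character(0), delta_genes = integer(0))

  list(genes = genes[], hsps = hsps[], query_lengths = query_lengths,
       truth = list(ancestor = ancestor[], descent = descent[],
                    ledger = ledger[], true_orthologs = true_orth[],
                    tree = tree, config = config))
}

# symmetric HSP rows (both BLAST directions) for homolog pairs
make_hsp_rows <- function(g1, g2, plen, identity, multi_hsp) {
  n <- length(g1)
  mk <- function(q, s, L, nid, qs, qe) {
    data.table(query_id = q, subject_id = s, hsp_length = as.integer(L),
               n_identities = as.integer(nid), query_start = as.integer(qs),
               query_end = as.integer(qe), subject_start = as.integer(qs),
               subject_end = as.integer(qe), score = round(2 * nid + 10, 1))
  }
  if (!multi_hsp) {
    nid <- pmin(plen, round(identity * plen / 100))
    one <- mk(g1, g2, plen, nid, 1L, plen)
    two <- mk(g2, g1, plen, nid, 1L, plen)
    return(rbind(one, two))
  }
  rows <- vector("list", n)
  k <- sample(2:4, n, replace = TRUE)
  for (i in seq_len(n)) {
    cuts <- sort(sample.int(plen[i] - 1L, k[i] - 1L))
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, plen[i])
    L <- ends - starts + 1L
    nid <- pmin(L, round(identity[i] * L / 100))
    rows[[i]] <- rbind(mk(g1[i], g2[i], L, nid, starts, ends),
                       mk(g2[i], g1[i], L, nid, starts, ends))
  }
  rbindlist(rows)
}

#' Write a simulated dataset to disk in the pipeline's input dialects
#'
#' Emits `genes.tsv` (the TSV gene-table dialect, with `protein_length`) and
#' `blast.tsv` (BLAST outfmt-6-with-nident layout readable by
#' [read_blast_tabular()]), plus the ground-truth tables (`truth_*.tsv`).
#'
#' @param sim output of [simulate_synteny_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(sim$genes, file.path(dir, "genes.tsv"), sep = "\t")
  h <- sim$hsps
  pident <- round(100 * h$n_identities / h$hsp_length, 2)
  out6 <- data.table(h$query_id, h$subject_id, pident, h$hsp_length,
                     h$hsp_length - h$n_identities, 0L,
                     h$query_start, h$query_end, h$subject_start,
                     h$subject_end, 1e-10, h$score, h$n_identities)
  fwrite(out6, file.path(dir, "blast.tsv"), sep = "\t", col.names = FALSE)
  fwrite(sim$truth$ancestor, file.path(dir, "truth_ancestor.tsv"), sep = "\t")
  fwrite(sim$truth$descent, file.path(dir, "truth_descent.tsv"), sep = "\t")
  fwrite(sim$truth$ledger, file.path(dir, "truth_ledger.tsv"), sep = "\t")
  fwrite(sim$truth$true_orthologs, file.path(dir, "truth_orthologs.tsv"), sep = "\t")
  invisible(dir)
}
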