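# Step 4 — merge synteny blocks across species pairs into conserved
# ancestral regions (CARs, protochromosomes), order protogenes, back-fill
# conserved genes beyond one-to-one relationships, classify core/dispensable
# protogenes and LF/MF post-WGD compartments.
#
# Protogenes (PGs) are connected components of the anchor-gene graph (genes
# linked by ortholog anchors across all species pairs, merged transitively).
# CARs are connected components of the block graph, where two blocks are
# linked when they share at least one protogene: this identifies the
# per-chromosome segments of different blocks by shared gene content rather
# than by span overlap, so a segment translocated into a chromosome does not
# fuse the host chromosome's CAR with its own.

#' Merge synteny blocks into CARs and protogenes
#'
#' @param blocks a `synteny_blocks` object covering one or more species
#'   pairs (see [chain_all_blocks()]).
#' @return An `ancestral_karyotype` object: list with
#'   \describe{
#'     \item{cars}{data.table `car_id`, `n_pgs`, `n_blocks`}
#'     \item{car_blocks}{data.table `car_id`, `block_id`}
#'     \item{protogenes}{data.table `pg_id`, `car_id`, `ancestral_rank`
#'       (`NA` until [order_protogenes()]), `status` (`NA` until
#'       [classify_protogenes()])}
#'     \item{members}{data.table `pg_id`, `species`, `gene_id`, `backfilled`}
#'     \item{segments}{per-CAR derived segments: `car_id`, `species`,
#'       `chromosome`, `rank_lo`, `rank_hi`}
#'     \item{species}{species seen among anchors}
#'   }
#' @export
group_blocks_into_cars <- function(blocks) {
  stopifnot(inherits(blocks, "synteny_blocks"))
  anc <- blocks$anchors[!is.na(block_id)]
  if (nrow(anc) == 0L) stop("no synteny blocks to merge")

  # protogenes: components of the gene graph under anchor edges
  g <- igraph::graph_from_data_frame(anc[, .(gene_a, gene_b)], directed = FALSE)
  memb <- igraph::components(g)$membership
  pg_of_gene <- split(names(memb), memb)
  # deterministic pg ids: order components by smallest member gene id
  ord <- order(vapply(pg_of_gene, min, character(1)))
  pg_of_gene <- pg_of_gene[ord]
  pg_ids <- sprintf("PG%06d", seq_along(pg_of_gene))
  gene2pg <- setNames(rep(pg_ids, lengths(pg_of_gene)), unlist(pg_of_gene))

  sp_of_gene <- c(setNames(anc$species_a, anc$gene_a),
                  setNames(anc$species_b, anc$gene_b))
  sp_of_gene <- sp_of_gene[!duplicated(names(sp_of_gene))]
  members <- data.table(gene_id = names(gene2pg),
                        pg_id = unname(gene2pg))
  members[, species := as.character(sp_of_gene[gene_id])]
  members[, backfilled := FALSE]
  setcolorder(members, c("pg_id", "species", "gene_id", "backfilled"))
  setorder(members, pg_id, species, gene_id)

  # block graph: blocks sharing >= 1 protogene are linked
  bp <- unique(rbind(anc[, .(block_id, pg_id = gene2pg[gene_a])],
                     anc[, .(block_id, pg_id = gene2pg[gene_b])]))
  setorder(bp, pg_id, block_id)
  edges <- bp[, if (.N > 1L) data.table(from = block_id[-.N], to = block_id[-1L]),
              by = pg_id]
  edges <- if (nrow(edges)) unique(edges[, .(from, to)]) else
    data.table(from = character(0), to = character(0))
  bg <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = unique(bp$block_id))
  bmemb <- igraph::components(bg)$membership
  car_of_block_raw <- split(names(bmemb), bmemb)
  # deterministic CAR ids: by size (pg count) desc, then smallest block id
  car_npg <- vapply(car_of_block_raw, function(bs) {
    length(unique(bp[block_id %in% bs, pg_id]))
  }, integer(1))
  car_min <- vapply(car_of_block_raw, min, character(1))
  ord <- order(-car_npg, car_min)
  car_of_block_raw <- car_of_block_raw[ord]
  car_ids <- sprintf("CAR%03d", seq_along(car_of_block_raw))
  block2car <- setNames(rep(car_ids, lengths(car_of_block_raw)),
                        unlist(car_of_block_raw))

  car_blocks <- data.table(block_id = names(block2car),
                           car_id = unname(block2car))
  setcolorder(car_blocks, c("car_id", "block_id"))
  setorder(car_blocks, car_id, block_id)

  # each pg's blocks all share it, hence lie in one CAR
  pg_car <- unique(bp[, .(pg_id, car_id = block2car[block_id])])
  pg_car <- unique(pg_car)
  stopifnot(!anyDuplicated(pg_car$pg_id))
  protogenes <- data.table(pg_id = pg_ids)
  protogenes <- merge(protogenes, pg_car, by = "pg_id", all.x = TRUE)
  protogenes[, `:=`(ancestral_rank = NA_integer_, status = NA_character_)]
  setorder(protogenes, pg_id)

  # derived segments: per CAR, species chromosome spans of its blocks
  blk <- merge(blocks$blocks, car_blocks, by = "block_id")
  segments <- rbind(
    blk[, .(car_id, species = species_a, chromosome = chr_a,
            rank_lo = span_a_lo, rank_hi = span_a_hi)],
    blk[, .(car_id, species = species_b, chromosome = chr_b,
            rank_lo = span_b_lo, rank_hi = span_b_hi)])
  segments <- segments[, .(rank_lo = min(rank_lo), rank_hi = max(rank_hi)),
                       by = .(car_id, species, chromosome)]
  setorder(segments, car_id, species, chromosome)

  cars <- merge(
    protogenes[!is.na(car_id), .(n_pgs = .N), by = car_id],
    car_blocks[, .(n_blocks = .N), by = car_id], by = "car_id")
  setorder(cars, car_id)

  out <- list(cars = cars[], car_blocks = car_blocks[],
              protogenes = protogenes[], members = members[],
              segments = segments[],
              species = sort(unique(c(anc$species_a, anc$species_b))))
  class(out) <- "ancestral_karyotype"
  out
}

#' Order protogenes within each CAR
#'
#' Every protogene gets a per-species normalized position: its member genes
#' of species s belonging to the CAR are located among that species' CAR
#' genes ordered by (chromosome, rank), scaled to \[0, 1\]. The sort key is
#' the position in the `reference` species when the protogene has a member
#' there, otherwise (or with `reference = "median"`) the median of the
#' normalized positions across species bearing it. Ties break by `pg_id`.
#' `ancestral_rank` is assigned 0-based along each CAR.
#'
#' @param karyotype an `ancestral_karyotype`.
#' @param genes gene table with ranks.
#' @param reference species name, or `"median"` for the median-rank rule.
#' @return The karyotype with `ancestral_rank` filled in.
#' @export
order_protogenes <- function(karyotype, genes, reference = "median") {
  stopifnot(inherits(karyotype, "ancestral_karyotype"))
  genes <- as.data.table(genes)
  mem <- merge(karyotype$members[backfilled == FALSE],
               karyotype$protogenes[, .(pg_id, car_id)], by = "pg_id")
  mem <- mem[!is.na(car_id)]
  mem <- merge(mem, genes[, .(gene_id, chromosome, rank)], by = "gene_id")
  if (reference != "median") {
    if (!reference %in% karyotype$species) {
      stop("reference species '", reference, "' absent from the karyotype")
    }
    by_car_sp <- unique(mem[, .(car_id, species)])
    miss <- setdiff(unique(mem$car_id), by_car_sp[species == reference, car_id])
    if (length(miss)) {
      stop("reference species '", reference, "' absent from CAR(s): ",
           paste(head(miss, 5), collapse = ", "))
    }
  }
  # normalized position of each member gene within (car, species)
  setorder(mem, car_id, species, chromosome, rank, gene_id)
  mem[, norm_pos := if (.N == 1L) 0.5 else (seq_len(.N) - 1) / (.N - 1),
      by = .(car_id, species)]
  pg_pos <- mem[, .(pos = mean(norm_pos)), by = .(car_id, species, pg_id)]
  keys <- pg_pos[, {
    if (reference != "median" && reference %in% species) {
      ref <- pos[species == reference][1]
      .(pg_key = if (!is.na(ref)) ref else median(pos))
    } else {
      .(pg_key = median(pos))
    }
  }, by = .(car_id, pg_id)]
  setorder(keys, car_id, pg_key, pg_id)
  keys[, ancestral_rank := seq_len(.N) - 1L, by = car_id]
  pg <- copy(karyotype$protogenes)
  pg[, ancestral_rank := NULL]
  pg <- merge(pg, keys[, .(pg_id, ancestral_rank)], by = "pg_id", all.x = TRUE)
  setcolorder(pg, c("pg_id", "car_id", "ancestral_rank", "status"))
  setorder(pg, pg_id)
  karyotype$protogenes <- pg[]
  karyotype
}

#' Back-fill conserved genes beyond one-to-one relationships
#'
#' Step-1 conserved genes that ended up in no protogene (extra WGD copies,
#' dispersed paralogs, tandem array members) are attached to an existing
#' protogene when they are conserved with at least one of its members. A
#' gene attaches to exactly one protogene — the one backing the
#' highest-scoring conserved pair (ties: lowest `pg_id`). Attachment flags
#' the member `backfilled = TRUE` and never alters CAR structure, protogene
#' count or ordering.
#'
#' @param karyotype an `ancestral_karyotype`.
#' @param step1_pairs conserved pairs from [filter_conserved_pairs()] (with
#'   species columns).
#' @return The karyotype with extended member lists.
#' @export
backfill_conserved_genes <- function(karyotype, step1_pairs) {
  stopifnot(inherits(karyotype, "ancestral_karyotype"))
  pairs <- as.data.table(step1_pairs)
  if (nrow(pairs) == 0L) return(karyotype)
  assigned <- karyotype$members$gene_id
  gene2pg <- setNames(karyotype$members$pg_id, assigned)
  cand <- rbind(
    pairs[gene_a %in% assigned & !(gene_b %in% assigned),
          .(gene = gene_b, sp = species_b, pg_id = gene2pg[gene_a], score)],
    pairs[gene_b %in% assigned & !(gene_a %in% assigned),
          .(gene = gene_a, sp = species_a, pg_id = gene2pg[gene_b], score)])
  if (nrow(cand) == 0L) return(karyotype)
  cand <- cand[, .(score = max(score)), by = .(gene, sp, pg_id)]
  setorder(cand, gene, -score, pg_id)
  best <- cand[, .SD[1L], by = gene]
  add <- best[, .(pg_id, species = sp, gene_id = gene, backfilled = TRUE)]
  karyotype$members <- rbind(karyotype$members, add)
  setorder(karyotype$members, pg_id, species, gene_id)
  karyotype
}

#' Classify protogenes as core or dispensable
#'
#' A protogene is *core* when it has members in every investigated species,
#' *dispensable* when present in a subset of at least two. A protogene with
#' members in fewer than two species violates the dispensable-protogene
#' definition and is a hard error.
#'
#' @param karyotype an `ancestral_karyotype`.
#' @param species character vector of investigated species (default: all
#'   species seen in the karyotype).
#' @return The karyotype with `status` filled in.
#' @export
classify_protogenes <- function(karyotype, species = karyotype$species) {
  stopifnot(inherits(karyotype, "ancestral_karyotype"))
  nsp <- karyotype$members[, .(n_sp = uniqueN(species)), by = pg_id]
  bad <- nsp[n_sp < 2L, pg_id]
  if (length(bad)) {
    stop("protogene(s) with members in < 2 species: ",
         paste(head(bad, 10), collapse = ", "))
  }
  sp_set <- species
  full <- karyotype$members[, .(all_sp = uniqueN(species[species %in% sp_set]) == length(sp_set)),
                            by = pg_id]
  st <- setNames(ifelse(full$all_sp, "core", "dispensable"), full$pg_id)
  karyotype$protogenes[, status := as.character(st[pg_id])]
  karyotype
}

#' Label least/most-fractionated (LF/MF) compartments
#'
#' For each pair of descendant segments deriving from one ancestral region
#' through a WGD, counts the protogenes retaining at least one member gene
#' in each segment; the segment retaining more is labelled LF (least
#' fractionated, dominant), the other MF (most fractionated, sensitive).
#' Ties are labelled by lexicographic segment id with a tie flag.
#'
#' @param karyotype an `ancestral_karyotype` (members populated).
#' @param segment_pairs data.table with one row per duplicated segment pair:
#'   `pair_id`, `segment_id_1`, `species_1`, `chromosome_1`, `lo_1`, `hi_1`,
#'   `segment_id_2`, `species_2`, `chromosome_2`, `lo_2`, `hi_2` (rank
#'   intervals, inclusive).
#' @param genes gene table with ranks.
#' @return data.table: `pair_id`, `lf_segment`, `mf_segment`, `n_lf`,
#'   `n_mf`, `tie`.
#' @export
classify_fractionation <- function(karyotype, segment_pairs, genes) {
  stopifnot(inherits(karyotype, "ancestral_karyotype"))
  sp <- as.data.table(segment_pairs)
  genes <- as.data.table(genes)
  mem <- merge(karyotype$members, genes[, .(gene_id, species, chromosome, rank)],
               by = c("gene_id", "species"))
  count_pgs <- function(spc, chrom, lo, hi) {
    mem[species == spc & chromosome == chrom & rank >= lo & rank <= hi,
        uniqueN(pg_id)]
  }
  res <- lapply(seq_len(nrow(sp)), function(i) {
    n1 <- count_pgs(sp$species_1[i], sp$chromosome_1[i], sp$lo_1[i], sp$hi_1[i])
    n2 <- count_pgs(sp$species_2[i], sp$chromosome_2[i], sp$lo_2[i], sp$hi_2[i])
    id1 <- sp$segment_id_1[i]; id2 <- sp$segment_id_2[i]
    tie <- n1 == n2
    if (n1 > n2 || (tie && id1 < id2)) {
      data.table(pair_id = sp$pair_id[i], lf_segment = id1, mf_segment = id2,
                 n_lf = n1, n_mf = n2, tie = tie)
    } else {
      data.table(pair_id = sp$pair_id[i], lf_segment = id2, mf_segment = id1,
                 n_lf = n2, n_mf = n1, tie = tie)
    }
  })
  rbindlist(res)
}

# internal audit used by tests: CAR disjointness and pg uniqueness
audit_karyotype <- function(karyotype) {
  stopifnot(inherits(karyotype, "ancestral_karyotype"))
  stopifnot(!anyDuplicated(karyotype$protogenes$pg_id))
  stopifnot(!anyDuplicated(karyotype$members[backfilled == FALSE, gene_id]))
  pgcar <- karyotype$protogenes[!is.na(car_id)]
  stopifnot(!anyDuplicated(pgcar$pg_id))
  invisible(TRUE)
}

#' @export
print.ancestral_karyotype <- function(x, ...) {
  cat("<ancestral_karyotype> ", nrow(x$cars), " CAR(s), ",
      nrow(x$protogenes), " protogene(s), ",
      nrow(x$members), " member gene(s), species: ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  invisible(x)
}
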