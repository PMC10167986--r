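# Step 2 — reduce conserved pairs to one-to-one (or 1-to-n under WGD)
# ortholog relationships: collapse tandem-duplicate arrays to a single
# representative, then apply a generalized reciprocal-best-hit rule.

#' Collapse tandem-duplicate arrays
#'
#' Within each species, genes that are conserved with each other (a
#' within-species pair passing the Step-1 thresholds), lie on the same
#' chromosome and are separated by at most `window` gene ranks form tandem
#' arrays (transitively). Each array is collapsed to one representative —
#' the member with the highest summed score over its cross-species conserved
#' pairs; ties go to the lowest rank, then the lexicographically smallest
#' gene id. All pairs involving non-representative array members are
#' dropped.
#'
#' @param pairs conserved pairs from [filter_conserved_pairs()], with species
#'   columns populated (pass `genes` there) and including within-species
#'   pairs.
#' @param genes gene table with ranks (see [assign_gene_ranks()]).
#' @param window maximum rank separation (in genes) joining an array.
#' @return list with `pairs` (filtered conserved pairs) and `report`
#'   (data.table: `species`, `chromosome`, `array_id`, `gene_id`, `rank`,
#'   `representative`, `is_representative`).
#' @export
collapse_tandem_duplicates <- function(pairs, genes, window = 5L) {
  pairs <- as.data.table(pairs)
  genes <- as.data.table(genes)
  empty_report <- data.table(species = character(0), chromosome = character(0),
                             array_id = integer(0), gene_id = character(0),
                             rank = integer(0), representative = character(0),
                             is_representative = logical(0))
  if (nrow(pairs) == 0L) return(list(pairs = pairs, report = empty_report))
  if (anyNA(pairs$species_a) || anyNA(pairs$species_b)) {
    stop("pairs must carry species annotations (pass `genes` to filter_conserved_pairs)")
  }
  pos <- setNames(genes$rank, genes$gene_id)
  chr <- setNames(paste(genes$species, genes$chromosome, sep = "\r"), genes$gene_id)

  intra <- pairs[species_a == species_b]
  same_chr <- intra[chr[gene_a] == chr[gene_b] &
                      abs(pos[gene_a] - pos[gene_b]) <= window]
  if (nrow(same_chr) == 0L) return(list(pairs = pairs, report = empty_report))

  g <- igraph::graph_from_data_frame(same_chr[, .(gene_a, gene_b)], directed = FALSE)
  comp <- igraph::components(g)
  arrays <- split(names(comp$membership), comp$membership)

  # summed cross-species score per gene
  inter <- pairs[species_a != species_b]
  sc <- rbind(inter[, .(gene = gene_a, score)], inter[, .(gene = gene_b, score)])
  sc <- sc[, .(total = sum(score)), by = gene]
  total_score <- setNames(sc$total, sc$gene)

  rep_rows <- lapply(seq_along(arrays), function(i) {
    members <- sort(arrays[[i]])
    ts <- total_score[members]
    ts[is.na(ts)] <- 0
    ord <- order(-ts, pos[members], members)
    members <- members[ord]
    data.table(species = genes$species[match(members, genes$gene_id)][1],
               chromosome = genes$chromosome[match(members, genes$gene_id)][1],
               array_id = i, gene_id = members,
               rank = as.integer(pos[members]),
               representative = members[1],
               is_representative = members == members[1])
  })
  report <- rbindlist(rep_rows)
  drop <- report$gene_id[!report$is_representative]
  out <- pairs[!(gene_a %in% drop) & !(gene_b %in% drop)]
  list(pairs = out[], report = report[])
}

#' Build a species-pair multiplicity map
#'
#' Directional expected copy ratios from known WGD history: an entry
#' `(species_a, species_b, n)` means each gene of `species_a` may keep up to
#' `n` partners in `species_b` (n-1 extra copies from n-ploidization on the
#' `species_b` lineage). Unlisted ordered pairs default to 1.
#'
#' @param species_a,species_b,n equal-length vectors.
#' @return data.table multiplicity map.
#' @export
multiplicity_map <- function(species_a = character(0),
                             species_b = character(0),
                             n = integer(0)) {
  stopifnot(all(n >= 1))
  data.table(species_a = as.character(species_a),
             species_b = as.character(species_b), n = as.integer(n))
}

mult_lookup <- function(mult, sa, sb) {
  if (is.null(mult) || nrow(mult) == 0L) return(1L)
  hit <- mult[species_a == sa & species_b == sb]
  if (nrow(hit)) hit$n[1] else 1L
}

#' Assign orthologs by generalized reciprocal best hits
#'
#' For each unordered species pair (A, B) with directional multiplicities
#' `n_ab` (partners a gene of A may keep in B) and `n_ba`, a conserved pair
#' (a, b) is retained iff b is among a's top-`n_ab` partners in B *and* a is
#' among b's top-`n_ba` partners in A, ranking by score (descending) with
#' lexicographic gene-id tie-break. With both multiplicities 1 this is
#' classical reciprocal best hit. Within-species pairs are ignored; genes
#' retaining no partner (species-specific after collapse) simply drop out.
#'
#' @param pairs conserved pairs (tandem-collapsed), species columns set.
#' @param mult multiplicity map from [multiplicity_map()], or `NULL` (all 1).
#' @return data.table ortholog table: `gene_a`, `gene_b`, `species_a`,
#'   `species_b`, `score`, `CIP`, `CALP`.
#' @export
assign_orthologs <- function(pairs, mult = NULL) {
  pairs <- as.data.table(pairs)
  empty <- data.table(gene_a = character(0), gene_b = character(0),
                      species_a = character(0), species_b = character(0),
                      score = numeric(0), CIP = numeric(0), CALP = numeric(0))
  if (nrow(pairs) == 0L) return(empty)
  if (anyNA(pairs$species_a) || anyNA(pairs$species_b)) {
    stop("pairs must carry species annotations")
  }
  inter <- pairs[species_a != species_b]
  if (nrow(inter) == 0L) return(empty)

  # directed view: one row per (gene, partner) in each direction
  directed <- rbind(
    inter[, .(gene = gene_a, sp = species_a, partner = gene_b, sp_p = species_b,
              score, CIP, CALP)],
    inter[, .(gene = gene_b, sp = species_b, partner = gene_a, sp_p = species_a,
              score, CIP, CALP)])
  setorder(directed, gene, sp_p, -score, partner)
  directed[, rnk := seq_len(.N), by = .(gene, sp_p)]

  # per-edge allowance from the multiplicity of (sp -> sp_p)
  sp_pairs <- unique(directed[, .(sp, sp_p)])
  sp_pairs[, n := vapply(seq_len(.N), function(i) mult_lookup(mult, sp[i], sp_p[i]),
                         integer(1))]
  directed <- merge(directed, sp_pairs, by = c("sp", "sp_p"))
  directed[, keep := rnk <= n]

  key_fwd <- directed[, paste(gene, partner, sep = "\r")]
  kept <- setNames(directed$keep, key_fwd)
  fwd <- inter[, paste(gene_a, gene_b, sep = "\r")]
  rev <- inter[, paste(gene_b, gene_a, sep = "\r")]
  retained <- inter[kept[fwd] & kept[rev]]
  out <- retained[, .(gene_a, gene_b, species_a, species_b, score, CIP, CALP)]
  setorder(out, species_a, species_b, gene_a, gene_b)
  out[]
}
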