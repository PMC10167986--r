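# Step 3 — chain ortholog anchors into synteny blocks per chromosome pair.
#
# Within one chromosome-to-chromosome combination, anchors are grouped by
# connected components of the gap-adjacency graph: two anchors are adjacent
# when they differ by <= max_gap ranks on both genomes. Components with at
# least min_anchors anchors (default 6: blocks must share *more than five*
# orthologous genes) become synteny blocks. max_gap = Inf reproduces the
# coarse chromosome-pair rule (every shared ortholog of a chromosome pair in
# one block).

#' Join ortholog rows to gene positions, yielding anchors
#'
#' @param orthologs ortholog table from [assign_orthologs()].
#' @param genes gene table with ranks.
#' @return data.table of anchors: `gene_a`, `gene_b`, `species_a`,
#'   `species_b`, `chr_a`, `chr_b`, `rank_a`, `rank_b`.
#' @export
build_anchors <- function(orthologs, genes) {
  orthologs <- as.data.table(orthologs)
  genes <- as.data.table(genes)
  if (nrow(orthologs) == 0L) {
    return(data.table(gene_a = character(0), gene_b = character(0),
                      species_a = character(0), species_b = character(0),
                      chr_a = character(0), chr_b = character(0),
                      rank_a = integer(0), rank_b = integer(0)))
  }
  missing <- setdiff(unique(c(orthologs$gene_a, orthologs$gene_b)), genes$gene_id)
  if (length(missing)) {
    stop("ortholog gene(s) missing from gene table: ",
         paste(head(missing, 10), collapse = ", "))
  }
  idx <- match(orthologs$gene_a, genes$gene_id)
  jdx <- match(orthologs$gene_b, genes$gene_id)
  out <- orthologs[, .(gene_a, gene_b, species_a, species_b)]
  out[, `:=`(chr_a = genes$chromosome[idx], chr_b = genes$chromosome[jdx],
             rank_a = genes$rank[idx], rank_b = genes$rank[jdx])]
  out[]
}

# connected components of the gap-adjacency graph for one chromosome pair;
# returns an integer membership vector
chain_components <- function(rank_a, rank_b, max_gap) {
  n <- length(rank_a)
  if (n == 1L || is.infinite(max_gap)) return(rep(1L, n))
  a <- data.table(i = seq_len(n), ra = as.numeric(rank_a), rb = as.numeric(rank_b))
  b <- a[, .(j = i, ra_lo = ra - max_gap, ra_hi = ra + max_gap,
             rb_lo = rb - max_gap, rb_hi = rb + max_gap)]
  edges <- a[b, on = .(ra >= ra_lo, ra <= ra_hi, rb >= rb_lo, rb <= rb_hi),
             .(i = x.i, j = j), nomatch = NULL]
  edges <- edges[i < j]
  if (nrow(edges) == 0L) return(seq_len(n))
  g <- igraph::graph_from_edgelist(as.matrix(edges[, .(i, j)]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

block_orientation <- function(rank_a, rank_b) {
  if (length(rank_a) < 2L) return("mixed")
  rho <- suppressWarnings(cor(rank_a, rank_b, method = "spearman"))
  if (is.na(rho)) return("mixed")
  if (rho >= 0.5) "same" else if (rho <= -0.5) "inverted" else "mixed"
}

#' Chain anchors of one species pair into synteny blocks
#'
#' @param anchors anchors from [build_anchors()], one species pair only.
#' @param min_anchors minimum orthologs per block (default 6, i.e. strictly
#'   more than five shared orthologous genes).
#' @param max_gap maximum rank gap joining two anchors on both genomes;
#'   `Inf` disables gap splitting (one block per chromosome pair).
#' @return A `synteny_blocks` object: list with `anchors` (input rows plus
#'   `block_id`, `NA` for anchors in no block) and `blocks` (per-block
#'   summary: id, chromosomes, `n_anchors`, `orientation`, rank spans).
#' @export
chain_blocks <- function(anchors, min_anchors = 6L, max_gap = 15) {
  anchors <- as.data.table(anchors)
  sp <- unique(anchors[, .(species_a, species_b)])
  if (nrow(sp) > 1L) {
    stop("anchors must come from a single species pair; got ",
         paste(sp[, paste(species_a, species_b, sep = "-")], collapse = ", "))
  }
  anchors <- copy(anchors)
  anchors[, block_id := NA_character_]
  blocks_empty <- data.table(block_id = character(0), species_a = character(0),
                             species_b = character(0), chr_a = character(0),
                             chr_b = character(0), n_anchors = integer(0),
                             orientation = character(0),
                             span_a_lo = integer(0), span_a_hi = integer(0),
                             span_b_lo = integer(0), span_b_hi = integer(0))
  out <- list(anchors = anchors, blocks = blocks_empty)
  class(out) <- "synteny_blocks"
  if (nrow(anchors) == 0L) return(out)

  setorder(anchors, chr_a, chr_b, rank_a, rank_b, gene_a)
  anchors[, chain := chain_components(rank_a, rank_b, max_gap), by = .(chr_a, chr_b)]
  anchors[, n_anchors := .N, by = .(chr_a, chr_b, chain)]
  anchors[n_anchors >= min_anchors,
          block_id := paste0(species_a, ":", chr_a, "|", species_b, ":", chr_b,
                             "#", as.integer(factor(chain, levels = unique(chain)))),
          by = .(chr_a, chr_b)]
  blocks <- if (any(!is.na(anchors$block_id))) {
    anchors[!is.na(block_id),
            .(species_a = species_a[1], species_b = species_b[1],
              chr_a = chr_a[1], chr_b = chr_b[1], n_anchors = .N,
              orientation = block_orientation(rank_a, rank_b),
              span_a_lo = min(rank_a), span_a_hi = max(rank_a),
              span_b_lo = min(rank_b), span_b_hi = max(rank_b)),
            by = block_id]
  } else blocks_empty
  anchors[, c("chain", "n_anchors") := NULL]
  out$anchors <- anchors[]
  out$blocks <- blocks[]
  out
}

#' Chain anchors of any number of species pairs
#'
#' Convenience wrapper applying [chain_blocks()] to each species pair and
#' concatenating the results (block ids embed the species pair, so they stay
#' globally unique).
#'
#' @inheritParams chain_blocks
#' @return A combined `synteny_blocks` object.
#' @export
chain_all_blocks <- function(anchors, min_anchors = 6L, max_gap = 15) {
  anchors <- as.data.table(anchors)
  parts <- split(anchors, by = c("species_a", "species_b"), drop = TRUE)
  res <- lapply(parts, chain_blocks, min_anchors = min_anchors, max_gap = max_gap)
  out <- list(anchors = rbindlist(lapply(res, `[[`, "anchors")),
              blocks = rbindlist(lapply(res, `[[`, "blocks")))
  if (nrow(out$anchors) == 0L) return(chain_blocks(anchors, min_anchors, max_gap))
  class(out) <- "synteny_blocks"
  out
}

#' Summary statistics for synteny blocks
#'
#' @param blocks a `synteny_blocks` object.
#' @return list with `per_block` (anchor count, spans, orientation, anchor
#'   density = n_anchors / span length on genome A) and
#'   `per_chromosome_pair` (block counts).
#' @export
block_statistics <- function(blocks) {
  stopifnot(inherits(blocks, "synteny_blocks"))
  per_block <- copy(blocks$blocks)
  if (nrow(per_block)) {
    per_block[, density_a := n_anchors / (span_a_hi - span_a_lo + 1)]
    per_block[, density_b := n_anchors / (span_b_hi - span_b_lo + 1)]
  } else {
    per_block[, `:=`(density_a = numeric(0), density_b = numeric(0))]
  }
  per_pair <- per_block[, .(n_blocks = .N, n_anchors = sum(n_anchors)),
                        by = .(species_a, species_b, chr_a, chr_b)]
  list(per_block = per_block[], per_chromosome_pair = per_pair[])
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("<synteny_blocks> ", nrow(x$blocks), " block(s), ",
      sum(!is.na(x$anchors$block_id)), "/", nrow(x$anchors),
      " anchors assigned\n", sep = "")
  invisible(x)
}
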