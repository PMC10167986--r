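# Step 1 — conserved-gene detection by cumulative identity percentage (CIP)
# and cumulative alignment length percentage (CALP).
#
# For a (query, subject) gene pair with HSPs h = 1..k:
#   AL   = sum of HSP lengths (no overlap trimming)
#   CIP  = 100 * (sum of identities over HSPs) / AL
#   CALP = 100 * AL / query_length
# CALP may exceed 100 when HSPs overlap on the query; this is accepted (the
# method defines AL as a plain sum) and surfaces in the output for auditing.

#' Aggregate HSPs into per-gene-pair alignment summaries
#'
#' Collapses the one-row-per-HSP BLAST table into one row per directed
#' `(query_id, subject_id)` pair, computing the cumulative aligned length
#' `AL`, total identities, `CIP = 100 * identities / AL`,
#' `CALP = 100 * AL / query_length`, and the maximum HSP score (used later
#' for ranking).
#'
#' @param hsps HSP table from [read_blast_tabular()] (or the simulator).
#' @param query_lengths named numeric vector (gene_id -> protein length in
#'   aa), or a data.frame with columns `gene_id`, `length`.
#' @return data.table: `query_id`, `subject_id`, `AL`, `total_identities`,
#'   `query_length`, `CIP`, `CALP`, `score`.
#' @export
summarize_hsps <- function(hsps, query_lengths) {
  hsps <- as.data.table(hsps)
  if (is.data.frame(query_lengths)) {
    query_lengths <- setNames(as.numeric(query_lengths[["length"]]),
                              as.character(query_lengths[["gene_id"]]))
  }
  if (nrow(hsps) == 0L) {
    return(data.table(query_id = character(0), subject_id = character(0),
                      AL = numeric(0), total_identities = numeric(0),
                      query_length = numeric(0), CIP = numeric(0),
                      CALP = numeric(0), score = numeric(0)))
  }
  missing <- setdiff(unique(hsps$query_id), names(query_lengths))
  if (length(missing)) {
    stop("missing query length for gene(s): ", paste(head(missing, 10), collapse = ", "))
  }
  out <- hsps[, .(AL = sum(as.numeric(hsp_length)),
                  total_identities = sum(as.numeric(n_identities)),
                  score = max(score)),
              by = .(query_id, subject_id)]
  out[, query_length := as.numeric(query_lengths[query_id])]
  out[, CIP := 100 * total_identities / AL]
  out[, CALP := 100 * AL / query_length]
  setcolorder(out, c("query_id", "subject_id", "AL", "total_identities",
                     "query_length", "CIP", "CALP", "score"))
  out[]
}

#' Retain conserved gene pairs by CIP/CALP thresholds
#'
#' Applies the stringency filter CIP >= `cip_min` and CALP >= `calp_min`
#' (inclusive; defaults 50/50). An all-vs-all BLAST reports each pair in two
#' directions (A as query, B as query); with `direction = "either"` (default)
#' a pair is retained when at least one direction passes both thresholds,
#' with `direction = "both"` only when every direction passes (a pair seen in
#' one direction only cannot satisfy `"both"`). Each unordered pair is stored
#' once, carrying the direction-wise maximum CIP, CALP and score.
#'
#' @param summaries output of [summarize_hsps()].
#' @param cip_min,calp_min inclusive thresholds, percent.
#' @param direction `"either"` or `"both"`.
#' @param genes optional gene table; when given, pairs are annotated with
#'   `species_a`/`species_b` (required downstream).
#' @return data.table of conserved pairs: `gene_a`, `gene_b` (lexicographic
#'   order), `species_a`, `species_b`, `CIP`, `CALP`, `score`.
#' @export
filter_conserved_pairs <- function(summaries, cip_min = 50, calp_min = 50,
                                   direction = c("either", "both"),
                                   genes = NULL) {
  direction <- match.arg(direction)
  s <- as.data.table(summaries)
  empty <- data.table(gene_a = character(0), gene_b = character(0),
                      species_a = character(0), species_b = character(0),
                      CIP = numeric(0), CALP = numeric(0), score = numeric(0))
  if (nrow(s) == 0L) return(empty)
  s[, `:=`(gene_a = pmin(query_id, subject_id),
           gene_b = pmax(query_id, subject_id),
           ok = CIP >= cip_min & CALP >= calp_min)]
  agg <- s[, .(n_dir = .N, n_ok = sum(ok),
               CIP = max(CIP), CALP = max(CALP), score = max(score)),
           by = .(gene_a, gene_b)]
  keep <- if (direction == "either") agg$n_ok >= 1L else agg$n_ok == 2L & agg$n_dir == 2L
  out <- agg[keep, .(gene_a, gene_b, CIP, CALP, score)]
  if (!is.null(genes)) {
    genes <- as.data.table(genes)
    sp <- setNames(genes$species, genes$gene_id)
    out[, `:=`(species_a = as.character(sp[gene_a]),
               species_b = as.character(sp[gene_b]))]
  } else {
    out[, `:=`(species_a = NA_character_, species_b = NA_character_)]
  }
  setcolorder(out, c("gene_a", "gene_b", "species_a", "species_b",
                     "CIP", "CALP", "score"))
  setorder(out, gene_a, gene_b)
  out[]
}
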