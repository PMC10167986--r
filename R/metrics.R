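# Recovery metrics against simulator ground truth.

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the contingency table:
#' ARI = (sum_ij C(n_ij,2) - E) / (0.5 * (a + b) - E), with
#' a = sum_i C(a_i,2), b = sum_j C(b_j,2), E = a*b / C(n,2).
#'
#' @param x,y label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 for identical partitions. Returns 1 when both
#'   partitions are trivial (no pair information).
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2L) return(1)
  tab <- table(x, y)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(as.numeric(tab))
  a <- ch2(as.numeric(rowSums(tab)))
  b <- ch2(as.numeric(colSums(tab)))
  npairs <- n * (n - 1) / 2
  expected <- a * b / npairs
  denom <- (a + b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}

#' Score an inferred karyotype against simulator ground truth
#'
#' Reports (i) precision and recall of the inferred ortholog table against
#' the true cross-species ortholog pairs, (ii) the adjusted Rand index
#' between the true ancestral-chromosome labels of CAR-assigned member genes
#' and their inferred CAR labels, and (iii) Kendall's tau per CAR between
#' inferred protogene order and the true ancestral gene order (computed on
#' the CAR's majority true chromosome; sign follows the inferred
#' orientation, which is arbitrary per CAR, so `mean_abs_tau` is the
#' orientation-free summary).
#'
#' @param karyotype an `ancestral_karyotype` (ordered, ideally).
#' @param truth `truth` component of [simulate_synteny_dataset()] output.
#' @param orthologs optional ortholog table (from [assign_orthologs()]); if
#'   `NULL`, precision/recall are `NA`.
#' @return list: `precision`, `recall`, `ari`, `per_car_tau` (data.table),
#'   `mean_abs_tau`, `n_cars`, `n_true_chromosomes`.
#' @export
truth_metrics <- function(karyotype, truth, orthologs = NULL) {
  stopifnot(inherits(karyotype, "ancestral_karyotype"))
  precision <- recall <- NA_real_
  if (!is.null(orthologs)) {
    orthologs <- as.data.table(orthologs)
    inf_pairs <- unique(orthologs[, paste(pmin(gene_a, gene_b),
                                          pmax(gene_a, gene_b), sep = "\r")])
    true_pairs <- unique(truth$true_orthologs[, paste(gene_a, gene_b, sep = "\r")])
    tp <- sum(inf_pairs %in% true_pairs)
    precision <- if (length(inf_pairs)) tp / length(inf_pairs) else NA_real_
    recall <- if (length(true_pairs)) tp / length(true_pairs) else NA_real_
  }

  anc_chrom <- setNames(truth$ancestor$chromosome, truth$ancestor$anc_id)
  anc_pos <- setNames(truth$ancestor$position, truth$ancestor$anc_id)
  gene_anc <- setNames(truth$descent$anc_id, truth$descent$gene_id)

  mem <- merge(karyotype$members[backfilled == FALSE],
               karyotype$protogenes[, .(pg_id, car_id, ancestral_rank)],
               by = "pg_id")
  mem <- mem[!is.na(car_id)]
  mem[, anc_id := gene_anc[gene_id]]
  mem <- mem[!is.na(anc_id)]
  ari <- if (nrow(mem) >= 2L) {
    adjusted_rand_index(as.character(anc_chrom[as.character(mem$anc_id)]),
                        mem$car_id)
  } else NA_real_

  # protogene-level: one true (chromosome, position) per pg via its members
  pg_truth <- mem[, .(true_chrom = as.integer(names(sort(table(anc_chrom[as.character(anc_id)]),
                                                         decreasing = TRUE)))[1],
                      true_pos = as.numeric(median(anc_pos[as.character(anc_id)]))),
                  by = .(pg_id, car_id)]
  pg_truth <- merge(pg_truth,
                    karyotype$protogenes[, .(pg_id, ancestral_rank)], by = "pg_id")
  per_car <- pg_truth[!is.na(ancestral_rank), {
    maj <- as.integer(names(sort(table(true_chrom), decreasing = TRUE)))[1]
    sub <- .SD[true_chrom == maj]
    tau <- if (nrow(sub) >= 2L)
      suppressWarnings(cor(sub$ancestral_rank, sub$true_pos, method = "kendall"))
    else NA_real_
    .(majority_chromosome = maj, n_pgs = .N, tau = tau)
  }, by = car_id]

  list(precision = precision, recall = recall, ari = ari,
       per_car_tau = per_car[],
       mean_abs_tau = mean(abs(per_car$tau), na.rm = TRUE),
       n_cars = nrow(karyotype$cars),
       n_true_chromosomes = length(unique(truth$ancestor$chromosome)))
}
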