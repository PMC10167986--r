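# Independent oracle implementations, deliberately written with different
# algorithms/data paths than the package (plain loops, union-find, BFS,
# pair counting) so dual-route checks never collapse onto one code path.

# CIP/CALP by direct one-pass recomputation over raw HSP rows
oracle_summarize <- function(hsps, query_lengths) {
  key <- paste(hsps$query_id, hsps$subject_id, sep = "\r")
  res <- list()
  for (k in unique(key)) {
    rows <- hsps[key == k, ]
    al <- 0; ids <- 0; sc <- -Inf
    for (i in seq_len(nrow(rows))) {
      al <- al + rows$hsp_length[i]
      ids <- ids + rows$n_identities[i]
      sc <- max(sc, rows$score[i])
    }
    q <- rows$query_id[1]
    res[[k]] <- data.frame(query_id = q, subject_id = rows$subject_id[1],
                           AL = al, total_identities = ids,
                           query_length = unname(query_lengths[q]),
                           CIP = 100 * ids / al,
                           CALP = 100 * al / unname(query_lengths[q]),
                           score = sc)
  }
  do.call(rbind, res)
}

# threshold filter by set comprehension over unordered pairs
oracle_filter <- function(summaries, cip_min, calp_min, direction = "either") {
  s <- as.data.frame(summaries)
  ga <- pmin(s$query_id, s$subject_id)
  gb <- pmax(s$query_id, s$subject_id)
  keys <- unique(paste(ga, gb, sep = "\r"))
  kept <- character(0)
  for (k in keys) {
    idx <- which(paste(ga, gb, sep = "\r") == k)
    ok <- s$CIP[idx] >= cip_min & s$CALP[idx] >= calp_min
    retain <- if (direction == "either") any(ok) else (length(idx) == 2 && all(ok))
    if (retain) kept <- c(kept, k)
  }
  sort(kept)
}

# plain union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
uf_union <- function(p, i, j) { p[uf_find(p, i)] <- uf_find(p, j); p }

# tandem arrays: union-find over (same species+chromosome, rank gap <= window,
# conserved-with-each-other) edges; returns list of sorted member vectors
oracle_tandem_arrays <- function(pairs, genes, window) {
  ids <- genes$gene_id
  p <- uf_new(length(ids))
  conserved <- paste(pmin(pairs$gene_a, pairs$gene_b),
                     pmax(pairs$gene_a, pairs$gene_b), sep = "\r")
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    gi <- genes[i, ]; gj <- genes[j, ]
    if (gi$species != gj$species || gi$chromosome != gj$chromosome) next
    if (abs(gi$rank - gj$rank) > window) next
    k <- paste(min(ids[i], ids[j]), max(ids[i], ids[j]), sep = "\r")
    if (k %in% conserved) p <- uf_union(p, i, j)
  }
  roots <- vapply(seq_along(ids), function(i) uf_find(p, i), integer(1))
  comps <- split(ids, roots)
  comps <- comps[lengths(comps) >= 2]
  unname(lapply(comps, sort))
}

# generalized RBH: exhaustive check of the retention predicate per edge
oracle_rbh <- function(edges, n_ab, n_ba) {
  # edges: data.frame gene_a (species A), gene_b (species B), score
  topn <- function(gene, side, n) {
    rows <- edges[edges[[side]] == gene, ]
    other <- setdiff(c("gene_a", "gene_b"), side)
    ord <- order(-rows$score, rows[[other]])
    head(rows[[other]][ord], n)
  }
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    keep[i] <- edges$gene_b[i] %in% topn(edges$gene_a[i], "gene_a", n_ab) &&
      edges$gene_a[i] %in% topn(edges$gene_b[i], "gene_b", n_ba)
  }
  edges[keep, c("gene_a", "gene_b")]
}

# gap-adjacency components by explicit adjacency matrix + BFS
oracle_chain_components <- function(rank_a, rank_b, max_gap) {
  n <- length(rank_a)
  adj <- abs(outer(rank_a, rank_a, "-")) <= max_gap &
    abs(outer(rank_b, rank_b, "-")) <= max_gap
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# ARI by pair counting (different formula route than the contingency table)
oracle_ari <- function(x, y) {
  n <- length(x)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- x[i] == x[j]; sy <- y[i] == y[j]
    if (sx && sy) n11 <- n11 + 1
    else if (!sx && !sy) n00 <- n00 + 1
    else if (sx && !sy) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  den <- (n00 + n01) * (n01 + n11) + (n00 + n10) * (n10 + n11)
  if (den == 0) return(1)
  2 * (n00 * n11 - n01 * n10) / den
}
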