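test_that("summarize_hsps computes CIP/CALP from summed HSPs", {
  hsps <- data.table(query_id = "gA", subject_id = "gB",
                     hsp_length = c(100L, 50L), n_identities = c(60L, 45L),
                     query_start = c(1L, 101L), query_end = c(100L, 150L),
                     subject_start = c(1L, 101L), subject_end = c(100L, 150L),
                     score = c(120, 80))
  s <- summarize_hsps(hsps, c(gA = 150))
  expect_equal(s$AL, 150)
  expect_equal(s$total_identities, 105)
  expect_equal(s$CIP, 70)
  expect_equal(s$CALP, 100)
  expect_equal(s$score, 120)

  # perfect identity at the CALP threshold
  one <- summarize_hsps(data.table(query_id = "q", subject_id = "s",
                                   hsp_length = 80L, n_identities = 80L,
                                   query_start = 1L, query_end = 80L,
                                   subject_start = 1L, subject_end = 80L,
                                   score = 160), c(q = 160))
  expect_equal(one$CIP, 100)
  expect_equal(one$CALP, 50)

  expect_error(summarize_hsps(hsps, c(other = 10)), "gA")
})

test_that("summarize_hsps matches the direct-recomputation oracle on fuzzed sets", {
  for (seed in c(101, 202)) {
    hsps <- random_hsps(60, seed)
    qlen <- random_query_lengths(hsps, seed)
    got <- summarize_hsps(hsps, qlen)
    exp <- oracle_summarize(as.data.frame(hsps), qlen)
    merged <- merge(got, as.data.table(exp),
                    by = c("query_id", "subject_id"), suffixes = c("", ".o"))
    expect_equal(nrow(merged), nrow(got))
    expect_equal(merged$CIP, merged$CIP.o, tolerance = 1e-12)
    expect_equal(merged$CALP, merged$CALP.o, tolerance = 1e-12)
  }
})

test_that("CIP behaves as a weighted mean under added HSPs", {
  base <- data.table(query_id = "q", subject_id = "s", hsp_length = 100L,
                     n_identities = 70L, query_start = 1L, query_end = 100L,
                     subject_start = 1L, subject_end = 100L, score = 1)
  cip0 <- summarize_hsps(base, c(q = 400))$CIP
  lower <- rbind(base, data.table(query_id = "q", subject_id = "s",
                                  hsp_length = 50L, n_identities = 10L,
                                  query_start = 1L, query_end = 50L,
                                  subject_start = 1L, subject_end = 50L, score = 1))
  higher <- rbind(base, data.table(query_id = "q", subject_id = "s",
                                   hsp_length = 50L, n_identities = 49L,
                                   query_start = 1L, query_end = 50L,
                                   subject_start = 1L, subject_end = 50L, score = 1))
  expect_lt(summarize_hsps(lower, c(q = 400))$CIP, cip0)
  expect_gt(summarize_hsps(higher, c(q = 400))$CIP, cip0)
  # order invariance
  expect_equal(summarize_hsps(lower[2:1], c(q = 400))$CIP,
               summarize_hsps(lower, c(q = 400))$CIP)
})

test_that("filter_conserved_pairs applies inclusive thresholds and direction rules", {
  mk <- function(q, s, cip, calp) {
    data.table(query_id = q, subject_id = s, AL = 100, total_identities = cip,
               query_length = 100, CIP = cip, CALP = calp, score = 10)
  }
  # exactly at threshold: retained (inclusive >=)
  at <- mk("a", "b", 50, 50)
  expect_equal(nrow(filter_conserved_pairs(at)), 1L)
  expect_equal(nrow(filter_conserved_pairs(mk("a", "b", 49.9, 90))), 0L)

  # either vs both
  twodir <- rbind(mk("a", "b", 80, 80), mk("b", "a", 40, 80))
  expect_equal(nrow(filter_conserved_pairs(twodir, direction = "either")), 1L)
  expect_equal(nrow(filter_conserved_pairs(twodir, direction = "both")), 0L)
  onedir <- mk("a", "b", 80, 80)
  expect_equal(nrow(filter_conserved_pairs(onedir, direction = "both")), 0L)

  # direction-maximal CIP/CALP stored
  got <- filter_conserved_pairs(rbind(mk("a", "b", 60, 90), mk("b", "a", 75, 55)))
  expect_equal(got$CIP, 75)
  expect_equal(got$CALP, 90)
})

test_that("filtering is monotone and matches the brute-force oracle", {
  set.seed(7)
  n <- 100
  s <- data.table(query_id = sprintf("g%02da", seq_len(n)),
                  subject_id = sprintf("g%02db", seq_len(n)),
                  AL = 100, total_identities = 50, query_length = 100,
                  CIP = runif(n, 30, 70), CALP = runif(n, 30, 130),
                  score = runif(n))
  # add reverse directions for half
  rev_idx <- seq_len(n / 2)
  s <- rbind(s, s[rev_idx, .(query_id = subject_id, subject_id = query_id,
                             AL, total_identities, query_length,
                             CIP = CIP + runif(.N, -10, 10),
                             CALP = CALP + runif(.N, -10, 10), score)])
  for (dir in c("either", "both")) {
    got <- filter_conserved_pairs(s, 50, 50, dir)
    expect_equal(got[, sort(paste(gene_a, gene_b, sep = "\r"))],
                 oracle_filter(s, 50, 50, dir))
  }
  loose <- filter_conserved_pairs(s, 40, 40)
  tight <- filter_conserved_pairs(s, 55, 60)
  key <- function(x) paste(x$gene_a, x$gene_b)
  expect_true(all(key(tight) %in% key(loose)))
  expect_true(all(key(filter_conserved_pairs(s, 50, 50, "both")) %in%
                    key(filter_conserved_pairs(s, 50, 50, "either"))))
})
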