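# small helper: build a MotifTable directly from a frequency design
make_table <- function(motifs, counts, lens, conds) {
  cgram:::.make_motif_table(motifs, counts, lens, conds, "cgram")
}

test_that("Benjamini-Yekutieli adjustment matches the hand-computed example", {
  expect_equal(byAdjust(0.03), 0.03)  # m = 1: c(1) = 1
  # m = 3, c(3) = 11/6: all three step-up minima equal 0.055
  expect_equal(byAdjust(c(0.01, 0.02, 0.03)), rep(0.055, 3))
  set.seed(5)
  p <- runif(50)
  q <- byAdjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_error(byAdjust(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("pooled c-grams are unique, expanded, and counted in every individual", {
  seqs <- list(fig1b_seq, rep(c(3L, 4L), 10))
  res <- lapply(seqs, compress)
  tab <- poolCgrams(res, seqs, conditions = c("x", "y"))

  expect_s4_class(tab, "MotifTable")
  keys <- motifLabels(tab)
  expect_identical(anyDuplicated(keys), 0L)
  expect_true("1-2-1" %in% keys)
  # motif from C's dictionary is absent from B's sequence: frequency 0
  expect_identical(assay(tab, "frequency")["1-2-1", 2], 0)
  expect_equal(assay(tab, "frequency")["1-2-1", 1], 5 / 19)
  expect_true(all(motifOrigin(tab) == "cgram"))

  # pooling the same individual twice deduplicates the shared motifs
  tab2 <- poolCgrams(list(res[[1]], res[[1]]), list(fig1b_seq, fig1b_seq),
                     c("x", "y"))
  expect_identical(nrow(tab2), length(rules(res[[1]])))
})

test_that("every pooled c-gram occurs at least twice in its source individual", {
  set.seed(17)
  seqs <- markov_cohort(4, 400)
  res <- lapply(seqs, compress)
  for (i in seq_along(seqs)) {
    for (r in rules(res[[i]])) {
      ex <- expandCgram(res[[i]], r@symbol)
      expect_gte(r_count_nonoverlap(seqLabels(seqs[[i]]), ex)$n, 2L)
    }
  }
})

test_that("n-gram enumeration is exhaustive and the c-gram pool is far smaller", {
  tab <- enumerateNgrams(list(c(1L, 2L, 3L)), conditions = "x", maxLen = 2)
  expect_setequal(motifLabels(tab), c("1", "2", "3", "1-2", "2-3"))
  expect_true(all(assay(tab, "count") == 1L))

  # k larger than available n-grams keeps all of them
  top <- topFrequentNgrams(list(c(1L, 2L, 3L)), conditions = "x",
                           k = 99, maxLen = 2)
  expect_setequal(motifLabels(top), motifLabels(tab))

  set.seed(19)
  seqs <- markov_cohort(4, 400)
  res <- lapply(seqs, compress)
  conds <- rep(c("x", "y"), 2)
  nC <- nrow(poolCgrams(res, seqs, conds))
  nN <- nrow(enumerateNgrams(seqs, conds, maxLen = 10))
  expect_lt(nC, nN / 10)

  # unique n-gram count outgrows unique c-gram count as maxLen rises
  n5 <- nrow(enumerateNgrams(seqs, conds, maxLen = 5))
  expect_gt(nN - n5, 0)
})

test_that("top-frequent selection keeps k per individual and length", {
  set.seed(29)
  seqs <- markov_cohort(3, 300)
  top <- topFrequentNgrams(seqs, conditions = c("x", "y", "x"),
                           k = 5, maxLen = 4)
  expect_true(all(motifLength(top) <= 4))
  # no more than 3 individuals x 5 picks per length can survive pooling
  perLen <- table(motifLength(top))
  expect_true(all(perLen <= 15))
  expect_true(all(motifOrigin(top) == "top_frequent_ngram"))
})

test_that("condition comparison flags planted differences and handles edge cases", {
  # single motif, single pair: q equals the raw p (BY with c(1) = 1)
  counts <- matrix(c(5L, 6L, 7L, 0L, 0L, 1L), nrow = 1)
  tab <- make_table(list(c(2L, 8L)), counts, rep(100L, 6),
                    rep(c("a", "b"), each = 3))
  res <- compareConditions(tab)
  expect_equal(comparisonTable(res)$q, comparisonTable(res)$p)

  # constant frequencies: p = 1, never a hit
  tabc <- make_table(list(c(2L, 8L)), matrix(3L, 1, 6), rep(100L, 6),
                     rep(c("a", "b"), each = 3))
  expect_equal(comparisonTable(compareConditions(tabc))$p, 1)

  # strongly separated groups: hit at FDR 5%
  counts2 <- matrix(c(rep(9:12, 2), rep(0L, 8)), nrow = 1)
  tabh <- make_table(list(c(2L, 8L)), counts2, rep(100L, 16),
                     rep(c("a", "b"), each = 8))
  resh <- compareConditions(tabh)
  expect_identical(hits(resh), "2-8")

  expect_error(compareConditions(make_table(list(1L), matrix(1L, 1, 2),
                                            c(10L, 10L), c("a", "b"))),
               "2 individuals")
})

test_that("comparison is invariant to individual order and label swaps", {
  set.seed(37)
  counts <- matrix(rpois(40, 5), nrow = 4)
  motifs <- list(1L, 2L, c(1L, 2L), c(2L, 1L))
  conds <- rep(c("a", "b"), each = 5)
  tab <- make_table(motifs, counts, rep(200L, 10), conds)
  base <- compareConditions(tab)

  perm <- sample(10)
  tabp <- make_table(motifs, counts[, perm], rep(200L, 10), conds[perm])
  permuted <- compareConditions(tabp)
  expect_equal(comparisonTable(base)$p, comparisonTable(permuted)$p)

  # swapping the condition labels flips group1/group2 but not p-values
  swapped <- make_table(motifs, counts, rep(200L, 10),
                        c("b", "a")[match(conds, c("a", "b"))])
  expect_equal(comparisonTable(compareConditions(swapped))$p,
               comparisonTable(base)$p)
})

test_that("hit summaries stratify by length and rank hits by best frequency", {
  counts2 <- matrix(c(rep(9:12, 2), rep(0L, 8),   # separated -> hit
                      rep(3L, 16)), nrow = 2, byrow = TRUE)
  tab <- make_table(list(c(2L, 8L), 5L), counts2, rep(100L, 16),
                    rep(c("a", "b"), each = 8))
  res <- compareConditions(tab)
  hs <- hitSummary(res)
  expect_identical(hs$nHits[hs$length == 2], 1L)
  expect_identical(hs$nHits[hs$length == 1], 0L)
  expect_equal(hs$hitFraction, c(0, 1))

  fr <- frequencyRankDistribution(tab, res)
  expect_identical(fr$motif, "2-8")
  expect_identical(fr$bestRank, 1L)  # most frequent in the 'a' individuals

  # no hits at all: empty rank table, zero fractions
  resc <- compareConditions(make_table(list(5L), matrix(3L, 1, 6),
                                       rep(100L, 6),
                                       rep(c("a", "b"), each = 3)))
  expect_identical(nrow(frequencyRankDistribution(
    make_table(list(5L), matrix(3L, 1, 6), rep(100L, 6),
               rep(c("a", "b"), each = 3)), resc)), 0L)
  expect_equal(hitSummary(resc)$hitFraction, 0)
})

test_that("c-gram hits discriminate conditions better than the n-gram pool", {
  spec <- cohortSpec(
    nPerCondition = 8, conditions = c("A", "B"), seqLength = 400,
    plantedMotifs = list(
      list(motif = c(7L, 3L, 9L, 3L), rates = c(A = 0.03, B = 0)),
      list(motif = c(21L, 40L, 2L), rates = c(A = 0, B = 0.03))),
    seed = 47)
  coh <- generateCohort(spec)
  seqs <- cohortSequences(coh)
  res <- lapply(seqs, compress)
  cg <- compareConditions(poolCgrams(res, seqs, conditions(coh)))
  ng <- compareConditions(enumerateNgrams(seqs, conditions(coh), maxLen = 5))
  cgFrac <- length(hits(cg)) / nrow(poolCgrams(res, seqs, conditions(coh)))
  ngFrac <- length(hits(ng)) /
    nrow(enumerateNgrams(seqs, conditions(coh), maxLen = 5))
  expect_gt(cgFrac, ngFrac)
})
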