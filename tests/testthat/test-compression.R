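test_that("savings follows the description-length formula", {
  expect_identical(savings(3, 5), 6L)
  expect_identical(savings(2, 3), 0L)   # 2-grams need N >= 4 to compress
  expect_identical(savings(2, 2), -1L)  # smallest repeat is never compressive
  expect_identical(savings(c(2, 10), c(4, 11)), c(1L, 88L))
})

test_that("non-overlapping counting is greedy left-to-right", {
  out <- countNonoverlapping(fig1b_seq, c(1, 2, 1))
  expect_identical(out$n, 5L)
  expect_identical(out$starts, c(1L, 4L, 9L, 12L, 17L))
  expect_identical(countNonoverlapping(c(1, 1, 1, 1), c(1, 1))$n, 2L)
  absent <- countNonoverlapping(fig1b_seq, c(9, 9))
  expect_identical(absent$n, 0L)
  expect_length(absent$starts, 0L)
  expect_error(countNonoverlapping(fig1b_seq, integer()), "non-empty")
})

test_that("countNonoverlapping agrees with a pure-R scan", {
  set.seed(21)
  for (i in 1:40) {
    s <- rand_labels(60, 3)
    sub <- rand_labels(sample(1:4, 1), 3)
    expect_identical(countNonoverlapping(s, sub),
                     r_count_nonoverlap(s, sub))
  }
})

test_that("the most compressive subsequence is found with canonical ties", {
  best <- findMostCompressive(fig1b_seq)
  expect_identical(best$body, c(1L, 2L, 1L))
  expect_identical(best$savings, 6)

  # after the first replacement both 4-grams tie at S = 1; canonical order
  # (ascending length then lexicographic) picks {3,2,2,3}
  it2 <- c(3L, 3L, 2L, 2L, 3L, 3L, 2L, 2L, 3L)
  a <- countNonoverlapping(it2, c(3, 2, 2, 3))
  b <- countNonoverlapping(it2, c(3, 3, 2, 2))
  expect_identical(savings(4, a$n), 1L)
  expect_identical(savings(4, b$n), 1L)
  tie <- findMostCompressive(it2)
  expect_identical(tie$body, c(3L, 2L, 2L, 3L))

  expect_null(findMostCompressive(c(1, 2, 3, 4, 5)))
})

test_that("findMostCompressive matches exhaustive enumeration", {
  set.seed(31)
  for (i in 1:150) {
    s <- rand_labels(sample(8:30, 1), sample(2:5, 1))
    got <- findMostCompressive(s, wMax = 10)
    want <- oracle_best(s, 10)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(got$body, as.integer(want$body))
      expect_identical(got$savings, as.numeric(want$savings))
      expect_identical(got$N, want$N)
      expect_identical(got$starts, want$starts)
    }
  }
})

test_that("compressing the two-symbol worked example gives the known dictionary", {
  res <- compress(fig1b_seq, wMax = 10)
  expect_identical(uncompressedLength(res), 19L)
  expect_identical(compressedSequence(res), c(3L, 4L, 4L))
  rl <- rules(res)
  expect_length(rl, 2L)
  expect_identical(rl[[1]]@body, c(1L, 2L, 1L))
  expect_identical(rl[[1]]@savings, 6L)
  expect_identical(rl[[2]]@body, c(3L, 2L, 2L, 3L))
  expect_identical(rl[[2]]@savings, 1L)
  expect_identical(sum(vapply(rl, function(r) r@W + 1L, integer(1))), 9L)
  expect_equal(compressibility(res), 7 / 19)
})

test_that("compression is lossless and satisfies the accounting identity", {
  set.seed(41)
  for (i in 1:60) {
    s <- rand_labels(sample(0:80, 1), sample(2:12, 1))
    res <- compress(s, wMax = sample(c(3L, 5L, 10L), 1))
    expect_identical(decompress(res), as.integer(s))
    sav <- vapply(rules(res), slot, integer(1), "savings")
    wp1 <- vapply(rules(res), function(r) r@W + 1L, integer(1))
    expect_identical(uncompressedLength(res),
                     length(compressedSequence(res)) + sum(wp1) + sum(sav))
    expect_true(compressibility(res) >= 0 && compressibility(res) < 1)
    expect_true(all(sav >= 1L))
  }
})

test_that("compression is deterministic and repeat-free input is incompressible", {
  s <- rand_labels(200, 4)
  r1 <- compress(s)
  r2 <- compress(s)
  expect_equal(r1, r2)
  expect_identical(compressibility(compress(sample(1:50))), 0)
  empty <- compress(integer())
  expect_identical(compressibility(empty), 0)
  expect_length(rules(empty), 0L)
})

test_that("decompress rejects a corrupt dictionary", {
  res <- compress(fig1b_seq)
  broken <- res
  broken@compressed <- c(broken@compressed, 99L)
  broken@l <- broken@l + 1L  # keep accounting consistent enough to test decode
  expect_error(decompress(broken), "unknown symbol")
})

test_that("c-grams expand to base labels and report nesting", {
  res <- compress(fig1b_seq)
  # base labels expand to themselves (over a realistic 90-state alphabet)
  res90 <- compress(fig1b_seq, alphabetSize = 90)
  expect_identical(expandCgram(res90, 17L), 17L)
  # alphabet of the toy sequence itself is 2, so symbol 3 is the first rule
  expect_identical(expandCgram(res, 3L), c(1L, 2L, 1L))
  expect_identical(expandCgram(res, 4L), c(1L, 2L, 1L, 2L, 2L, 1L, 2L, 1L))
  expect_identical(nestingDepth(res, 1L), 0L)
  expect_identical(nestingDepth(res, 3L), 1L)
  expect_identical(nestingDepth(res, 4L), 2L)
  expect_error(expandCgram(res, 99L), "dangling")

  den <- cgramDendrogram(res, 4L)
  expect_identical(den$symbol, 4L)
  expect_identical(den$n, 2L)
  expect_identical(vapply(den$children, `[[`, integer(1), "symbol"),
                   c(3L, 2L, 2L, 3L))
  expect_identical(den$children[[1]]$n, 5L)
  expect_length(den$children[[2]]$children, 0L)
})

test_that("rule expansions occur in the original sequence", {
  set.seed(51)
  for (i in 1:20) {
    s <- rand_labels(150, 4)
    res <- compress(s)
    for (r in rules(res)) {
      ex <- expandCgram(res, r@symbol)
      hit <- r_count_nonoverlap(s, ex)
      expect_gte(hit$n, 1L)
      # occurrences recorded at creation map to expansions in original coords
      expect_true(all(vapply(r@origStarts, function(p)
        p + length(ex) - 1L <= length(s) &&
          identical(s[p:(p + length(ex) - 1L)], ex), logical(1))))
    }
  }
})

test_that("arc diagrams connect adjacent occurrences in original coordinates", {
  res <- compress(fig1b_seq)
  arcs <- arcDiagram(res)
  a3 <- arcs[arcs$symbol == 3L, ]
  expect_identical(a3$start1, c(1L, 4L, 9L, 12L))
  expect_identical(a3$start2, c(4L, 9L, 12L, 17L))
  expect_true(all(a3$width == 3L))
  a4 <- arcs[arcs$symbol == 4L, ]
  expect_identical(nrow(a4), 1L)
  expect_identical(a4$width, 8L)

  # repeat-free sequence: no rules, hence no arcs
  none <- arcDiagram(compress(sample(1:40)))
  expect_identical(nrow(none), 0L)
})

test_that("shuffling a structured sequence removes most arcs", {
  set.seed(61)
  src <- simulateMarkov(defaultBaseModel(90), 1700)
  structured <- nrow(arcDiagram(compress(src)))
  shuffled <- nrow(arcDiagram(compress(shuffleSequence(src))))
  expect_gt(structured, 4 * max(shuffled, 1))
})

test_that("chunked phenotype reports per-chunk compressibility and dwell", {
  set.seed(71)
  lab <- seqLabels(simulateMarkov(defaultBaseModel(90), 1234))
  ws <- WarpedSequence(lab, durations = rep(2, 1234))
  ph <- chunkedPhenotype(ws, chunkLen = 500)
  expect_identical(nrow(ph), 2L)  # floor(1234 / 500)
  expect_identical(ph$chunk, 1:2)
  expect_true(all(ph$meanStateDuration == 2))

  # all-distinct chunk: zero compressibility, mean dwell as given
  ws2 <- WarpedSequence(1:500, durations = rep(c(1, 3), 250))
  ph2 <- chunkedPhenotype(ws2, chunkLen = 500)
  expect_identical(ph2$compressibility, 0)
  expect_identical(ph2$meanStateDuration, 2)

  short <- chunkedPhenotype(WarpedSequence(1:10), chunkLen = 500)
  expect_identical(nrow(short), 0L)
})
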