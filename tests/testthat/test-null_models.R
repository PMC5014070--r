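test_that("uniform random sequences are reproducible and nearly incompressible", {
  a <- uniformRandomSequence(90, 1000, seed = 5)
  b <- uniformRandomSequence(90, 1000, seed = 5)
  expect_identical(a, b)
  expect_true(all(a >= 1 & a <= 90))

  # a tiny alphabet forces repeats and substantial compression
  small <- uniformRandomSequence(2, 1000, seed = 5)
  expect_gt(compressibility(compress(small)), 0.3)
})

test_that("the deterministic cycle bounds compressibility from above", {
  expect_identical(cyclicSequence(90, 5), 1:5)
  expect_identical(compressibility(compress(cyclicSequence(90, 90))), 0)
  # frozen regression value for the 1..90 cycle truncated at 990
  expect_equal(compressibility(compress(cyclicSequence(90, 990))), 872 / 990)
})

test_that("shuffle and sort preserve the label multiset", {
  set.seed(3)
  ws <- simulateMarkov(defaultBaseModel(30, seed = 8), 400)
  sh <- shuffleSequence(ws, seed = 9)
  expect_identical(shuffleSequence(ws, seed = 9), sh)
  expect_identical(sort(sh), sort(seqLabels(ws)))
  expect_identical(sortLabels(ws), sort(seqLabels(ws)))

  # sorting creates maximal runs: far more compressible than shuffling
  expect_gt(compressibility(compress(sortLabels(ws))),
            compressibility(compress(sh)))
})

test_that("shuffling does not increase compressibility of structured sequences", {
  set.seed(13)
  spec <- cohortSpec(nPerCondition = 8, conditions = "A", seqLength = 600,
                     plantedMotifs = list(list(motif = c(7L, 3L, 9L, 3L),
                                               rates = c(A = 0.02))),
                     seed = 13)
  seqs <- cohortSequences(generateCohort(spec))
  orig <- vapply(seqs, function(s) compressibility(compress(s)), numeric(1))
  shuf <- vapply(seqs, function(s)
    compressibility(compress(shuffleSequence(s))), numeric(1))
  expect_lt(mean(shuf), mean(orig))
})

test_that("Markov fitting recovers observed transition frequencies", {
  m <- fitMarkov(c(1, 2, 1, 2, 1))
  expect_identical(m@states, c(1L, 2L))
  expect_equal(m@transMatrix, rbind(c(0, 1), c(1, 0)))
  expect_equal(m@initDist, c(3, 2) / 5)

  # simulation from the alternating model is strictly alternating and
  # therefore highly compressible
  sim <- simulateMarkov(m, 60, seed = 2)
  lab <- seqLabels(sim)
  expect_true(all(lab[-1] != lab[-60]))
  expect_gt(compressibility(compress(sim)), 0.5)

  # terminal state without outgoing observations gets a uniform row
  expect_message(m2 <- fitMarkov(c(1, 2, 3)), "no outgoing")
  expect_equal(m2@transMatrix[3, ], c(0.5, 0.5, 0))
  expect_error(fitMarkov(1L), "at least 2")
})

test_that("pooled Markov fits sit below the planted-motif source", {
  set.seed(23)
  spec <- cohortSpec(nPerCondition = 10, conditions = "A", seqLength = 800,
                     plantedMotifs = list(list(motif = c(7L, 3L, 9L, 3L),
                                               rates = c(A = 0.02))),
                     seed = 23)
  seqs <- cohortSequences(generateCohort(spec))
  src <- vapply(seqs, function(s) compressibility(compress(s)), numeric(1))
  model <- fitMarkov(seqs)
  sim <- replicate(20, compressibility(compress(simulateMarkov(model, 800))))
  expect_lt(mean(sim), mean(src))
  expect_gt(mean(sim), mean(replicate(
    10, compressibility(compress(uniformRandomSequence(90, 800))))))
})

test_that("compressibility curves have the expected shapes", {
  cyc <- compressibilityCurve(function(n) cyclicSequence(90, n),
                              lengths = c(180, 450, 900))
  expect_true(all(diff(cyc$mean) > 0))
  expect_identical(cyc$sd, c(0, 0, 0))

  unif <- compressibilityCurve(function(n) uniformRandomSequence(90, n),
                               lengths = c(250, 500, 1000),
                               replicates = 10, seed = 4)
  expect_true(all(unif$mean < 0.01))
  expect_identical(compressibilityCurve(function(n) cyclicSequence(90, n),
                                        lengths = c(180, 450, 900)), cyc)
})
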