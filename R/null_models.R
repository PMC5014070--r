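#' Null-model sequence generators
#'
#' Control sequences for calibrating compressibility: uniform random
#' sequences are essentially incompressible at realistic alphabet sizes,
#' the deterministic cycle is an upper bound, and shuffled / sorted versions
#' of a sequence bound it while preserving its label frequencies.
#'
#' `uniformRandomSequence()` samples i.i.d. labels; adjacent repeats are
#' allowed (each occurs with probability 1/alphabet per step), so its output
#' is a plain label vector rather than a [WarpedSequence-class].
#'
#' @param alphabet alphabet size (>= 2).
#' @param length sequence length.
#' @param seed optional integer seed; same seed gives the identical sequence.
#' @return integer label vector.
#' @examples
#' compressibility(compress(cyclicSequence(90, 90)))  # 0: no repeat yet
#' @export
uniformRandomSequence <- function(alphabet = 90L, length, seed = NULL) {
  stopifnot(alphabet >= 2L)
  draw <- function() sample.int(alphabet, length, replace = TRUE)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @rdname uniformRandomSequence
#' @details `cyclicSequence()` repeats the symbols `1..alphabet` in turn up
#'   to the requested length — the maximally ordered control.
#' @export
cyclicSequence <- function(alphabet = 90L, length) {
  stopifnot(alphabet >= 2L)
  ((seq_len(length) - 1L) %% as.integer(alphabet)) + 1L
}

#' Shuffle or sort a sequence, preserving label frequencies
#'
#' `shuffleSequence()` randomly permutes the labels (destroying temporal
#' order); `sortLabels()` sorts them (creating maximal runs). Both preserve
#' the label multiset exactly. Because a permutation or sort can place equal
#' labels adjacently, both return plain label vectors.
#'
#' @param x a [WarpedSequence-class] or integer label vector.
#' @param seed optional integer seed for the shuffle.
#' @return integer label vector with the same multiset as the input.
#' @export
shuffleSequence <- function(x, seed = NULL) {
  lab <- if (is(x, "WarpedSequence")) seqLabels(x) else as.integer(x)
  draw <- function() sample(lab)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @rdname shuffleSequence
#' @export
sortLabels <- function(x) {
  lab <- if (is(x, "WarpedSequence")) seqLabels(x) else as.integer(x)
  sort(lab)
}

#' Fit a first-order Markov model to a warped sequence
#'
#' Transition probabilities are the observed conditional frequencies
#' `P(j | i) = count(i -> j) / count(i -> .)` over the states present in the
#' sequence. Warped sequences contain no self-transitions, so the diagonal
#' is zero. States observed but with no outgoing transition (only possible
#' for the final state) get a uniform row over the other states, so that
#' simulation is well defined at any length.
#'
#' @param x a [WarpedSequence-class] or label vector without adjacent
#'   repeats, length >= 2 — or a list of them, in which case transition
#'   counts are pooled across the sequences (the usual way to estimate the
#'   model from a cohort of recordings, and much less prone to overfitting
#'   than a single-sequence fit at large alphabets).
#' @return a [MarkovModel-class]; the initial distribution is the empirical
#'   label distribution.
#' @export
fitMarkov <- function(x) {
  if (!is.list(x)) x <- list(x)
  labs <- lapply(x, function(s)
    if (is(s, "WarpedSequence")) seqLabels(s) else as.integer(s))
  if (sum(lengths(labs)) < 2L)
    stop("need at least 2 elements to fit transitions")
  states <- sort(unique(unlist(labs)))
  k <- length(states)
  P <- matrix(0, k, k)
  cnt <- numeric(k)
  for (lab in labs) {
    idx <- match(lab, states)
    cnt <- cnt + tabulate(idx, k)
    if (length(idx) < 2L) next
    from <- idx[-length(idx)]
    to <- idx[-1L]
    for (t in seq_along(from)) P[from[t], to[t]] <- P[from[t], to[t]] + 1
  }
  zero <- rowSums(P) == 0
  if (any(zero)) {
    message(sprintf("fitMarkov: %d state(s) with no outgoing observations; using uniform rows", sum(zero)))
    for (i in which(zero)) P[i, -i] <- 1
  }
  P <- P / rowSums(P)
  new("MarkovModel", states = as.integer(states), transMatrix = P,
      initDist = cnt / sum(cnt))
}

#' Simulate a warped sequence from a Markov model
#'
#' Draws the initial state from the model's initial distribution and then
#' iterates the transition matrix. The zero diagonal guarantees no adjacent
#' repeats, so the output is a valid [WarpedSequence-class] (with unit
#' durations).
#'
#' @param model a [MarkovModel-class].
#' @param length number of warped symbols to emit.
#' @param seed optional integer seed.
#' @return a [WarpedSequence-class].
#' @export
simulateMarkov <- function(model, length, seed = NULL) {
  stopifnot(is(model, "MarkovModel"), length >= 1L)
  draw <- function() {
    k <- base::length(model@states)
    out <- integer(length)
    cur <- sample.int(k, 1L, prob = model@initDist)
    out[1L] <- cur
    if (length > 1L) for (t in 2:length) {
      cur <- sample.int(k, 1L, prob = model@transMatrix[cur, ])
      out[t] <- cur
    }
    model@states[out]
  }
  lab <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  WarpedSequence(lab, alphabetSize = max(90L, model@states))
}

setMethod("show", "MarkovModel", function(object) {
  cat(sprintf("MarkovModel over %d states (zero-diagonal, row-stochastic)\n",
              length(object@states)))
})

#' Compressibility as a function of sequence length
#'
#' Runs a generator at each requested length, compresses the result, and
#' tabulates the mean and standard deviation of compressibility over
#' replicates — the compressibility-versus-length curve used to place a
#' sequence family between the random and deterministic extremes.
#'
#' @param generator a function of a single argument (the length) returning
#'   an integer label vector or [WarpedSequence-class].
#' @param lengths integer vector of sequence lengths (each >= 2).
#' @param replicates replicates per length (default 1).
#' @param wMax passed to [compress()].
#' @param seed optional integer seed applied to the whole sweep.
#' @return data.frame with columns `length`, `mean`, `sd` (`sd` is 0 for a
#'   single replicate).
#' @examples
#' compressibilityCurve(function(n) cyclicSequence(10, n), c(20, 50))
#' @export
compressibilityCurve <- function(generator, lengths, replicates = 1L,
                                 wMax = 10L, seed = NULL) {
  stopifnot(all(lengths >= 2L), replicates >= 1L)
  run <- function() {
    do.call(rbind, lapply(lengths, function(L) {
      cs <- vapply(seq_len(replicates), function(i) {
        compressibility(compress(generator(L), wMax = wMax))
      }, numeric(1))
      data.frame(length = L, mean = mean(cs),
                 sd = if (replicates > 1L) sd(cs) else 0)
    }))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
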