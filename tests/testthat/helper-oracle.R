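# Independent pure-R reference implementations used as oracles.
# Deliberately simple and separate from the package's C++ path.

# greedy left-to-right non-overlapping scan
r_count_nonoverlap <- function(seq, sub) {
  n <- 0L
  starts <- integer()
  W <- length(sub)
  L <- length(seq)
  p <- 1L
  while (p + W - 1L <= L) {
    if (all(seq[p:(p + W - 1L)] == sub)) {
      n <- n + 1L
      starts <- c(starts, p)
      p <- p + W
    } else {
      p <- p + 1L
    }
  }
  list(n = n, starts = starts)
}

# exhaustive enumeration of every unique subsequence with 2 <= W <= wmax,
# canonical tie order (ascending length, then lexicographic)
oracle_best <- function(seq, wmax) {
  L <- length(seq)
  if (L < 4L) return(NULL)
  cands <- list()
  for (W in 2:min(wmax, L)) {
    for (p in 1:(L - W + 1L)) cands[[length(cands) + 1L]] <- seq[p:(p + W - 1L)]
  }
  keys <- vapply(cands, paste, character(1), collapse = "-")
  cands <- cands[!duplicated(keys)]
  pad <- vapply(cands, function(m) paste(sprintf("%08d", m), collapse = ""),
                character(1))
  cands <- cands[order(lengths(cands), pad)]
  best <- NULL
  for (m in cands) {
    cnt <- r_count_nonoverlap(seq, m)
    if (cnt$n < 2L) next
    W <- length(m)
    s <- W * cnt$n - (W + 1L + cnt$n)
    if (s >= 1L && (is.null(best) || s > best$savings)) {
      best <- list(body = m, W = W, N = cnt$n, savings = s,
                   starts = cnt$starts)
    }
  }
  best
}

# repeat-rich random test sequence (small alphabets force structure)
rand_labels <- function(len, alphabet) {
  sample.int(alphabet, len, replace = TRUE)
}

# small motif-free Markov cohort for pooling tests
markov_cohort <- function(n, len, model = defaultBaseModel(30, seed = 99)) {
  lapply(seq_len(n), function(i) simulateMarkov(model, len))
}

fig1b_seq <- c(1L, 2L, 1L, 1L, 2L, 1L, 2L, 2L, 1L, 2L, 1L, 1L, 2L, 1L, 2L,
               2L, 1L, 2L, 1L)
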