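#' Description-length savings of a replacement
#'
#' Replacing a subsequence of length `W` occurring `N` times by a new symbol
#' saves `W*N` symbols in the sequence but costs `W + 1` dictionary symbols
#' and `N` new symbols in the compressed sequence, for a net saving of
#' `S = W*N - (W + 1 + N)`.
#'
#' @param W subsequence length(s).
#' @param N occurrence count(s).
#' @return integer savings; vectorized over `W` and `N`.
#' @examples
#' savings(3, 5)  # 6
#' savings(2, 3)  # 0: a 2-gram needs N >= 4 to be compressive
#' @export
savings <- function(W, N) {
  as.integer(W * N - (W + 1 + N))
}

#' Greedy non-overlapping occurrence count
#'
#' Scans left to right; after a match at position `p` the scan resumes at
#' `p + length(sub)`, so occurrences never overlap. This is the occurrence
#' count `N` used throughout the compression algorithm and for motif
#' frequencies.
#'
#' @param seq integer label vector to scan.
#' @param sub non-empty integer pattern.
#' @return list with `n` (count) and `starts` (1-based match positions).
#' @examples
#' countNonoverlapping(c(1, 1, 1, 1), c(1, 1))$n  # 2
#' @export
countNonoverlapping <- function(seq, sub) {
  if (length(sub) < 1L) stop("sub must be non-empty")
  if (is(seq, "WarpedSequence")) seq <- seqLabels(seq)
  .cpp_count_nonoverlapping(as.integer(seq), as.integer(sub))
}

#' Find the maximally compressive subsequence
#'
#' Considers every unique subsequence of the current sequence with length
#' between 2 and `wMax` and at least two (greedy non-overlapping)
#' occurrences, and returns the one maximizing [savings()], provided the
#' maximum is >= 1. Ties are resolved by taking the candidate that appears
#' first in the canonically sorted list of unique subsequences (ascending
#' length, then lexicographic by labels), which makes the choice total and
#' the algorithm deterministic.
#'
#' @param seq integer label vector (or [WarpedSequence-class]).
#' @param wMax maximum candidate length (default 10).
#' @return a list with `body`, `W`, `N`, `savings`, `starts`, or `NULL` when
#'   no subsequence is compressive.
#' @export
findMostCompressive <- function(seq, wMax = 10L) {
  if (is(seq, "WarpedSequence")) seq <- seqLabels(seq)
  stopifnot(wMax >= 2L)
  out <- .cpp_best_candidate(as.integer(seq), as.integer(wMax))
  if (length(out) == 0L) NULL else out
}

.compress_labels <- function(labels, wMax, alphabetSize) {
  labels <- as.integer(labels)
  l <- length(labels)
  raw <- .cpp_compress(labels, as.integer(wMax), as.integer(alphabetSize))
  rl <- lapply(raw$rules, function(r) {
    new("Rule", symbol = as.integer(r$symbol), body = as.integer(r$body),
        W = as.integer(r$W), N = as.integer(r$N),
        savings = as.integer(r$savings), starts = as.integer(r$starts),
        origStarts = as.integer(r$origStarts))
  })
  tot <- sum(vapply(rl, slot, integer(1), "savings"))
  new("CompressionResult", compressed = as.integer(raw$compressed),
      rules = rl, l = as.integer(l),
      compressibility = if (l > 0L) tot / l else 0,
      alphabetSize = as.integer(alphabetSize))
}

#' @describeIn compress compress a time-warped sequence.
#' @export
setMethod("compress", "WarpedSequence", function(x, wMax = 10L, ...) {
  .compress_labels(x@labels, wMax, x@alphabetSize)
})

#' @describeIn compress compress a plain integer label vector; the alphabet
#'   size is taken as the largest label (rule symbols are assigned above it).
#' @param alphabetSize base alphabet size for the vector method; defaults to
#'   the largest label present.
#' @export
setMethod("compress", "numeric", function(x, wMax = 10L,
                                          alphabetSize = NULL, ...) {
  if (is.null(alphabetSize))
    alphabetSize <- if (length(x)) max(x) else 1
  .compress_labels(x, wMax, alphabetSize)
})

#' @rdname cgram-generics
#' @export
setMethod("rules", "CompressionResult", function(x) x@rules)

#' @rdname cgram-generics
#' @export
setMethod("compressedSequence", "CompressionResult", function(x) x@compressed)

#' @rdname cgram-generics
#' @export
setMethod("uncompressedLength", "CompressionResult", function(x) x@l)

#' @rdname cgram-generics
#' @export
setMethod("compressibility", "CompressionResult", function(x) x@compressibility)

#' @rdname cgram-generics
#' @export
setMethod("alphabetSize", "CompressionResult", function(x) x@alphabetSize)

setMethod("show", "Rule", function(object) {
  cat(sprintf("Rule %d -> {%s}  W=%d N=%d S=%d\n", object@symbol,
              paste(object@body, collapse = ","), object@W, object@N,
              object@savings))
})

setMethod("show", "CompressionResult", function(object) {
  cat(sprintf(
    "CompressionResult: l=%d, compressed length=%d, %d rules, compressibility=%.4g\n",
    object@l, length(object@compressed), length(object@rules),
    object@compressibility))
  for (r in head(object@rules, 5L)) show(r)
  if (length(object@rules) > 5L)
    cat(sprintf("  ... and %d more rules\n", length(object@rules) - 5L))
})

#' Losslessly decode a compression result
#'
#' Recursively substitutes every rule symbol by its body until only base
#' labels remain, recovering the original sequence exactly.
#'
#' @param result a [CompressionResult-class].
#' @return integer vector equal to the original input of [compress()].
#' @export
decompress <- function(result) {
  stopifnot(is(result, "CompressionResult"))
  bodies <- .rule_bodies(result)
  out <- result@compressed
  base <- result@alphabetSize
  repeat {
    isRule <- out > base
    if (!any(isRule)) return(out)
    pieces <- lapply(out, function(s) {
      if (s > base) {
        b <- bodies[[as.character(s)]]
        if (is.null(b)) stop(sprintf("unknown symbol %d: corrupt dictionary", s))
        b
      } else s
    })
    out <- as.integer(unlist(pieces, use.names = FALSE))
  }
}

.rule_bodies <- function(x) {
  rl <- if (is(x, "CompressionResult")) x@rules else x
  setNames(lapply(rl, slot, "body"),
           vapply(rl, function(r) as.character(r@symbol), character(1)))
}

#' Expand a c-gram to base posture labels
#'
#' A c-gram (dictionary symbol) may be nested: its body can contain earlier
#' rule symbols. This expands it fully to the underlying base-label
#' sequence. Base labels expand to themselves.
#'
#' @param x a [CompressionResult-class] or a list of [Rule-class].
#' @param symbol a base label or rule symbol.
#' @return integer vector of base labels.
#' @export
expandCgram <- function(x, symbol) {
  bodies <- .rule_bodies(x)
  base <- if (is(x, "CompressionResult")) x@alphabetSize else {
    syms <- as.integer(names(bodies))
    if (length(syms)) min(syms) - 1L else .Machine$integer.max
  }
  expand1 <- function(s) {
    if (s <= base) return(s)
    b <- bodies[[as.character(s)]]
    if (is.null(b)) stop(sprintf("dangling symbol %d", s))
    unlist(lapply(b, expand1), use.names = FALSE)
  }
  as.integer(expand1(as.integer(symbol)))
}

#' Nesting depth of a c-gram
#'
#' Depth 0 for base labels; otherwise 1 plus the maximum depth of the
#' symbols in the rule body. Highly nested c-grams are "patterns of
#' patterns" in the behavioural hierarchy.
#'
#' @inheritParams expandCgram
#' @return integer nesting depth.
#' @export
nestingDepth <- function(x, symbol) {
  bodies <- .rule_bodies(x)
  base <- if (is(x, "CompressionResult")) x@alphabetSize else {
    syms <- as.integer(names(bodies))
    if (length(syms)) min(syms) - 1L else .Machine$integer.max
  }
  depth1 <- function(s) {
    if (s <= base) return(0L)
    b <- bodies[[as.character(s)]]
    if (is.null(b)) stop(sprintf("dangling symbol %d", s))
    1L + max(vapply(b, depth1, integer(1)))
  }
  depth1(as.integer(symbol))
}

#' Hierarchical dendrogram of a c-gram
#'
#' Returns the nesting tree of a dictionary symbol: each node carries the
#' symbol, the occurrence count `N` recorded when the rule was created
#' (`NA` for base-label leaves), and its children (the body symbols).
#' Leaves are base labels.
#'
#' @inheritParams expandCgram
#' @return a nested list with elements `symbol`, `n`, `children`.
#' @export
cgramDendrogram <- function(x, symbol) {
  rl <- if (is(x, "CompressionResult")) x@rules else x
  bodies <- .rule_bodies(rl)
  ns <- setNames(lapply(rl, slot, "N"), names(bodies))
  base <- if (is(x, "CompressionResult")) x@alphabetSize else {
    syms <- as.integer(names(bodies))
    if (length(syms)) min(syms) - 1L else .Machine$integer.max
  }
  node <- function(s) {
    if (s <= base)
      return(list(symbol = s, n = NA_integer_, children = list()))
    b <- bodies[[as.character(s)]]
    if (is.null(b)) stop(sprintf("dangling symbol %d", s))
    list(symbol = s, n = ns[[as.character(s)]],
         children = lapply(as.integer(b), node))
  }
  node(as.integer(symbol))
}

#' Arc diagram of dictionary motif repeats
#'
#' For every rule, consecutive pairs of its occurrence start positions
#' (mapped back to original-sequence coordinates) give one arc; the arc
#' width is the fully expanded c-gram length. Frequent short motifs yield
#' many small arcs; rare long behaviours yield long wide arcs.
#'
#' @param result a [CompressionResult-class].
#' @return data.frame with columns `symbol`, `start1`, `start2`, `width`;
#'   zero rows when no rule has two or more occurrences.
#' @export
arcDiagram <- function(result) {
  stopifnot(is(result, "CompressionResult"))
  rows <- lapply(result@rules, function(r) {
    st <- sort(r@origStarts)
    if (length(st) < 2L) return(NULL)
    w <- length(expandCgram(result, r@symbol))
    data.frame(symbol = r@symbol, start1 = st[-length(st)], start2 = st[-1L],
               width = w)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(symbol = integer(), start1 = integer(),
                      start2 = integer(), width = integer())
  rownames(out) <- NULL
  out
}

#' Chunked compressibility / dwell-time phenotype
#'
#' Divides a warped sequence into consecutive non-overlapping chunks of
#' exactly `chunkLen` labels (discarding any trailing partial chunk, so the
#' length-dependence of compressibility cancels between individuals) and
#' returns, per chunk, the compressibility and the mean state duration
#' (average time spent in each of the chunk's postures).
#'
#' @param x a [WarpedSequence-class].
#' @param chunkLen chunk length in warped symbols (default 500).
#' @param wMax passed to [compress()].
#' @return data.frame with columns `chunk`, `compressibility`,
#'   `meanStateDuration`; zero rows if the sequence is shorter than
#'   `chunkLen`.
#' @export
chunkedPhenotype <- function(x, chunkLen = 500L, wMax = 10L) {
  stopifnot(is(x, "WarpedSequence"), chunkLen >= 2L)
  nChunk <- length(x) %/% chunkLen
  if (nChunk == 0L)
    return(data.frame(chunk = integer(), compressibility = numeric(),
                      meanStateDuration = numeric()))
  do.call(rbind, lapply(seq_len(nChunk), function(i) {
    idx <- ((i - 1L) * chunkLen + 1L):(i * chunkLen)
    cr <- .compress_labels(x@labels[idx], wMax, x@alphabetSize)
    data.frame(chunk = i, compressibility = cr@compressibility,
               meanStateDuration = mean(x@durations[idx]))
  }))
}
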