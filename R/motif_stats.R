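.motif_key <- function(v) paste(v, collapse = "-")

.parse_motif <- function(s) as.integer(strsplit(s, "-", fixed = TRUE)[[1L]])

# canonical motif order: ascending length, then lexicographic by labels
.canonical_order <- function(motifs) {
  lens <- lengths(motifs)
  pad <- vapply(motifs, function(m) paste(sprintf("%08d", m), collapse = ""),
                character(1))
  order(lens, pad)
}

.seq_list <- function(sequences) {
  lapply(sequences, function(s)
    if (is(s, "WarpedSequence")) seqLabels(s) else as.integer(s))
}

.make_motif_table <- function(motifs, counts, lens, conditions, origin,
                              individuals = NULL) {
  if (is.null(individuals))
    individuals <- sprintf("ind%02d", seq_along(conditions))
  freq <- sweep(counts, 2L, lens, "/")
  keys <- vapply(motifs, .motif_key, character(1))
  dimnames(counts) <- dimnames(freq) <- list(keys, individuals)
  se <- SummarizedExperiment(
    assays = list(count = counts, frequency = freq),
    rowData = DataFrame(motif = keys, length = lengths(motifs),
                        origin = origin, row.names = keys),
    colData = DataFrame(condition = as.character(conditions),
                        seqLength = lens, row.names = individuals))
  new("MotifTable", se)
}

#' Pool c-grams across individuals into a motif table
#'
#' Expands every dictionary rule of every individual's compression result to
#' base labels, keeps the unique motifs, and recomputes each motif's greedy
#' non-overlapping occurrence count in every individual's warped sequence.
#' Frequencies are counts divided by warped-sequence length, so activity
#' differences between individuals cancel.
#'
#' @param results list of [CompressionResult-class], one per individual.
#' @param sequences list of [WarpedSequence-class] (or label vectors), the
#'   sequences the results were computed from, same order.
#' @param conditions per-individual condition labels.
#' @return a [MotifTable-class] with origin `"cgram"`.
#' @export
poolCgrams <- function(results, sequences, conditions) {
  stopifnot(length(results) == length(sequences),
            length(sequences) == length(conditions),
            length(sequences) >= 2L)
  labs <- .seq_list(sequences)
  motifs <- list()
  for (res in results)
    for (r in rules(res))
      motifs[[length(motifs) + 1L]] <- expandCgram(res, r@symbol)
  keys <- vapply(motifs, .motif_key, character(1))
  motifs <- motifs[!duplicated(keys)]
  motifs <- motifs[.canonical_order(motifs)]
  counts <- vapply(labs, function(s) .cpp_count_many(motifs, s),
                   integer(length(motifs)))
  counts <- matrix(counts, nrow = length(motifs))
  .make_motif_table(motifs, counts, lengths(labs), conditions, "cgram")
}

#' Enumerate all n-grams (or the most frequent ones) across individuals
#'
#' `enumerateNgrams()` pools every distinct contiguous subsequence of length
#' `1..maxLen` across the cohort — the exhaustive control against which the
#' much smaller c-gram pool is compared. `topFrequentNgrams()` keeps, per
#' individual and per length, only the `k` n-grams with the highest greedy
#' non-overlapping count (ties broken by canonical motif order) before
#' pooling — the frequency-biased control.
#'
#' @param sequences list of [WarpedSequence-class] or label vectors.
#' @param conditions per-individual condition labels.
#' @param maxLen maximum n-gram length (default 10).
#' @param k n-grams kept per individual and length (default 5).
#' @return a [MotifTable-class] with origin `"all_ngram"` or
#'   `"top_frequent_ngram"`.
#' @export
enumerateNgrams <- function(sequences, conditions, maxLen = 10L) {
  stopifnot(maxLen >= 1L, length(sequences) == length(conditions))
  labs <- .seq_list(sequences)
  per <- lapply(labs, function(s) .cpp_ngram_counts(s, 1L, as.integer(maxLen)))
  perKeys <- lapply(per, function(p)
    vapply(p$grams, .motif_key, character(1)))
  allKeys <- unique(unlist(perKeys, use.names = FALSE))
  motifs <- lapply(allKeys, .parse_motif)
  ord <- .canonical_order(motifs)
  motifs <- motifs[ord]
  allKeys <- allKeys[ord]
  counts <- matrix(0L, length(allKeys), length(labs))
  for (j in seq_along(labs)) {
    i <- match(perKeys[[j]], allKeys)
    counts[i, j] <- per[[j]]$counts
  }
  .make_motif_table(motifs, counts, lengths(labs), conditions, "all_ngram")
}

#' @rdname enumerateNgrams
#' @export
topFrequentNgrams <- function(sequences, conditions, k = 5L, maxLen = 10L) {
  stopifnot(k >= 1L, maxLen >= 1L, length(sequences) == length(conditions))
  labs <- .seq_list(sequences)
  picked <- list()
  for (s in labs) {
    p <- .cpp_ngram_counts(s, 1L, as.integer(maxLen))
    lens <- lengths(p$grams)
    for (L in unique(lens)) {
      i <- which(lens == L)
      # grams arrive in canonical order per length; stable sort keeps that
      # order among count ties
      keep <- i[order(-p$counts[i])][seq_len(min(k, length(i)))]
      picked <- c(picked, p$grams[keep])
    }
  }
  keys <- vapply(picked, .motif_key, character(1))
  motifs <- picked[!duplicated(keys)]
  motifs <- motifs[.canonical_order(motifs)]
  counts <- vapply(labs, function(s) .cpp_count_many(motifs, s),
                   integer(length(motifs)))
  counts <- matrix(counts, nrow = length(motifs))
  .make_motif_table(motifs, counts, lengths(labs), conditions,
                    "top_frequent_ngram")
}

#' @rdname cgram-generics
#' @export
setMethod("conditions", "MotifTable", function(x) colData(x)$condition)

#' MotifTable row accessors
#'
#' @param x a [MotifTable-class].
#' @return `motifLabels()`: hyphen-joined motif strings; `motifList()`: the
#'   motifs as integer vectors; `motifLength()`, `motifOrigin()`: per-motif
#'   length and origin.
#' @export
motifLabels <- function(x) rowData(x)$motif

#' @rdname motifLabels
#' @export
motifList <- function(x) lapply(rowData(x)$motif, .parse_motif)

#' @rdname motifLabels
#' @export
motifLength <- function(x) rowData(x)$length

#' @rdname motifLabels
#' @export
motifOrigin <- function(x) rowData(x)$origin

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment valid under arbitrary dependence:
#' `q(i) = min over j >= i of p(j) * m * c(m) / j` on ascending-sorted
#' p-values, with `c(m) = sum(1/h, h = 1..m)`, capped at 1. Wraps
#' [stats::p.adjust()] with `method = "BY"`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @examples
#' byAdjust(c(0.01, 0.02, 0.03))  # all 0.055
#' @export
byAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BY")
}

#' Compare motif frequencies across conditions
#'
#' For every motif and every unordered pair of conditions, performs a
#' two-sided Wilcoxon rank-sum test on the per-individual frequencies, then
#' applies one Benjamini-Yekutieli adjustment over the whole family (all
#' motifs times all pairs). A motif is a hit when its adjusted q-value is at
#' or below `fdr` in at least one pair.
#'
#' Frequencies that are constant across both groups give p = 1 for that
#' test. For small tie-free groups the exact rank-sum distribution is used;
#' otherwise the normal approximation with tie correction.
#'
#' @param table a [MotifTable-class] with at least two conditions and two
#'   individuals per condition.
#' @param fdr FDR level for hit calling (default 0.05).
#' @return a [ComparisonResult-class].
#' @export
compareConditions <- function(table, fdr = 0.05) {
  stopifnot(is(table, "MotifTable"))
  cond <- conditions(table)
  grp <- unique(cond)
  if (length(grp) < 2L) stop("need at least 2 conditions")
  if (any(tabulate(factor(cond, grp)) < 2L))
    stop("need at least 2 individuals per condition")
  freq <- assay(table, "frequency")
  pairs <- utils::combn(grp, 2L)
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    g1 <- cond == pairs[1L, j]
    g2 <- cond == pairs[2L, j]
    stat <- pval <- numeric(nrow(freq))
    for (i in seq_len(nrow(freq))) {
      x <- freq[i, g1]
      y <- freq[i, g2]
      if (max(c(x, y)) == min(c(x, y))) {      # constant in both groups
        stat[i] <- sum(g1) * sum(g2) / 2
        pval[i] <- 1
      } else {
        wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
        stat[i] <- unname(wt$statistic)
        pval[i] <- wt$p.value
      }
    }
    rows[[j]] <- DataFrame(motif = motifLabels(table),
                           length = motifLength(table),
                           origin = motifOrigin(table),
                           group1 = pairs[1L, j], group2 = pairs[2L, j],
                           statistic = stat, p = pval)
  }
  tb <- do.call(rbind, rows)
  tb$q <- byAdjust(tb$p)
  tb$hit <- tb$q <= fdr
  new("ComparisonResult", table = tb, fdrLevel = fdr)
}

#' ComparisonResult accessors
#'
#' @param x a [ComparisonResult-class].
#' @return `comparisonTable()` returns the full per-motif, per-pair
#'   [S4Vectors::DataFrame]; `hits()` the unique motif strings flagged as
#'   hits in at least one condition pair; `fdrLevel()` the FDR level used.
#' @export
comparisonTable <- function(x) {
  stopifnot(is(x, "ComparisonResult"))
  x@table
}

#' @rdname comparisonTable
#' @export
hits <- function(x) {
  stopifnot(is(x, "ComparisonResult"))
  unique(x@table$motif[x@table$hit])
}

#' @rdname comparisonTable
#' @export
fdrLevel <- function(x) {
  stopifnot(is(x, "ComparisonResult"))
  x@fdrLevel
}

setMethod("show", "ComparisonResult", function(object) {
  tb <- object@table
  cat(sprintf(
    "ComparisonResult: %d motifs x %d condition pairs, FDR %.2g; %d hit motif(s)\n",
    length(unique(tb$motif)), length(unique(paste(tb$group1, tb$group2))),
    object@fdrLevel, length(unique(tb$motif[tb$hit]))))
})

#' Summarize hits by motif length and origin
#'
#' A motif counts as a hit when flagged in at least one condition pair.
#' Returns, per origin and motif length, the number of motifs, the number of
#' hits, and the hit fraction — the stratification used to compare the
#' discriminative power of c-grams against exhaustive and frequency-biased
#' n-gram pools.
#'
#' @param result a [ComparisonResult-class].
#' @return data.frame with columns `origin`, `length`, `nMotifs`, `nHits`,
#'   `hitFraction`.
#' @export
hitSummary <- function(result) {
  stopifnot(is(result, "ComparisonResult"))
  tb <- as.data.frame(result@table)
  per <- stats::aggregate(hit ~ motif + length + origin, data = tb, FUN = any)
  agg <- stats::aggregate(hit ~ origin + length, data = per,
                          FUN = function(h) c(n = length(h), k = sum(h)))
  data.frame(origin = agg$origin, length = agg$length,
             nMotifs = agg$hit[, "n"], nHits = agg$hit[, "k"],
             hitFraction = agg$hit[, "k"] / agg$hit[, "n"])
}

#' Best frequency rank attained by each hit motif
#'
#' Ranks motifs within each individual by decreasing frequency (rank 1 =
#' most frequent, ties take the smallest rank) and reports, for each hit,
#' the numerically smallest rank it attains in any individual. Evenly
#' spread ranks indicate that hits are drawn from across the frequency
#' spectrum rather than only from frequent motifs.
#'
#' @param table the [MotifTable-class] the comparison was computed from.
#' @param result a [ComparisonResult-class] on that table.
#' @return data.frame with columns `motif` and `bestRank`, one row per hit.
#' @export
frequencyRankDistribution <- function(table, result) {
  stopifnot(is(table, "MotifTable"), is(result, "ComparisonResult"))
  hit <- hits(result)
  freq <- assay(table, "frequency")
  rk <- apply(freq, 2L, function(col) rank(-col, ties.method = "min"))
  i <- match(hit, motifLabels(table))
  if (anyNA(i)) stop("hits not found in the motif table")
  best <- if (length(i)) apply(rk[i, , drop = FALSE], 1L, min) else integer()
  data.frame(motif = hit, bestRank = as.integer(best), row.names = NULL)
}
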