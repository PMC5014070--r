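#' Time-warped behavioural label sequence
#'
#' A discrete behavioural sequence after non-uniform time warping: runs of
#' identical labels have been collapsed to a single element, so no two
#' adjacent labels are equal, and each element carries the dwell duration of
#' the run it came from. Labels index a fixed alphabet of behavioural states
#' (by default the 90 posture templates used for worm midline shapes).
#'
#' @slot labels integer vector of state labels, each in `[1, alphabetSize]`,
#'   with no two adjacent labels equal.
#' @slot durations numeric vector of per-element dwell times (frames, or
#'   seconds when a frame interval was applied), same length as `labels`,
#'   all strictly positive.
#' @slot alphabetSize single integer, the number of possible base labels.
#'
#' @seealso [collapseRepeats()], [expandSequence()], [compress()]
#' @export
setClass("WarpedSequence",
  representation(labels = "integer", durations = "numeric",
                 alphabetSize = "integer"))

setValidity("WarpedSequence", function(object) {
  msg <- character()
  lab <- object@labels
  if (length(object@durations) != length(lab))
    msg <- c(msg, "durations and labels must have equal length")
  if (length(object@alphabetSize) != 1L || is.na(object@alphabetSize) ||
      object@alphabetSize < 1L)
    msg <- c(msg, "alphabetSize must be a single positive integer")
  if (length(lab)) {
    if (anyNA(lab) || any(lab < 1L) || any(lab > object@alphabetSize))
      msg <- c(msg, "labels must lie in [1, alphabetSize]")
    if (length(lab) > 1L && any(lab[-1L] == lab[-length(lab)]))
      msg <- c(msg, "adjacent labels must differ (sequence is time-warped)")
    if (anyNA(object@durations) || any(object@durations <= 0))
      msg <- c(msg, "durations must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Posture template set
#'
#' An ordered set of descriptor vectors (one per behavioural state), e.g.
#' the canonical worm midline-angle templates. Frames are discretized by
#' assigning the 1-based index of the nearest template.
#'
#' @slot templates numeric matrix, one template per row.
#' @seealso [discretize()]
#' @export
setClass("TemplateSet", representation(templates = "matrix"))

setValidity("TemplateSet", function(object) {
  tm <- object@templates
  if (!is.numeric(tm)) return("templates must be numeric")
  if (nrow(tm) < 2L) return("need at least 2 templates")
  if (anyNA(tm)) return("templates must not contain NA")
  TRUE
})

#' One dictionary rule of a compression result
#'
#' A rule maps a newly introduced symbol to the subsequence it replaced.
#' Bodies may contain symbols of earlier rules, giving the dictionary its
#' hierarchical (nested) structure.
#'
#' @slot symbol integer; the new label, greater than the alphabet size,
#'   assigned in order of creation.
#' @slot body integer vector; the replaced subsequence (base labels and/or
#'   earlier rule symbols).
#' @slot W integer; body length (>= 2).
#' @slot N integer; number of non-overlapping occurrences replaced (>= 2).
#' @slot savings integer; description-length saving `W*N - (W + 1 + N)`.
#' @slot starts integer; 1-based occurrence start positions in the sequence
#'   as it existed at the iteration that created this rule.
#' @slot origStarts integer; the same occurrences mapped back to positions
#'   in the original uncompressed sequence.
#' @export
setClass("Rule",
  representation(symbol = "integer", body = "integer", W = "integer",
                 N = "integer", savings = "integer", starts = "integer",
                 origStarts = "integer"))

setValidity("Rule", function(object) {
  msg <- character()
  if (object@W != length(object@body)) msg <- c(msg, "W must equal length(body)")
  if (object@W < 2L) msg <- c(msg, "W must be >= 2")
  if (object@N < 2L) msg <- c(msg, "N must be >= 2")
  s <- object@W * object@N - (object@W + 1L + object@N)
  if (object@savings != s || s < 1L)
    msg <- c(msg, "savings must equal W*N - (W + 1 + N) and be >= 1")
  if (any(object@body >= object@symbol))
    msg <- c(msg, "body may only contain symbols created earlier")
  if (length(msg)) msg else TRUE
})

#' Result of hierarchical dictionary compression
#'
#' Holds the compressed sequence, the ordered dictionary of [Rule-class]
#' objects, the uncompressed length `l`, and the compressibility
#' (total savings divided by `l`). The accounting identity
#' `l = length(compressed) + sum(W + 1) + sum(savings)` holds exactly, and
#' decoding ([decompress()]) reproduces the input.
#'
#' @slot compressed integer vector; the fully compressed sequence.
#' @slot rules list of [Rule-class], in order of creation.
#' @slot l integer; uncompressed sequence length.
#' @slot compressibility numeric in `[0, 1)`.
#' @slot alphabetSize integer; base alphabet size (rule symbols start above).
#' @seealso [compress()], [decompress()], [expandCgram()], [arcDiagram()]
#' @export
setClass("CompressionResult",
  representation(compressed = "integer", rules = "list", l = "integer",
                 compressibility = "numeric", alphabetSize = "integer"))

setValidity("CompressionResult", function(object) {
  msg <- character()
  if (!all(vapply(object@rules, is, logical(1), "Rule")))
    msg <- c(msg, "rules must be a list of Rule objects")
  sav <- vapply(object@rules, slot, integer(1), "savings")
  wp1 <- vapply(object@rules, function(r) r@W + 1L, integer(1))
  if (object@l != length(object@compressed) + sum(wp1) + sum(sav))
    msg <- c(msg, "accounting identity l = |compressed| + sum(W+1) + sum(savings) violated")
  if (object@l > 0L &&
      abs(object@compressibility - sum(sav) / object@l) > 1e-12)
    msg <- c(msg, "compressibility must equal sum(savings)/l")
  if (object@compressibility < 0 || object@compressibility >= 1)
    msg <- c(msg, "compressibility must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' First-order Markov model over warped behavioural states
#'
#' Transition model fitted from (or used to simulate) time-warped sequences.
#' Because warped sequences contain no adjacent repeats, the diagonal of the
#' transition matrix is zero.
#'
#' @slot states integer vector of state labels.
#' @slot transMatrix row-stochastic matrix of transition probabilities with
#'   zero diagonal.
#' @slot initDist initial state probability vector.
#' @seealso [fitMarkov()], [simulateMarkov()]
#' @export
setClass("MarkovModel",
  representation(states = "integer", transMatrix = "matrix",
                 initDist = "numeric"))

setValidity("MarkovModel", function(object) {
  msg <- character()
  k <- length(object@states)
  P <- object@transMatrix
  if (!all(dim(P) == c(k, k)))
    msg <- c(msg, "transMatrix must be square with one row per state")
  else {
    if (any(abs(rowSums(P) - 1) > 1e-9))
      msg <- c(msg, "transition matrix rows must sum to 1")
    if (any(abs(diag(P)) > 1e-12))
      msg <- c(msg, "diagonal must be 0 (warped sequences have no self-transitions)")
    if (any(P < 0)) msg <- c(msg, "transition probabilities must be >= 0")
  }
  if (length(object@initDist) != k || abs(sum(object@initDist) - 1) > 1e-9 ||
      any(object@initDist < 0))
    msg <- c(msg, "initDist must be a probability vector over the states")
  if (length(msg)) msg else TRUE
})

#' Pooled motif-by-individual frequency table
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one row per unique
#' motif (expanded to base labels) and one column per individual. Assays are
#' `count` (greedy non-overlapping occurrence counts in each individual's
#' warped sequence) and `frequency` (count divided by warped-sequence
#' length). Row metadata records each motif's label string, length and
#' origin (`cgram`, `all_ngram` or `top_frequent_ngram`); column metadata
#' records each individual's condition and sequence length.
#'
#' @seealso [poolCgrams()], [enumerateNgrams()], [compareConditions()]
#' @export
setClass("MotifTable", contains = "SummarizedExperiment")

setValidity("MotifTable", function(object) {
  msg <- character()
  need <- c("count", "frequency")
  if (!all(need %in% names(assays(object))))
    msg <- c(msg, "assays 'count' and 'frequency' are required")
  rd <- rowData(object)
  if (!all(c("motif", "length", "origin") %in% names(rd)))
    msg <- c(msg, "rowData must contain motif, length and origin")
  else if (anyDuplicated(paste(rd$origin, rd$motif)))
    msg <- c(msg, "motifs must be unique within origin")
  if (!"condition" %in% names(colData(object)))
    msg <- c(msg, "colData must contain a condition column")
  if ("frequency" %in% names(assays(object)) &&
      any(assay(object, "frequency") < 0))
    msg <- c(msg, "frequencies must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Cross-condition motif comparison result
#'
#' Per motif and unordered condition pair: the Wilcoxon rank-sum statistic,
#' raw p-value, Benjamini-Yekutieli adjusted q-value (one adjustment over
#' the whole family of motif x pair tests), and a hit flag (`q <= fdrLevel`).
#'
#' @slot table a [S4Vectors::DataFrame] with columns `motif`, `length`,
#'   `origin`, `group1`, `group2`, `statistic`, `p`, `q`, `hit`.
#' @slot fdrLevel the FDR level used for hit calling (default 0.05).
#' @seealso [compareConditions()], [hitSummary()]
#' @export
setClass("ComparisonResult",
  representation(table = "DataFrame", fdrLevel = "numeric"))

setValidity("ComparisonResult", function(object) {
  need <- c("motif", "length", "origin", "group1", "group2",
            "statistic", "p", "q", "hit")
  if (!all(need %in% names(object@table)))
    return(paste("table must contain columns:", paste(need, collapse = ", ")))
  tb <- object@table
  if (nrow(tb)) {
    if (any(tb$q < tb$p - 1e-12)) return("q-values must be >= raw p-values")
    if (!identical(as.logical(tb$hit), tb$q <= object@fdrLevel))
      return("hit flags must equal q <= fdrLevel")
  }
  TRUE
})

#' Specification of a synthetic behavioural cohort
#'
#' Describes a multi-condition cohort of warped sequences: a base sequence
#' model (first-order Markov, or uniform with adjacent repeats forbidden),
#' planted higher-order motifs with per-condition insertion rates, and a
#' log-normal dwell-duration model. Used by [generateCohort()].
#'
#' @slot nPerCondition integer; individuals per condition.
#' @slot conditions character vector of condition labels.
#' @slot alphabetSize integer; base alphabet size (default 90).
#' @slot seqLength integer; warped-sequence length per individual.
#' @slot baseModel a [MarkovModel-class], or the string `"uniform"`.
#' @slot plantedMotifs list; each element a list with `motif` (integer
#'   vector, no adjacent equal labels) and `rates` (named numeric, insertion
#'   rate per symbol for each condition).
#' @slot seed integer scalar or NA; master seed for reproducibility.
#' @export
setClass("CohortSpec",
  representation(nPerCondition = "integer", conditions = "character",
                 alphabetSize = "integer", seqLength = "integer",
                 baseModel = "ANY", plantedMotifs = "list", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@conditions) < 1L || anyDuplicated(object@conditions))
    msg <- c(msg, "conditions must be distinct labels")
  if (length(object@nPerCondition) != 1L || object@nPerCondition < 1L)
    msg <- c(msg, "nPerCondition must be a single positive integer")
  if (object@seqLength < 2L) msg <- c(msg, "seqLength must be >= 2")
  if (!(identical(object@baseModel, "uniform") || is(object@baseModel, "MarkovModel")))
    msg <- c(msg, "baseModel must be 'uniform' or a MarkovModel")
  for (pm in object@plantedMotifs) {
    m <- pm$motif
    if (is.null(m) || is.null(pm$rates) || any(pm$rates < 0))
      msg <- c(msg, "each planted motif needs a motif and non-negative rates")
    else {
      if (length(m) > 1L && any(m[-1L] == m[-length(m)]))
        msg <- c(msg, "planted motifs must have no adjacent equal labels")
      if (length(m) > object@seqLength)
        msg <- c(msg, "planted motif longer than the sequence")
      if (!all(object@conditions %in% names(pm$rates)))
        msg <- c(msg, "planted motif rates must name every condition")
    }
  }
  if (length(msg)) msg else TRUE
})

#' A generated synthetic cohort
#'
#' Sequences, condition labels and the ground-truth planted-motif table
#' produced by [generateCohort()], together with the generating
#' [CohortSpec-class].
#'
#' @slot sequences list of [WarpedSequence-class], one per individual.
#' @slot conditions character; per-individual condition labels.
#' @slot truth data.frame of planted motifs and per-condition rates.
#' @slot spec the generating [CohortSpec-class].
#' @export
setClass("BehaviourCohort",
  representation(sequences = "list", conditions = "character",
                 truth = "data.frame", spec = "CohortSpec"))

setValidity("BehaviourCohort", function(object) {
  if (length(object@sequences) != length(object@conditions))
    return("one condition label per sequence required")
  if (!all(vapply(object@sequences, is, logical(1), "WarpedSequence")))
    return("sequences must be WarpedSequence objects")
  TRUE
})
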