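#' Construct a cohort specification
#'
#' Describes the synthetic study design: a multi-condition cohort of
#' time-warped sequences with first-order Markov base structure (or uniform
#' sampling without adjacent repeats) plus planted higher-order motifs whose
#' insertion rate may differ between conditions.
#'
#' @param nPerCondition individuals per condition (default 20).
#' @param conditions condition labels (default `c("A", "B")`).
#' @param alphabetSize base alphabet size (default 90, the posture-template
#'   count).
#' @param seqLength warped-sequence length per individual (default 2000).
#' @param baseModel a [MarkovModel-class], or `"uniform"`; default is
#'   [defaultBaseModel()] over the alphabet.
#' @param plantedMotifs list of `list(motif =, rates =)` entries: `motif` an
#'   integer vector without adjacent equal labels, `rates` a named numeric
#'   vector of per-symbol insertion rates, one per condition.
#' @param seed master seed; every random choice in [generateCohort()] flows
#'   from it.
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(nPerCondition = 20L, conditions = c("A", "B"),
                       alphabetSize = 90L, seqLength = 2000L,
                       baseModel = defaultBaseModel(alphabetSize),
                       plantedMotifs = list(), seed = NA_integer_) {
  new("CohortSpec", nPerCondition = as.integer(nPerCondition),
      conditions = as.character(conditions),
      alphabetSize = as.integer(alphabetSize),
      seqLength = as.integer(seqLength), baseModel = baseModel,
      plantedMotifs = plantedMotifs, seed = as.integer(seed))
}

#' Default first-order Markov base model
#'
#' A locally structured transition model emulating the short-range order of
#' real behavioural sequences: each state concentrates a fixed probability
#' mass (default 0.7) on a few preferred successor states (default 5,
#' chosen reproducibly from `seed`), with the remainder spread uniformly
#' over the other states. The diagonal is zero, so simulated sequences are
#' valid warped sequences. Sequences from this model are more compressible
#' than uniform noise but far less than deterministic cycles.
#'
#' @param alphabetSize number of states (default 90).
#' @param nPreferred preferred successors per state.
#' @param preferredMass total probability on the preferred successors.
#' @param seed seed for the choice of preferred successors.
#' @return a [MarkovModel-class].
#' @export
defaultBaseModel <- function(alphabetSize = 90L, nPreferred = 5L,
                             preferredMass = 0.7, seed = 2016L) {
  k <- as.integer(alphabetSize)
  stopifnot(k >= 3L, nPreferred < k, preferredMass > 0, preferredMass < 1)
  P <- withr::with_seed(seed, {
    M <- matrix(0, k, k)
    for (i in seq_len(k)) {
      pref <- sample(setdiff(seq_len(k), i), nPreferred)
      M[i, pref] <- preferredMass / nPreferred
      rest <- setdiff(seq_len(k), c(i, pref))
      M[i, rest] <- (1 - preferredMass) / length(rest)
    }
    M
  })
  new("MarkovModel", states = seq_len(k), transMatrix = P,
      initDist = rep(1 / k, k))
}

# uniform labels with adjacent repeats forbidden (valid warped sequence)
.uniform_norepeat <- function(alphabet, n) {
  out <- integer(n)
  out[1L] <- sample.int(alphabet, 1L)
  if (n > 1L) for (t in 2:n) {
    s <- sample.int(alphabet - 1L, 1L)
    out[t] <- if (s >= out[t - 1L]) s + 1L else s
  }
  out
}

# splice motif copies into a label sequence at the given insertion points,
# dropping the flanking base symbol where a splice would create an adjacent
# repeat (the motif itself is kept intact)
.splice_motifs <- function(lab, motif, points) {
  for (p in sort(points, decreasing = TRUE)) {
    left <- lab[seq_len(p)]
    right <- if (p < length(lab)) lab[(p + 1L):length(lab)] else integer()
    if (length(left) && left[length(left)] == motif[1L])
      left <- left[-length(left)]
    if (length(right) && right[1L] == motif[length(motif)])
      right <- right[-1L]
    lab <- c(left, motif, right)
  }
  lab
}

#' Generate a synthetic cohort
#'
#' For each individual: simulates the base model, splices in each planted
#' motif at a Poisson number of uniformly placed positions (expected count =
#' rate x sequence length for the individual's condition), repairs any
#' adjacent-equal labels created at splice boundaries by dropping the
#' flanking base symbol, trims to the specified length, and draws log-normal
#' dwell durations (median 3 frames). Fully reproducible from the spec seed.
#'
#' @param spec a [CohortSpec-class].
#' @return a [BehaviourCohort-class]; its `truth` slot tabulates every
#'   planted motif with its per-condition insertion rate.
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  gen <- function() {
    conds <- rep(spec@conditions, each = spec@nPerCondition)
    seqs <- vector("list", length(conds))
    for (i in seq_along(conds)) {
      # base needs headroom: trimming after insertion must not fall short
      lab <- if (identical(spec@baseModel, "uniform")) {
        .uniform_norepeat(spec@alphabetSize, spec@seqLength)
      } else {
        m <- spec@baseModel
        k <- length(m@states)
        out <- integer(spec@seqLength)
        cur <- sample.int(k, 1L, prob = m@initDist)
        out[1L] <- cur
        if (spec@seqLength > 1L) for (t in 2:spec@seqLength) {
          cur <- sample.int(k, 1L, prob = m@transMatrix[cur, ])
          out[t] <- cur
        }
        m@states[out]
      }
      for (pm in spec@plantedMotifs) {
        rate <- pm$rates[[conds[i]]]
        if (rate <= 0) next
        nIns <- rpois(1L, rate * spec@seqLength)
        if (nIns == 0L) next
        pts <- sample.int(length(lab), min(nIns, length(lab)))
        lab <- .splice_motifs(lab, as.integer(pm$motif), pts)
      }
      lab <- head(lab, spec@seqLength)
      dur <- pmax(1, round(rlnorm(length(lab), meanlog = log(3), sdlog = 0.6)))
      seqs[[i]] <- WarpedSequence(lab, dur, spec@alphabetSize)
    }
    list(seqs = seqs, conds = conds)
  }
  out <- if (is.na(spec@seed)) gen() else withr::with_seed(spec@seed, gen())
  truth <- do.call(rbind, lapply(spec@plantedMotifs, function(pm) {
    data.frame(motif = .motif_key(pm$motif),
               condition = spec@conditions,
               rate = as.numeric(pm$rates[spec@conditions]))
  }))
  if (is.null(truth))
    truth <- data.frame(motif = character(), condition = character(),
                        rate = numeric())
  new("BehaviourCohort", sequences = out$seqs, conditions = out$conds,
      truth = truth, spec = spec)
}

#' BehaviourCohort accessors
#'
#' @param x a [BehaviourCohort-class].
#' @return `cohortSequences()`: list of [WarpedSequence-class];
#'   `cohortTruth()`: the planted-motif ground-truth table.
#' @export
cohortSequences <- function(x) {
  stopifnot(is(x, "BehaviourCohort"))
  x@sequences
}

#' @rdname cohortSequences
#' @export
cohortTruth <- function(x) {
  stopifnot(is(x, "BehaviourCohort"))
  x@truth
}

#' @rdname cgram-generics
#' @export
setMethod("conditions", "BehaviourCohort", function(x) x@conditions)

setMethod("show", "BehaviourCohort", function(object) {
  cat(sprintf("BehaviourCohort: %d individuals (%s), length %d, alphabet %d, %d planted motif(s)\n",
              length(object@sequences),
              paste(sprintf("%s x %d", object@spec@conditions,
                            object@spec@nPerCondition), collapse = ", "),
              object@spec@seqLength, object@spec@alphabetSize,
              length(object@spec@plantedMotifs)))
})

#' Emit a noisy descriptor stream for a label sequence
#'
#' For every frame of the expanded sequence, emits the frame's template
#' descriptor plus isotropic Gaussian noise — a synthetic posture stream for
#' exercising [discretize()].
#'
#' @param templates a [TemplateSet-class].
#' @param x a [WarpedSequence-class] over `1..nrow(templates)`.
#' @param noiseSd standard deviation of the added noise (>= 0).
#' @param seed optional integer seed.
#' @return numeric matrix, one frame per row.
#' @export
generateDescriptorStream <- function(templates, x, noiseSd = 0, seed = NULL) {
  stopifnot(is(templates, "TemplateSet"), is(x, "WarpedSequence"),
            noiseSd >= 0)
  frames <- expandSequence(x)
  if (max(frames) > nrow(templates@templates))
    stop("sequence labels exceed the number of templates")
  draw <- function() {
    m <- templates@templates[frames, , drop = FALSE]
    if (noiseSd > 0)
      m <- m + matrix(stats::rnorm(length(m), sd = noiseSd), nrow(m))
    m
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
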