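#' Construct a WarpedSequence
#'
#' @param labels integer vector of state labels (no two adjacent equal).
#' @param durations per-element dwell times; defaults to 1 per element.
#' @param alphabetSize number of possible base labels; defaults to 90 (the
#'   canonical posture-template count) or to the largest label if larger.
#' @return a [WarpedSequence-class].
#' @examples
#' ws <- WarpedSequence(c(1L, 2L, 3L, 1L), durations = c(1, 2, 1, 3))
#' seqLabels(ws)
#' @export
WarpedSequence <- function(labels, durations = rep(1, length(labels)),
                           alphabetSize = NULL) {
  labels <- as.integer(labels)
  if (is.null(alphabetSize))
    alphabetSize <- max(90L, labels, na.rm = FALSE)
  if (length(labels) == 0L) alphabetSize <- max(90L, as.integer(alphabetSize))
  new("WarpedSequence", labels = labels, durations = as.numeric(durations),
      alphabetSize = as.integer(alphabetSize))
}

#' Construct a TemplateSet
#'
#' @param templates numeric matrix with one template descriptor per row
#'   (e.g. 90 rows of 49 midline angles), or a list of equal-length vectors.
#' @return a [TemplateSet-class].
#' @export
TemplateSet <- function(templates) {
  if (is.list(templates)) {
    d <- unique(lengths(templates))
    if (length(d) != 1L) stop("all templates must have the same dimension")
    templates <- do.call(rbind, templates)
  }
  new("TemplateSet", templates = as.matrix(templates))
}

#' @rdname cgram-generics
#' @export
setMethod("seqLabels", "WarpedSequence", function(x) x@labels)

#' @rdname cgram-generics
#' @export
setMethod("durations", "WarpedSequence", function(x) x@durations)

#' @rdname cgram-generics
#' @export
setMethod("alphabetSize", "WarpedSequence", function(x) x@alphabetSize)

#' @describeIn WarpedSequence number of (warped) elements, i.e. the
#'   uncompressed length l.
#' @param x a WarpedSequence.
#' @export
setMethod("length", "WarpedSequence", function(x) length(x@labels))

setMethod("show", "WarpedSequence", function(object) {
  n <- length(object)
  cat(sprintf("WarpedSequence of length %d over alphabet 1..%d\n",
              n, object@alphabetSize))
  if (n) {
    k <- min(n, 12L)
    cat("  labels:    ", paste(object@labels[seq_len(k)], collapse = " "),
        if (n > k) "..." else "", "\n")
    cat("  durations: ", paste(format(object@durations[seq_len(k)]),
                               collapse = " "),
        if (n > k) "..." else "", "\n")
  }
})

setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet: %d templates of dimension %d\n",
              nrow(object@templates), ncol(object@templates)))
})

#' Accessors for TemplateSet
#'
#' @param x a [TemplateSet-class].
#' @return `templates()` returns the template matrix (one row per template);
#'   `templateDim()` its descriptor dimension.
#' @export
templates <- function(x) {
  stopifnot(is(x, "TemplateSet"))
  x@templates
}

#' @rdname templates
#' @export
templateDim <- function(x) {
  stopifnot(is(x, "TemplateSet"))
  ncol(x@templates)
}

#' Collapse consecutive repeats (non-uniform time warping)
#'
#' Merges runs of identical labels into single elements, recording the dwell
#' duration of each run, so that behaviours performed at different speeds
#' map onto the same label sequence. For example `{1,2,3,1,1,1,4,1}` is
#' reduced to `{1,2,3,1,4,1}` with durations `{1,1,1,3,1,1}` (at unit frame
#' interval). Expanding the result by its durations reproduces the input
#' exactly; see [expandSequence()].
#'
#' @param labels integer vector of raw per-frame state labels (all >= 1).
#' @param frameInterval time per frame; durations are run lengths multiplied
#'   by this (default 1, i.e. durations in frames).
#' @param alphabetSize passed to [WarpedSequence()].
#' @return a [WarpedSequence-class]; empty input gives an empty sequence.
#' @examples
#' ws <- collapseRepeats(c(1, 2, 3, 1, 1, 1, 4, 1))
#' seqLabels(ws)   # 1 2 3 1 4 1
#' durations(ws)   # 1 1 1 3 1 1
#' @export
collapseRepeats <- function(labels, frameInterval = 1, alphabetSize = NULL) {
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 1L))
    stop("labels must be positive integers")
  if (length(labels) == 0L)
    return(WarpedSequence(integer(), numeric(), alphabetSize))
  r <- rle(labels)
  WarpedSequence(r$values, r$lengths * frameInterval, alphabetSize)
}

#' Expand a warped sequence back to per-frame labels
#'
#' Inverse of [collapseRepeats()]: repeats each label
#' `round(duration / frameInterval)` times.
#'
#' @param x a [WarpedSequence-class].
#' @param frameInterval time per frame used when the sequence was collapsed.
#' @return integer vector of per-frame labels.
#' @export
expandSequence <- function(x, frameInterval = 1) {
  stopifnot(is(x, "WarpedSequence"))
  rep(x@labels, times = as.integer(round(x@durations / frameInterval)))
}

#' Discretize continuous posture descriptors against a template set
#'
#' Assigns each frame the 1-based index of the template minimizing the
#' Euclidean distance to its descriptor vector. Ties are broken towards the
#' lowest template index, making the assignment deterministic.
#'
#' @param descriptors numeric matrix, one frame per row (columns = descriptor
#'   dimension, e.g. 49 midline angles).
#' @param templates a [TemplateSet-class] of matching dimension.
#' @return integer vector of template labels, one per frame; empty input
#'   gives an empty vector.
#' @examples
#' ts <- TemplateSet(diag(2))
#' discretize(matrix(c(0.9, 0.1), 1), ts)  # 1
#' @export
discretize <- function(descriptors, templates) {
  stopifnot(is(templates, "TemplateSet"))
  tm <- templates@templates
  if (is.null(dim(descriptors)))
    descriptors <- matrix(descriptors, nrow = 1L)
  descriptors <- as.matrix(descriptors)
  if (nrow(descriptors) == 0L) return(integer())
  if (ncol(descriptors) != ncol(tm))
    stop(sprintf("descriptor dimension (%d) does not match template dimension (%d)",
                 ncol(descriptors), ncol(tm)))
  # squared Euclidean distances via the expansion |x - t|^2 = |x|^2 - 2 x.t + |t|^2;
  # |x|^2 is constant per frame so argmin needs only the cross term and |t|^2
  cross <- descriptors %*% t(tm)                      # frames x templates
  d2 <- sweep(-2 * cross, 2L, rowSums(tm^2), "+")
  # max.col(-d2, "first") breaks exact ties towards the lowest index, but is
  # sensitive to float noise in the expansion; snap near-ties first
  apply(d2, 1L, function(r) {
    m <- min(r)
    which(r <= m + 1e-9 * max(1, abs(m)))[1L]
  })
}
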