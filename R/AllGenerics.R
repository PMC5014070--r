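#' @name cgram-generics
#' @title Generics defined by cgram
#' @description S4 generics for the sequence-compression data model.
#' @param x,object an object of the relevant class.
#' @param ... passed to methods.
#' @keywords internal
NULL

#' @rdname cgram-generics
#' @export
setGeneric("seqLabels", function(x) standardGeneric("seqLabels"))

#' @rdname cgram-generics
#' @export
setGeneric("durations", function(x) standardGeneric("durations"))

#' @rdname cgram-generics
#' @export
setGeneric("alphabetSize", function(x) standardGeneric("alphabetSize"))

#' Compress a label sequence with the offline compressive heuristic
#'
#' @param x a [WarpedSequence-class] or a plain integer label vector.
#' @param wMax maximum subsequence length considered per iteration
#'   (default 10).
#' @param ... unused.
#' @return a [CompressionResult-class].
#' @export
setGeneric("compress", function(x, wMax = 10L, ...) standardGeneric("compress"))

#' @rdname cgram-generics
#' @export
setGeneric("rules", function(x) standardGeneric("rules"))

#' @rdname cgram-generics
#' @export
setGeneric("compressedSequence", function(x) standardGeneric("compressedSequence"))

#' @rdname cgram-generics
#' @export
setGeneric("uncompressedLength", function(x) standardGeneric("uncompressedLength"))

#' @rdname cgram-generics
#' @export
setGeneric("compressibility", function(x) standardGeneric("compressibility"))

#' @rdname cgram-generics
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))
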