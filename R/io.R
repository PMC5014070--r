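.prov_header <- function(kind) {
  sprintf("# cgram %s %s", as.character(packageVersion("cgram")), kind)
}

# write via a temporary file in the same directory, then rename: readers
# never observe a partially written output
.atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop(sprintf("could not write '%s'", path))
  invisible(path)
}

.read_lines_nocomment <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  ln <- readLines(path, warn = FALSE)
  ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
}

#' Read and write label sequence files
#'
#' The on-disk format is auto-detected on read: either one integer label per
#' line, a single line of whitespace- or comma-separated labels, or two
#' whitespace-separated columns (label, dwell duration). Lines starting with
#' `#` are comments. The writer emits the two-column form with a provenance
#' header.
#'
#' @param path file path.
#' @param alphabetSize passed to [WarpedSequence()] on read.
#' @return `readLabelSequence()` returns a [WarpedSequence-class] (unit
#'   durations when the file has none). A duration-free file containing
#'   adjacent repeats is treated as a raw frame stream and collapsed via
#'   [collapseRepeats()] (with a message); adjacent repeats alongside an
#'   explicit duration column are an error.
#' @export
readLabelSequence <- function(path, alphabetSize = NULL) {
  raw <- .read_seq_file(path)
  lab <- raw$labels
  has_rep <- length(lab) > 1L && any(lab[-1L] == lab[-length(lab)])
  if (has_rep) {
    if (!is.null(raw$durations))
      stop(sprintf("'%s': adjacent repeated labels with explicit durations; not a warped sequence",
                   path))
    message(sprintf("readLabelSequence: '%s' contains adjacent repeats; collapsing",
                    path))
    return(collapseRepeats(lab, alphabetSize = alphabetSize))
  }
  if (is.null(raw$durations)) WarpedSequence(lab, alphabetSize = alphabetSize)
  else WarpedSequence(lab, raw$durations, alphabetSize)
}

# parse a sequence file into labels (+ optional durations), without any
# warping semantics
.read_seq_file <- function(path) {
  ln <- .read_lines_nocomment(path)
  if (length(ln) == 0L) return(list(labels = integer(), durations = NULL))
  tok <- lapply(ln, function(s)
    strsplit(trimws(gsub(",", " ", s)), "\\s+")[[1L]])
  ncols <- unique(lengths(tok))
  bad <- function(i, why) stop(sprintf("malformed sequence file '%s' line %d: %s",
                                       path, i, why))
  if (length(ln) == 1L && ncols > 2L) {        # single-line form
    v <- suppressWarnings(as.numeric(tok[[1L]]))
    if (anyNA(v)) bad(1L, "non-numeric label")
    return(list(labels = as.integer(v), durations = NULL))
  }
  if (!all(ncols %in% c(1L, 2L)) || length(ncols) != 1L) {
    i <- which(lengths(tok) != lengths(tok)[1L])[1L]
    bad(if (is.na(i)) 1L else i, "inconsistent column count")
  }
  lab <- suppressWarnings(as.numeric(vapply(tok, `[`, character(1), 1L)))
  if (anyNA(lab)) bad(which(is.na(lab))[1L], "non-numeric label")
  dur <- NULL
  if (ncols == 2L) {
    dur <- suppressWarnings(as.numeric(vapply(tok, `[`, character(1), 2L)))
    if (anyNA(dur)) bad(which(is.na(dur))[1L], "non-numeric duration")
  }
  list(labels = as.integer(lab), durations = dur)
}

#' @rdname readLabelSequence
#' @param x a [WarpedSequence-class].
#' @export
writeLabelSequence <- function(x, path) {
  stopifnot(is(x, "WarpedSequence"))
  .atomic_write(path, function(tmp) {
    writeLines(c(.prov_header("sequence"),
                 paste(x@labels, format(x@durations, trim = TRUE,
                                        scientific = FALSE))), tmp)
  })
}

#' Read and write compression dictionaries
#'
#' JSON is the round-trippable machine format (the reader reconstructs the
#' full [CompressionResult-class]); TSV is a flat per-rule table (symbol,
#' hyphen-joined body, W, N, savings, comma-joined occurrence starts in
#' iteration and original coordinates).
#'
#' @param result a [CompressionResult-class].
#' @param path file path.
#' @param format `"json"` or `"tsv"`.
#' @export
writeDictionary <- function(result, path, format = c("json", "tsv")) {
  stopifnot(is(result, "CompressionResult"))
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      generator = .prov_header("dictionary"),
      alphabetSize = result@alphabetSize, l = result@l,
      compressibility = result@compressibility,
      compressed = result@compressed,
      rules = lapply(result@rules, function(r)
        list(symbol = r@symbol, body = r@body, W = r@W, N = r@N,
             savings = r@savings, starts = r@starts,
             origStarts = r@origStarts)))
    .atomic_write(path, function(tmp)
      jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA))
  } else {
    rows <- vapply(result@rules, function(r) {
      paste(r@symbol, paste(r@body, collapse = "-"), r@W, r@N, r@savings,
            paste(r@starts, collapse = ","),
            paste(r@origStarts, collapse = ","), sep = "\t")
    }, character(1))
    .atomic_write(path, function(tmp)
      writeLines(c(.prov_header("dictionary"),
                   paste("symbol", "body", "W", "N", "savings", "starts",
                         "origStarts", sep = "\t"), rows), tmp))
  }
}

#' @rdname writeDictionary
#' @return `readDictionary()` returns the [CompressionResult-class]
#'   serialized by `writeDictionary(..., format = "json")`.
#' @export
readDictionary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pick <- function(col, i) {          # columns may simplify to matrix/list
    if (is.matrix(col)) col[i, ] else if (is.list(col)) col[[i]] else col[i]
  }
  rl <- list()
  if (length(obj$rules)) {
    rr <- obj$rules
    rl <- lapply(seq_len(nrow(rr)), function(i) {
      new("Rule", symbol = as.integer(pick(rr$symbol, i)),
          body = as.integer(pick(rr$body, i)),
          W = as.integer(pick(rr$W, i)), N = as.integer(pick(rr$N, i)),
          savings = as.integer(pick(rr$savings, i)),
          starts = as.integer(pick(rr$starts, i)),
          origStarts = as.integer(pick(rr$origStarts, i)))
    })
  }
  new("CompressionResult", compressed = as.integer(obj$compressed),
      rules = rl, l = as.integer(obj$l),
      compressibility = as.numeric(obj$compressibility),
      alphabetSize = as.integer(obj$alphabetSize))
}

#' Export arc diagrams and dendrograms
#'
#' Arcs are written as TSV or JSON; dendrograms as JSON (their natural
#' nested form).
#'
#' @param arcs the data.frame from [arcDiagram()].
#' @param path file path.
#' @param format `"tsv"` or `"json"`.
#' @export
writeArcs <- function(arcs, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    .atomic_write(path, function(tmp)
      jsonlite::write_json(arcs, tmp, digits = NA))
  } else {
    .atomic_write(path, function(tmp) {
      con <- file(tmp, "w")
      on.exit(close(con))
      writeLines(.prov_header("arcs"), con)
      write.table(arcs, con, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }
}

#' @rdname writeArcs
#' @param dendro a nested list from [cgramDendrogram()].
#' @export
writeDendrogram <- function(dendro, path) {
  .atomic_write(path, function(tmp)
    jsonlite::write_json(dendro, tmp, auto_unbox = TRUE, digits = NA))
}

#' Read and write Markov models
#'
#' A delimited numeric table: a `state` column, one transition-probability
#' column per state (header row carries the state labels), and a final
#' `init` column with the initial distribution.
#'
#' @param model a [MarkovModel-class].
#' @param path file path.
#' @export
writeMarkovModel <- function(model, path) {
  stopifnot(is(model, "MarkovModel"))
  df <- data.frame(state = model@states, model@transMatrix,
                   init = model@initDist, check.names = FALSE)
  names(df) <- c("state", as.character(model@states), "init")
  .atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(.prov_header("markov"), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' @rdname writeMarkovModel
#' @export
readMarkovModel <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE)
  states <- as.integer(df$state)
  P <- as.matrix(df[, as.character(states), drop = FALSE])
  dimnames(P) <- NULL
  new("MarkovModel", states = states, transMatrix = P,
      initDist = as.numeric(df$init))
}

#' Read and write motif tables
#'
#' One row per motif (hyphen-joined base labels, length, origin) and one
#' count column per individual; each individual's condition and warped
#' sequence length are carried in structured header comments so the table
#' round-trips to an identical [MotifTable-class].
#'
#' @param table a [MotifTable-class].
#' @param path file path.
#' @export
writeMotifTable <- function(table, path) {
  stopifnot(is(table, "MotifTable"))
  cd <- colData(table)
  df <- data.frame(motif = motifLabels(table), length = motifLength(table),
                   origin = motifOrigin(table),
                   as.data.frame(assay(table, "count")), check.names = FALSE)
  .atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(c(.prov_header("motifs"),
                 paste("#condition", paste(rownames(cd), collapse = "\t"),
                       paste(cd$condition, collapse = "\t"), sep = "\t"),
                 paste("#seqLength", paste(cd$seqLength, collapse = "\t"),
                       sep = "\t")), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' @rdname writeMotifTable
#' @export
readMotifTable <- function(path) {
  ln <- readLines(path, warn = FALSE)
  condLine <- ln[grepl("^#condition\t", ln)]
  lenLine <- ln[grepl("^#seqLength\t", ln)]
  if (length(condLine) != 1L || length(lenLine) != 1L)
    stop(sprintf("'%s' is not a cgram motif table", path))
  ct <- strsplit(sub("^#condition\t", "", condLine), "\t")[[1L]]
  nInd <- length(ct) / 2L
  individuals <- ct[seq_len(nInd)]
  conds <- ct[nInd + seq_len(nInd)]
  lens <- as.integer(strsplit(sub("^#seqLength\t", "", lenLine), "\t")[[1L]])
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, colClasses = c(motif = "character"))
  counts <- as.matrix(df[, individuals, drop = FALSE])
  storage.mode(counts) <- "integer"
  motifs <- lapply(df$motif, .parse_motif)
  .make_motif_table(motifs, counts, lens, conds, df$origin, individuals)
}

#' Write a comparison result table
#'
#' @param result a [ComparisonResult-class].
#' @param path file path.
#' @export
writeComparison <- function(result, path) {
  stopifnot(is(result, "ComparisonResult"))
  .atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(c(.prov_header("comparison"),
                 sprintf("#fdrLevel\t%g", result@fdrLevel)), con)
    write.table(as.data.frame(result@table), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
}

#' Read and write per-individual condition tables
#'
#' Two tab-separated columns: `individual`, `condition`.
#'
#' @param conditions named character vector (names = individuals) or a
#'   data.frame with columns `individual` and `condition`.
#' @param path file path.
#' @export
writeConditions <- function(conditions, path) {
  if (!is.data.frame(conditions))
    conditions <- data.frame(individual = names(conditions),
                             condition = unname(conditions))
  .atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(.prov_header("conditions"), con)
    write.table(conditions, con, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' @rdname writeConditions
#' @return `readConditions()` returns a named character vector
#'   (names = individuals).
#' @export
readConditions <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character")
  setNames(df$condition, df$individual)
}

#' Read and write cohort specifications (YAML)
#'
#' All fields of the [CohortSpec-class], including an embedded Markov base
#' model when one is used, serialize to a single YAML document.
#'
#' @param spec a [CohortSpec-class].
#' @param path file path.
#' @export
writeCohortSpec <- function(spec, path) {
  stopifnot(is(spec, "CohortSpec"))
  bm <- if (identical(spec@baseModel, "uniform")) "uniform" else
    list(states = spec@baseModel@states,
         transMatrix = apply(spec@baseModel@transMatrix, 1L, c,
                             simplify = FALSE),
         initDist = spec@baseModel@initDist)
  obj <- list(nPerCondition = spec@nPerCondition,
              conditions = as.list(spec@conditions),
              alphabetSize = spec@alphabetSize, seqLength = spec@seqLength,
              baseModel = bm,
              plantedMotifs = lapply(spec@plantedMotifs, function(pm)
                list(motif = pm$motif, rates = as.list(pm$rates))),
              seed = if (is.na(spec@seed)) NULL else spec@seed)
  .atomic_write(path, function(tmp)
    yaml::write_yaml(obj, tmp, precision = 15L))
}

#' @rdname writeCohortSpec
#' @export
readCohortSpec <- function(path) {
  obj <- yaml::read_yaml(path)
  bm <- if (identical(obj$baseModel, "uniform")) "uniform" else {
    P <- do.call(rbind, lapply(obj$baseModel$transMatrix, as.numeric))
    P <- P / rowSums(P)                       # undo serialization rounding
    init <- as.numeric(obj$baseModel$initDist)
    new("MarkovModel", states = as.integer(obj$baseModel$states),
        transMatrix = P, initDist = init / sum(init))
  }
  pms <- lapply(obj$plantedMotifs, function(pm)
    list(motif = as.integer(pm$motif), rates = unlist(pm$rates)))
  cohortSpec(nPerCondition = obj$nPerCondition,
             conditions = unlist(obj$conditions),
             alphabetSize = obj$alphabetSize, seqLength = obj$seqLength,
             baseModel = bm, plantedMotifs = pms,
             seed = if (is.null(obj$seed)) NA_integer_ else obj$seed)
}

#' Write a generated cohort to a directory
#'
#' One two-column sequence file per individual (`<individual>.seq`), a
#' `conditions.tsv` table, and the planted-motif ground truth
#' (`truth.tsv`).
#'
#' @param cohort a [BehaviourCohort-class].
#' @param dir output directory (created if missing).
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "BehaviourCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ind <- sprintf("ind%02d", seq_along(cohort@sequences))
  for (i in seq_along(ind))
    writeLabelSequence(cohort@sequences[[i]],
                       file.path(dir, paste0(ind[i], ".seq")))
  writeConditions(setNames(cohort@conditions, ind),
                  file.path(dir, "conditions.tsv"))
  .atomic_write(file.path(dir, "truth.tsv"), function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(.prov_header("truth"), con)
    write.table(cohort@truth, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  invisible(dir)
}

#' @rdname writeCohort
#' @return `readCohort()` returns a list with `sequences` (named list of
#'   [WarpedSequence-class]) and `conditions` (named character vector).
#' @export
readCohort <- function(dir) {
  cond <- readConditions(file.path(dir, "conditions.tsv"))
  seqs <- lapply(names(cond), function(i)
    readLabelSequence(file.path(dir, paste0(i, ".seq"))))
  names(seqs) <- names(cond)
  list(sequences = seqs, conditions = cond)
}
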