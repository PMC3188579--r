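#' Read an experiment design manifest
#'
#' The manifest is a tab-delimited file with columns `replicate_id`,
#' `treatment`, `path` describing one read file per replicate.
#'
#' @param x path to the manifest, or a data.frame with those columns.
#' @return validated design data.frame.
#' @export
read_design <- function(x) {
  d <- if (is.data.frame(x)) x else read_tsv(x)
  abort_if(!all(c("replicate_id", "treatment", "path") %in% names(d)),
           "design needs columns replicate_id, treatment, path")
  abort_if(anyDuplicated(d$replicate_id) > 0, "duplicate replicate_ids")
  abort_if(any(is.na(d$treatment) | d$treatment == ""),
           "every replicate needs a treatment label")
  d$replicate_id <- as.character(d$replicate_id)
  d$treatment <- as.character(d$treatment)
  d
}

#' Read sequences from FASTA or FASTQ
#'
#' Qualities in FASTQ input are read and discarded; only fixed-position
#' trimming is supported downstream.
#'
#' @param path input file; format detected from the first character.
#' @return character vector of read sequences.
#' @export
read_seqs <- function(path) {
  first <- readLines(path, n = 1L)
  fmt <- if (length(first) && startsWith(first, "@")) "fastq" else "fasta"
  if (length(first) == 0L) return(character(0))
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}

#' Trim fixed head and tail positions from reads
#'
#' Removes `head` bases from the 5' end and `tail` bases from the 3' end of
#' every read (the pipeline default emulates removing the first six and last
#' five cycles of a short Illumina read). Reads whose post-trim length falls
#' below `min_length` are dropped and tallied.
#'
#' @param reads character vector of read sequences.
#' @param head,tail non-negative trim widths.
#' @param min_length minimum retained post-trim length (default 20).
#' @return character vector of trimmed reads; attribute `dropped` counts the
#'   reads removed for being too short.
#' @export
trim_reads <- function(reads, head = 6L, tail = 5L, min_length = 20L) {
  stopifnot(head >= 0L, tail >= 0L)
  n <- nchar(reads)
  newlen <- n - head - tail
  keep <- newlen >= min_length
  out <- substr(reads[keep], head + 1L, n[keep] - tail)
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Collapse reads to unique sequences with per-replicate occurrences
#'
#' Identifies each distinct post-trim sequence and counts its occurrences in
#' every replicate. Reads containing non-ACGT symbols are excluded and
#' tallied, matching the aligner's own exclusion rule. Read ids are assigned
#' in lexicographic sequence order so a store is byte-reproducible regardless
#' of input read order.
#'
#' @param reads_by_replicate named list (replicate_id -> character vector of
#'   trimmed reads).
#' @param design optional design data.frame; if given, replicate order and
#'   completeness are taken from it.
#' @return object of class `read_store`: list with `sequences` (named
#'   character vector read_id -> sequence), `occurrences` (matrix unique read
#'   x replicate), `ambiguous` and `dropped` per-replicate tallies.
#' @export
collapse_reads <- function(reads_by_replicate, design = NULL) {
  reps <- if (!is.null(design)) design$replicate_id else names(reads_by_replicate)
  abort_if(is.null(reps) || !all(reps %in% names(reads_by_replicate)),
           "replicates named in the design are missing from the input")
  ambiguous <- stats::setNames(integer(length(reps)), reps)
  dropped <- stats::setNames(integer(length(reps)), reps)
  clean <- list()
  for (r in reps) {
    v <- reads_by_replicate[[r]]
    if (!length(v)) warning("replicate '", r, "' has no reads")
    dropped[r] <- attr(v, "dropped") %||% 0L
    ok <- is_acgt(v)
    ambiguous[r] <- sum(!ok)
    clean[[r]] <- v[ok]
  }
  all_seqs <- sort(unique(unlist(clean, use.names = FALSE)))
  occ <- matrix(0L, nrow = length(all_seqs), ncol = length(reps),
                dimnames = list(NULL, reps))
  for (r in reps) {
    tb <- table(factor(clean[[r]], levels = all_seqs))
    occ[, r] <- as.integer(tb)
  }
  ids <- sprintf("r%06d", seq_along(all_seqs))
  rownames(occ) <- ids
  structure(list(
    sequences = stats::setNames(all_seqs, ids),
    occurrences = occ,
    ambiguous = ambiguous,
    dropped = dropped
  ), class = "read_store")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.read_store <- function(x, ...) {
  cat("Read store:", length(x$sequences), "unique sequences,",
      ncol(x$occurrences), "replicate(s),",
      sum(x$occurrences), "retained reads\n")
  invisible(x)
}

#' Build a read store from a design manifest
#'
#' Convenience wrapper: reads each replicate's FASTA/FASTQ file, trims, and
#' collapses to a read store.
#'
#' @param design design data.frame or manifest path (see [read_design()]).
#' @param head,tail,min_length trimming parameters (see [trim_reads()]).
#' @return a `read_store`.
#' @export
load_reads <- function(design, head = 6L, tail = 5L, min_length = 20L) {
  design <- read_design(design)
  by_rep <- lapply(stats::setNames(design$path, design$replicate_id),
                   function(p) trim_reads(read_seqs(p), head, tail, min_length))
  collapse_reads(by_rep, design)
}
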