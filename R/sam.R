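#' Write alignment hits as SAM
#'
#' Emits a SAM v1 stream with an @SQ header line per reference sequence and
#' one record per hit. Ungapped alignments only (CIGAR `<L>M`); the mismatch
#' count is carried in the mandatory NM tag. After the first record of a read,
#' further hits are flagged secondary (0x100). Minus-strand records store the
#' reverse complement of the read with flag 0x10, per the SAM convention.
#'
#' @param hits data.frame with read_id, seq_id, pos (0-based), strand,
#'   mismatches.
#' @param reads named character vector mapping read_id to the read sequence.
#' @param seq_lengths named integer vector of reference lengths.
#' @param path optional file to write; if NULL the lines are returned.
#' @return invisibly, the character vector of SAM lines.
#' @export
write_sam <- function(hits, reads, seq_lengths, path = NULL) {
  stopifnot(all(c("read_id", "seq_id", "pos", "strand", "mismatches")
                %in% names(hits)))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                   as.integer(seq_lengths)))
  lines <- hdr
  if (nrow(hits)) {
    o <- order(hits$read_id, hits$seq_id, hits$pos, hits$strand)
    h <- hits[o, , drop = FALSE]
    secondary <- duplicated(h$read_id)
    flag <- ifelse(h$strand == "-", 16L, 0L) + ifelse(secondary, 256L, 0L)
    seqs <- reads[h$read_id]
    abort_if(anyNA(seqs), "hits reference read ids absent from `reads`")
    seqs[h$strand == "-"] <- revcomp(seqs[h$strand == "-"])
    rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                   h$read_id, flag, h$seq_id, h$pos + 1L,
                   nchar(seqs), seqs, h$mismatches)
    lines <- c(lines, rec)
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read SAM alignments
#'
#' Parses a SAM stream produced by [write_sam()] or any SAM-compliant aligner,
#' recovering (read_id, seq_id, pos, strand, mismatches) and the original read
#' sequence. Records referencing a sequence absent from the @SQ header are
#' rejected with their line numbers rather than dropped silently; unmapped
#' records (flag 0x4) are skipped.
#'
#' @param x path to a SAM file, or a character vector of SAM lines.
#' @return data.frame of hits; attributes `seq_lengths` (named integer vector
#'   from the header) and `rejects` (data.frame line/reason).
#' @export
read_sam <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  is_hdr <- startsWith(lines, "@")
  sq <- lines[startsWith(lines, "@SQ")]
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  seq_lengths <- stats::setNames(ln, sn)

  body_idx <- which(!is_hdr & nzchar(lines))
  rej_line <- integer(0); rej_reason <- character(0)
  rows <- vector("list", length(body_idx))
  for (j in seq_along(body_idx)) {
    i <- body_idx[j]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) {
      rej_line <- c(rej_line, i); rej_reason <- c(rej_reason, "malformed record")
      next
    }
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next
    if (!(f[3] %in% sn)) {
      rej_line <- c(rej_line, i)
      rej_reason <- c(rej_reason, paste0("unknown sequence '", f[3], "'"))
      next
    }
    nm <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    minus <- bitwAnd(flag, 16L) != 0L
    rows[[j]] <- data.frame(
      read_id = f[1], seq_id = f[3], pos = as.integer(f[4]) - 1L,
      strand = if (minus) "-" else "+",
      mismatches = if (length(nm)) as.integer(sub("^NM:i:", "", nm[1])) else NA_integer_,
      seq = if (minus) revcomp(f[10]) else f[10],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), seq_id = character(0),
                      pos = integer(0), strand = character(0),
                      mismatches = integer(0), seq = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "seq_lengths") <- seq_lengths
  attr(out, "rejects") <- data.frame(line = rej_line, reason = rej_reason,
                                     stringsAsFactors = FALSE)
  out
}
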