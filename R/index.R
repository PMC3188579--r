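#' Build a hashed two-bit seed index over reference sequences
#'
#' Indexes every full-length word (preamble + 16-base suffix) of every
#' sequence on both strands. Words are keyed by the two-bit integer value of
#' their leading `preamble_length` bases ("preamble containers"); containers
#' for preambles absent from the reference are simply never created. Within a
#' container, entries are sorted ascending by the packed integer value of the
#' 16 bases following the preamble, so membership queries run as a binary
#' search. Windows touching a non-ACGT reference base are not indexed and can
#' never produce alignments.
#'
#' @param sequences named character vector of reference sequences.
#' @param preamble_length container key width in bases (default 12).
#' @param suffix_length bases in the sort key following the preamble
#'   (default 16, packing into a 32-bit value held exactly in a double).
#' @param kinds optional character vector (same length as `sequences`) tagging
#'   each sequence, e.g. "genome" or "junction"; propagated to alignment hits.
#' @return an object of class `two_bit_index`.
#' @export
build_index <- function(sequences, preamble_length = 12L, suffix_length = 16L,
                        kinds = NULL) {
  stopifnot(is.character(sequences), length(sequences) > 0)
  abort_if(is.null(names(sequences)) || anyNA(names(sequences)) ||
             any(names(sequences) == ""), "sequences must be named")
  abort_if(anyDuplicated(names(sequences)) > 0, "duplicate sequence names")
  p <- as.integer(preamble_length)
  s16 <- as.integer(suffix_length)
  word <- p + s16
  nseq <- length(sequences)
  lens <- nchar(sequences)
  if (any(lens < word)) {
    warning(sum(lens < word), " sequence(s) shorter than the word length (",
            word, " nt) were not indexed")
  }

  # per-sequence, per-strand code vectors (9 marks non-ACGT) kept for
  # verification during alignment
  codes <- vector("list", nseq)
  pre_all <- suf_all <- numeric(0)
  seq_all <- pos_all <- str_all <- integer(0)
  for (i in seq_len(nseq)) {
    fwd <- base_codes(sequences[[i]])
    rev <- base_codes(revcomp_na(sequences[[i]]))
    codes[[i]] <- list(ifelse(is.na(fwd), 9L, fwd), ifelse(is.na(rev), 9L, rev))
    if (lens[i] < word) next
    for (st in 1:2) {
      cc <- if (st == 1L) fwd else rev
      pre <- rolling_kmer_values(cc, p)
      suf <- rolling_kmer_values(cc, s16)
      nw <- lens[i] - word + 1L
      pre_w <- pre[seq_len(nw)]
      suf_w <- suf[seq.int(p + 1L, p + nw)]
      keep <- which(!is.na(pre_w) & !is.na(suf_w))
      if (!length(keep)) next
      pre_all <- c(pre_all, pre_w[keep])
      suf_all <- c(suf_all, suf_w[keep])
      seq_all <- c(seq_all, rep.int(i, length(keep)))
      pos_all <- c(pos_all, keep - 1L)       # 0-based start on this strand
      str_all <- c(str_all, rep.int(st, length(keep)))
    }
  }

  containers <- new.env(hash = TRUE, parent = emptyenv())
  if (length(pre_all)) {
    o <- order(pre_all, suf_all, seq_all, str_all, pos_all)
    pre_all <- pre_all[o]; suf_all <- suf_all[o]
    seq_all <- seq_all[o]; pos_all <- pos_all[o]; str_all <- str_all[o]
    grp <- split(seq_along(pre_all), pre_all)
    for (key in names(grp)) {
      ii <- grp[[key]]
      assign(key, list(suf = suf_all[ii], seq = seq_all[ii],
                       pos = pos_all[ii], strand = str_all[ii]),
             envir = containers)
    }
  }

  structure(list(
    preamble_length = p, suffix_length = s16, word_length = word,
    seq_names = names(sequences), seq_lengths = unname(lens),
    seq_kinds = if (is.null(kinds)) rep("genome", nseq) else as.character(kinds),
    codes = codes, containers = containers,
    n_entries = length(pre_all)
  ), class = "two_bit_index")
}

# revcomp that tolerates N (Biostrings complements IUPAC codes)
revcomp_na <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @export
print.two_bit_index <- function(x, ...) {
  cat("Two-bit seed index:", length(x$seq_names), "sequence(s),",
      x$n_entries, "indexed positions\n")
  cat("  preamble", x$preamble_length, "nt + suffix", x$suffix_length,
      "nt (word", x$word_length, "nt), containers:",
      length(ls(x$containers)), "\n")
  invisible(x)
}

#' Exact word lookup in a two-bit index
#'
#' Locates all indexed positions whose full word equals `kmer`, by hashing the
#' preamble to its container and binary-searching the sorted suffix keys.
#'
#' @param index a `two_bit_index`.
#' @param kmer DNA string of exactly `word_length` bases.
#' @return data.frame with columns seq_id, pos (0-based, on the given strand's
#'   coordinates as stored), strand ("+" or "-").
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "two_bit_index"),
            nchar(kmer) == index$word_length)
  cc <- base_codes(kmer)
  abort_if(anyNA(cc), "query k-mer contains non-ACGT characters")
  p <- index$preamble_length
  pre <- sum(cc[1:p] * 4^((p - 1):0))
  suf <- sum(cc[(p + 1):length(cc)] * 4^((index$suffix_length - 1):0))
  cont <- get0(as.character(pre), envir = index$containers)
  if (is.null(cont)) {
    return(data.frame(seq_id = character(0), pos = integer(0),
                      strand = character(0)))
  }
  # binary search for the run of entries equal to suf
  rng <- findInterval(c(suf - 0.5, suf + 0.5), cont$suf)
  if (rng[2] <= rng[1]) {
    return(data.frame(seq_id = character(0), pos = integer(0),
                      strand = character(0)))
  }
  ii <- (rng[1] + 1L):rng[2]
  # report minus-strand entries in forward coordinates of the word
  pos <- cont$pos[ii]
  sl <- index$seq_lengths[cont$seq[ii]]
  fwd <- ifelse(cont$strand[ii] == 1L, pos, sl - pos - index$word_length)
  data.frame(seq_id = index$seq_names[cont$seq[ii]], pos = as.integer(fwd),
             strand = c("+", "-")[cont$strand[ii]],
             stringsAsFactors = FALSE)
}
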