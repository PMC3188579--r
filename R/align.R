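#' Exhaustively align one read against a two-bit index
#'
#' Finds every placement of `read` on either strand of every indexed sequence
#' with Hamming distance at most `max_mismatch`. Candidate placements are
#' located by seed lookup in the preamble containers: for reads of at least
#' twice the preamble width, the two seeds are the first and second
#' preamble-width fragments of the read and each seed's integer is incremented
#' through all substitution variants with up to floor(k/2) mismatches (by the
#' pigeonhole principle the seed carrying fewer mismatches of any true hit is
#' always enumerated); shorter reads use a single seed enumerated up to k
#' mismatches. Every candidate is then verified base by base against the
#' reference, so over-enumeration never creates false hits. The few windows at
#' a sequence's 3' end where the seeds lack a fully indexed word are verified
#' directly, keeping the search exhaustive for every placement.
#'
#' @param read a single A/C/G/T string.
#' @param index a [build_index()] object.
#' @param max_mismatch maximum Hamming distance k (0, 1 or 2).
#' @return data.frame of hits with columns seq_id, pos (0-based leftmost on
#'   the forward strand), strand, mismatches, target_kind. Zero rows if
#'   unmapped; attribute `too_short` is TRUE when the read was shorter than
#'   the seed and could not be searched.
#' @export
align_read <- function(read, index, max_mismatch = 2L) {
  stopifnot(inherits(index, "two_bit_index"), length(read) == 1L)
  k <- as.integer(max_mismatch)
  abort_if(k < 0L || k > 2L, "max_mismatch must be 0, 1 or 2")
  rc <- base_codes(read)
  abort_if(anyNA(rc), "read contains non-ACGT characters")
  L <- length(rc)
  p <- index$preamble_length
  empty <- data.frame(seq_id = character(0), pos = integer(0),
                      strand = character(0), mismatches = integer(0),
                      target_kind = character(0), stringsAsFactors = FALSE)
  if (L < p) {
    attr(empty, "too_short") <- TRUE
    return(empty)
  }

  seeds <- if (L >= 2L * p) {
    list(list(offset = 0L, budget = k %/% 2L),
         list(offset = p, budget = k %/% 2L))
  } else {
    list(list(offset = 0L, budget = k))
  }

  cand_seq <- cand_pos <- cand_str <- integer(0)
  for (sd in seeds) {
    o <- sd$offset
    vals <- seed_variants(rc[(o + 1L):(o + p)], sd$budget)
    for (v in vals) {
      cont <- get0(as.character(v), envir = index$containers)
      if (is.null(cont)) next
      cp <- cont$pos - o
      ok <- cp >= 0L & cp + L <= index$seq_lengths[cont$seq]
      if (!any(ok)) next
      cand_seq <- c(cand_seq, cont$seq[ok])
      cand_pos <- c(cand_pos, cp[ok])
      cand_str <- c(cand_str, cont$strand[ok])
    }
  }
  # Directly verify the windows at each sequence's 3' end where the seed
  # lookup is not exhaustive: a seed at offset o only has an indexed word for
  # placements q with q + o + word <= M. With two seeds the pigeonhole
  # guarantee needs the *second* seed (offset p), so every placement beyond
  # M - word - p must be scanned; with a single seed, every placement beyond
  # M - word.
  tail_off <- index$word_length + if (length(seeds) == 2L) p else 0L
  for (i in seq_along(index$seq_lengths)) {
    M <- index$seq_lengths[i]
    lo <- max(0L, M - tail_off + 1L)
    hi <- M - L
    if (hi < lo) next
    qs <- lo:hi
    cand_seq <- c(cand_seq, rep.int(i, 2L * length(qs)))
    cand_pos <- c(cand_pos, qs, qs)
    cand_str <- c(cand_str, rep.int(1L, length(qs)), rep.int(2L, length(qs)))
  }
  if (!length(cand_seq)) return(empty)

  keep <- !duplicated(cbind(cand_seq, cand_pos, cand_str))
  cand_seq <- cand_seq[keep]; cand_pos <- cand_pos[keep]
  cand_str <- cand_str[keep]

  out_seq <- out_pos <- out_str <- out_mm <- integer(0)
  for (key in unique(cand_seq * 2L + cand_str)) {
    st <- if (key %% 2L == 1L) 1L else 2L
    i <- (key - st) %/% 2L
    sel <- which(cand_seq == i & cand_str == st)
    ref <- index$codes[[i]][[st]]
    qs <- cand_pos[sel]
    idx <- outer(qs, seq_len(L), `+`)
    refm <- matrix(ref[idx], nrow = length(qs))
    mm <- rowSums(refm != matrix(rc, nrow = length(qs), ncol = L, byrow = TRUE))
    bad <- rowSums(refm == 9L) > 0L   # windows touching non-ACGT bases
    hit <- which(!bad & mm <= k)
    if (!length(hit)) next
    out_seq <- c(out_seq, rep.int(i, length(hit)))
    out_str <- c(out_str, rep.int(st, length(hit)))
    out_pos <- c(out_pos, qs[hit])
    out_mm <- c(out_mm, as.integer(mm[hit]))
  }
  if (!length(out_seq)) return(empty)
  # convert minus-strand (reverse-complement coordinate) starts to forward
  M <- index$seq_lengths[out_seq]
  fwd <- ifelse(out_str == 1L, out_pos, M - out_pos - L)
  o <- order(out_seq, fwd, out_str)
  data.frame(seq_id = index$seq_names[out_seq[o]],
             pos = as.integer(fwd[o]),
             strand = c("+", "-")[out_str[o]],
             mismatches = out_mm[o],
             target_kind = index$seq_kinds[out_seq[o]],
             stringsAsFactors = FALSE)
}

# All packed integer values of a seed with at most `budget` substitutions.
seed_variants <- function(codes, budget) {
  p <- length(codes)
  w <- 4^((p - 1):0)
  v0 <- sum(codes * w)
  vals <- v0
  if (budget >= 1L) {
    for (j in seq_len(p)) {
      alt <- setdiff(0:3, codes[j])
      vals <- c(vals, v0 + (alt - codes[j]) * w[j])
    }
  }
  if (budget >= 2L) {
    for (j1 in seq_len(p - 1L)) {
      a1 <- setdiff(0:3, codes[j1])
      for (j2 in (j1 + 1L):p) {
        a2 <- setdiff(0:3, codes[j2])
        d <- outer((a1 - codes[j1]) * w[j1], (a2 - codes[j2]) * w[j2], `+`)
        vals <- c(vals, v0 + as.numeric(d))
      }
    }
  }
  vals
}

#' Align a set of reads
#'
#' Vectorized driver over [align_read()]; returns one data.frame with a
#' read_id column. Reads shorter than the seed width are reported in the
#' `unmapped_short` attribute.
#'
#' @param reads named character vector (names = read ids).
#' @param index a `two_bit_index`.
#' @param max_mismatch maximum Hamming distance.
#' @param best_only keep only each read's best mismatch stratum.
#' @return data.frame of hits (read_id, seq_id, pos, strand, mismatches,
#'   target_kind).
#' @export
align_reads <- function(reads, index, max_mismatch = 2L, best_only = TRUE) {
  stopifnot(!is.null(names(reads)))
  res <- vector("list", length(reads))
  short <- character(0)
  for (i in seq_along(reads)) {
    h <- align_read(reads[[i]], index, max_mismatch)
    if (isTRUE(attr(h, "too_short"))) short <- c(short, names(reads)[i])
    if (nrow(h)) {
      if (best_only) h <- best_stratum(h)
      h$read_id <- names(reads)[i]
      res[[i]] <- h
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(seq_id = character(0), pos = integer(0),
                      strand = character(0), mismatches = integer(0),
                      target_kind = character(0), read_id = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[c("read_id", "seq_id", "pos", "strand", "mismatches",
               "target_kind")]
  rownames(out) <- NULL
  attr(out, "unmapped_short") <- short
  out
}

#' Best mismatch stratum of a read's hits
#'
#' Keeps only the alignments whose mismatch count equals the minimum over all
#' of the read's alignments: perfect matches take precedence over 1-mismatch
#' hits, which take precedence over 2-mismatch hits. Idempotent; empty input
#' gives empty output.
#'
#' @param hits data.frame of hits for a single read (needs a `mismatches`
#'   column).
#' @return the subset of `hits` in the best stratum.
#' @export
best_stratum <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
}
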