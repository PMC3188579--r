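#' Two-bit packing of DNA sequences
#'
#' Packs a DNA string over the alphabet A/C/G/T into integers, two bits per
#' base with A = 00, C = 01, G = 10, T = 11. Bases are packed big-endian in
#' sequence order: the first base occupies the most significant bits of its
#' word. Sequences longer than `word` bases are split into successive words;
#' the final word packs the remaining bases (so a 4-base tail packs into 8
#' bits). Words are returned as doubles because a 16-base word needs 32 bits,
#' which exceeds R's integer range; doubles represent these values exactly.
#'
#' @param x a single DNA string over A/C/G/T.
#' @param word bases per packed word (default 16, i.e. 32 bits).
#' @return numeric vector of packed words with attributes `length` (bases)
#'   and `word`.
#' @seealso [decode_2bit()]
#' @export
#' @examples
#' encode_2bit("ACGT")   # 27 == 0b00011011
#' decode_2bit(encode_2bit("ACGTTGCA"))
encode_2bit <- function(x, word = 16L) {
  stopifnot(length(x) == 1L, is.character(x))
  codes <- base_codes(x)
  abort_if(anyNA(codes), "sequence contains non-ACGT characters")
  n <- length(codes)
  starts <- seq.int(1L, n, by = word)
  vals <- vapply(starts, function(s) {
    chunk <- codes[s:min(s + word - 1L, n)]
    sum(chunk * 4^(rev(seq_along(chunk)) - 1))
  }, numeric(1))
  structure(vals, length = n, word = as.integer(word))
}

#' Unpack a two-bit-encoded sequence
#'
#' @param v numeric vector produced by [encode_2bit()] (or a raw numeric
#'   vector, in which case `length` and `word` must be given).
#' @param length total number of bases encoded.
#' @param word bases per packed word.
#' @return the DNA string.
#' @export
decode_2bit <- function(v, length = attr(v, "length"), word = attr(v, "word")) {
  stopifnot(!is.null(length), !is.null(word))
  n <- length
  starts <- seq.int(1L, n, by = word)
  out <- character(0)
  for (i in seq_along(starts)) {
    k <- min(starts[i] + word - 1L, n) - starts[i] + 1L
    val <- v[i]
    codes <- integer(k)
    for (j in k:1) {
      codes[j] <- val %% 4
      val <- val %/% 4
    }
    out <- c(out, DNA_BASES[codes + 1L])
  }
  paste(out, collapse = "")
}

# Integer codes 0..3 for each base of a string; NA for non-ACGT.
base_codes <- function(x) {
  m <- match(strsplit(x, "", fixed = TRUE)[[1]], DNA_BASES) - 1L
  m
}

# Rolling big-endian 2-bit values of every k-mer window (NA where the window
# touches a non-ACGT base). Returned as doubles; exact up to k = 26.
rolling_kmer_values <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  v <- stats::filter(as.numeric(codes), 4^(0:(k - 1)), sides = 1)
  as.numeric(v[k:n])
}
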