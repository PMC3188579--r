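#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim rbinom rgamma rpois runif dnbinom dbinom phyper
#'   smooth.spline predict p.adjust
#' @importFrom utils read.table write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive `n` deterministic sub-seeds (< 2^31) from one top-level seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Reverse complement of DNA strings
#'
#' Thin wrapper over [Biostrings::reverseComplement()] that accepts and
#' returns plain character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_acgt <- function(x) {
  !grepl("[^ACGT]", x)
}

# Stable TSV writers so repeated runs are byte-identical.
write_tsv <- function(df, path) {
  is_num <- vapply(df, is.double, logical(1))
  df[is_num] <- lapply(df[is_num], function(v) sprintf("%.10g", v))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, quote = "", comment.char = "", ...)
}

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}
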