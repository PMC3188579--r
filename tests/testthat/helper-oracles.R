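# Independent oracles used across the test files. Each reimplements the
# quantity under test by a different route than the package code.

# All placements of `read` on either strand of each sequence with Hamming
# distance <= k, by a full window scan (Biostrings::neditStartingAt does the
# per-window mismatch counting; the package aligner never calls it).
oracle_hits <- function(seqs, read, k) {
  out <- list()
  L <- nchar(read)
  for (nm in names(seqs)) {
    subj <- Biostrings::DNAString(seqs[[nm]])
    M <- length(subj)
    if (M < L) next
    starts <- seq_len(M - L + 1L)
    for (st in c("+", "-")) {
      pat <- Biostrings::DNAString(if (st == "+") read else revcomp(read))
      d <- Biostrings::neditStartingAt(pat, subj, starting.at = starts,
                                       with.indels = FALSE)
      hit <- which(d <= k)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          seq_id = nm, pos = starts[hit] - 1L, strand = st,
          mismatches = as.integer(d[hit]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seq_id = character(0), pos = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

sort_hits <- function(h) {
  h <- h[order(h$seq_id, h$pos, h$strand),
         c("seq_id", "pos", "strand", "mismatches"), drop = FALSE]
  rownames(h) <- NULL
  h
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Conditional exact-test p-value by direct enumeration written from the
# NB-pmf definition via lgamma (shared p^.. q^.. factors cancel), never
# calling dnbinom/dbinom.
oracle_exact_p <- function(y_a, y_b, phi, alpha, mu = mean(c(y_a, y_b))) {
  sa <- sum(y_a); S <- sa + sum(y_b)
  if (S == 0) return(1)
  na <- length(y_a); nb <- length(y_b)
  r <- mu^(2 - alpha) / phi
  ra <- na * r; rb <- nb * r
  s <- 0:S
  lw <- lgamma(s + ra) - lgamma(s + 1) - lgamma(ra) +
    lgamma(S - s + rb) - lgamma(S - s + 1) - lgamma(rb)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  sum(w[w <= w[sa + 1L] * (1 + 1e-7)])
}

# Ancestor set (term plus everything reachable by parent links) by plain
# frontier expansion on the parents list; no graph library involved.
naive_ancestors <- function(dag, term) {
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier])), seen)
  }
  sort(seen)
}

# A small two-gene catalog used by several files: gene GA (+ strand, two
# isoforms sharing exon 1) and gene GB (- strand, single isoform), on one
# 400-nt contig fixed by seed.
toy_catalog <- function(flank = 10L) {
  seq <- with_seed_chr(401L, 400L)
  gff <- c(
    "##gff-version 3",
    "chrT\ttoy\tgene\t21\t140\t.\t+\t.\tID=GA",
    "chrT\ttoy\tmRNA\t21\t140\t.\t+\t.\tID=GA.1;Parent=GA",
    "chrT\ttoy\texon\t21\t70\t.\t+\t.\tParent=GA.1",
    "chrT\ttoy\texon\t101\t140\t.\t+\t.\tParent=GA.1",
    "chrT\ttoy\tmRNA\t21\t140\t.\t+\t.\tID=GA.2;Parent=GA",
    "chrT\ttoy\texon\t21\t70\t.\t+\t.\tParent=GA.2",
    "chrT\ttoy\texon\t121\t140\t.\t+\t.\tParent=GA.2",
    "chrT\ttoy\tgene\t201\t330\t.\t-\t.\tID=GB",
    "chrT\ttoy\tmRNA\t201\t330\t.\t-\t.\tID=GB.1;Parent=GB",
    "chrT\ttoy\texon\t201\t250\t.\t-\t.\tParent=GB.1",
    "chrT\ttoy\texon\t291\t330\t.\t-\t.\tParent=GB.1")
  cat <- load_reference(c(chrT = seq), gff)
  build_junctions(cat, flank = flank)
}

# deterministic random contig without touching the caller's RNG state
with_seed_chr <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
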