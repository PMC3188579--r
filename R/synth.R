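#' Generate a synthetic genome with annotated gene models
#'
#' Produces a uniform-random genome carrying non-overlapping multi-exon genes
#' (2-4 exons, random strand), a fraction of which get a second isoform
#' sharing at least one exon (an internal exon is skipped, or the downstream
#' exon dropped for 2-exon genes). First and last exons of every gene carry
#' 5' and 3' UTR sub-intervals so typed-feature tallies are exercised. The
#' output is valid GFF3 plus FASTA, with full ground truth retained, and is
#' byte-reproducible from the seed.
#'
#' @param n_contigs number of contigs.
#' @param length length of each contig in nt (>= 1000).
#' @param gene_density genes per kilobase (placement fails loudly if the
#'   requested density cannot be placed).
#' @param isoform_rate fraction of genes given a second isoform.
#' @param seed integer RNG seed.
#' @return object of class `synth_truth`: list with `sequences` (named
#'   character), `gff3` (lines), `genes` (data.frame), `exons` (data.frame of
#'   per-isoform exon intervals), `params`.
#' @export
make_genome <- function(n_contigs = 1L, length = 20000L, gene_density = 0.5,
                        isoform_rate = 0.3, seed = 1L) {
  abort_if(length < 1000L, "contig length must be at least 1 kb")
  n_genes <- max(1L, round(gene_density * n_contigs * length / 1000))
  with_seed(seed, {
    sequences <- stats::setNames(
      vapply(seq_len(n_contigs), function(i)
        paste(sample(DNA_BASES, length, replace = TRUE), collapse = ""),
        character(1)),
      sprintf("chr%02d", seq_len(n_contigs)))

    genes <- list(); exon_rows <- list()
    gi <- 0L
    per_contig <- diff(round(seq(0, n_genes, length.out = n_contigs + 1L)))
    for (ci in seq_len(n_contigs)) {
      cursor <- sample(50:150, 1L)
      placed <- 0L
      while (placed < per_contig[ci]) {
        n_ex <- sample(2:4, 1L)
        ex_len <- sample(60:150, n_ex, replace = TRUE)
        in_len <- if (n_ex > 1L) sample(40:90, n_ex - 1L, replace = TRUE)
                  else integer(0)
        span <- sum(ex_len) + sum(in_len)
        if (cursor + span > length) {
          abort_if(placed < per_contig[ci],
                   "gene_density too high: cannot place ", per_contig[ci],
                   " genes on a ", length, " nt contig")
        }
        gi <- gi + 1L
        gene_id <- sprintf("g%04d", gi)
        strand <- sample(c("+", "-"), 1L)
        starts <- cursor + cumsum(c(0L, utils::head(ex_len, -1L) + in_len))
        ends <- starts + ex_len
        genes[[gi]] <- data.frame(
          gene_id = gene_id, class = "gene",
          seq_id = names(sequences)[ci], start = starts[1L],
          end = ends[n_ex], strand = strand, n_exons = n_ex,
          stringsAsFactors = FALSE)
        iso1 <- paste0(gene_id, ".1")
        exon_rows[[base::length(exon_rows) + 1L]] <- data.frame(
          gene_id = gene_id, isoform_id = iso1, seq_id = names(sequences)[ci],
          start = starts, end = ends, strand = strand,
          stringsAsFactors = FALSE)
        if (runif(1) < isoform_rate) {
          iso2 <- paste0(gene_id, ".2")
          keep <- if (n_ex >= 3L) setdiff(seq_len(n_ex), sample(2:(n_ex - 1L), 1L))
                  else 1L
          exon_rows[[base::length(exon_rows) + 1L]] <- data.frame(
            gene_id = gene_id, isoform_id = iso2,
            seq_id = names(sequences)[ci],
            start = starts[keep], end = ends[keep], strand = strand,
            stringsAsFactors = FALSE)
        }
        cursor <- ends[n_ex] + sample(80:200, 1L)
        placed <- placed + 1L
      }
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exon_rows)
    gff3 <- synth_gff3(genes, exons)
    structure(list(sequences = sequences, gff3 = gff3, genes = genes,
                   exons = exons,
                   params = list(n_contigs = n_contigs, length = length,
                                 gene_density = gene_density,
                                 isoform_rate = isoform_rate, seed = seed)),
              class = "synth_truth")
  })
}

# GFF3 lines for the synthetic gene models (1-based inclusive on disk)
synth_gff3 <- function(genes, exons) {
  lines <- "##gff-version 3"
  utr <- 15L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, sprintf("%s\tsynth\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$seq_id, g$class, g$start + 1L, g$end,
                              g$strand, g$gene_id))
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    for (iso in unique(ex$isoform_id)) {
      e <- ex[ex$isoform_id == iso, , drop = FALSE]
      lines <- c(lines, sprintf(
        "%s\tsynth\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$seq_id, min(e$start) + 1L, max(e$end), g$strand, iso, g$gene_id))
      lines <- c(lines, sprintf(
        "%s\tsynth\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        e$seq_id, e$start + 1L, e$end, e$strand, iso))
    }
    # UTR sub-intervals on the primary isoform's terminal exons
    e1 <- ex[ex$isoform_id == paste0(g$gene_id, ".1"), , drop = FALSE]
    e1 <- e1[order(e1$start), , drop = FALSE]
    five <- if (g$strand == "+") e1[1L, ] else e1[nrow(e1), ]
    three <- if (g$strand == "+") e1[nrow(e1), ] else e1[1L, ]
    f_int <- if (g$strand == "+") c(five$start, five$start + utr) else
      c(five$end - utr, five$end)
    t_int <- if (g$strand == "+") c(three$end - utr, three$end) else
      c(three$start, three$start + utr)
    lines <- c(lines, sprintf(
      "%s\tsynth\tfive_prime_UTR\t%d\t%d\t.\t%s\t.\tParent=%s",
      g$seq_id, f_int[1] + 1L, f_int[2], g$strand, paste0(g$gene_id, ".1")))
    lines <- c(lines, sprintf(
      "%s\tsynth\tthree_prime_UTR\t%d\t%d\t.\t%s\t.\tParent=%s",
      g$seq_id, t_int[1] + 1L, t_int[2], g$strand, paste0(g$gene_id, ".1")))
  }
  lines
}

#' Simulate RNA-Seq reads with known provenance
#'
#' Per-gene per-replicate counts are drawn from the NBP noise model
#' (`Var = mu + phi * mu^alpha`, via a Gamma-Poisson mixture); genes in the
#' planted differentially-expressed set have their mean multiplied by `fold`
#' in the second treatment. Each read picks one of its gene's isoforms
#' uniformly, a uniform start along the spliced transcript (so reads crossing
#' exon boundaries exercise the junction sequences), a random orientation,
#' and per-base substitution errors at `mismatch_rate` capped at two per
#' read. Optional pads of random bases are prepended/appended to exercise
#' fixed-position trimming. The number of emitted reads per gene equals the
#' drawn count exactly, so counting is checkable by identity.
#'
#' @param truth a `synth_truth` from [make_genome()].
#' @param design data.frame (replicate_id, treatment) with two treatments;
#'   a `path` column is added pointing at the written FASTA files.
#' @param out_dir directory for the per-replicate FASTA files.
#' @param read_len length of the aligned portion of each read.
#' @param pad_head,pad_tail random bases added at the 5'/3' ends (removed
#'   again by [trim_reads()]).
#' @param mismatch_rate per-base substitution probability.
#' @param de_fraction fraction of genes planted as differentially expressed.
#' @param fold mean multiplier for planted genes in treatment 2.
#' @param phi,alpha NBP noise parameters.
#' @param mean_range log-uniform range for per-gene expression means.
#' @param depth_factors optional per-replicate depth multipliers (named by
#'   replicate); defaults to 1 (equal libraries).
#' @param seed integer RNG seed.
#' @return the `synth_truth` augmented with `design`, `mu` (gene x replicate
#'   expected means), `de_genes`, `counts_true` (gene x replicate emitted
#'   counts), and `provenance` (one row per read).
#' @export
make_reads <- function(truth, design, out_dir, read_len = 25L,
                       pad_head = 0L, pad_tail = 0L, mismatch_rate = 0.002,
                       de_fraction = 0.1, fold = 4, phi = 0.1, alpha = 2,
                       mean_range = c(20, 200), depth_factors = NULL,
                       seed = 1L) {
  stopifnot(inherits(truth, "synth_truth"))
  design <- design[, c("replicate_id", "treatment")]
  trts <- unique(design$treatment)
  abort_if(length(trts) != 2L, "design needs exactly two treatments")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tx <- synth_transcripts(truth)
  abort_if(any(nchar(unlist(tx$seq)) < read_len),
           "read_len exceeds the shortest transcript")
  genes <- truth$genes$gene_id
  nreps <- nrow(design)
  if (is.null(depth_factors)) {
    depth_factors <- stats::setNames(rep(1, nreps), design$replicate_id)
  }
  with_seed(seed, {
    mu0 <- exp(runif(length(genes), log(mean_range[1]), log(mean_range[2])))
    de_genes <- sample(genes, round(de_fraction * length(genes)))
    mu <- matrix(mu0, nrow = length(genes), ncol = nreps,
                 dimnames = list(genes, design$replicate_id))
    t2 <- design$replicate_id[design$treatment == trts[2]]
    mu[de_genes, t2] <- mu[de_genes, t2] * fold
    mu <- sweep(mu, 2, depth_factors[colnames(mu)], `*`)

    counts <- matrix(0L, length(genes), nreps,
                     dimnames = dimnames(mu))
    prov <- list()
    paths <- character(nreps)
    for (j in seq_len(nreps)) {
      rep_id <- design$replicate_id[j]
      r <- mu[, j]^(2 - alpha) / phi
      lam <- rgamma(length(genes), shape = r, rate = r / mu[, j])
      y <- rpois(length(genes), lam)
      counts[, j] <- y
      ids <- seqs <- character(sum(y))
      pg <- pi_ <- character(sum(y)); pt <- pm <- integer(sum(y))
      pj <- logical(sum(y))
      k <- 0L
      for (gidx in seq_along(genes)) {
        if (y[gidx] == 0L) next
        g <- genes[gidx]
        isos <- tx$by_gene[[g]]
        for (b in seq_len(y[gidx])) {
          k <- k + 1L
          iso <- if (length(isos) == 1L) isos else sample(isos, 1L)
          tseq <- tx$seq[[iso]]
          tpos <- sample.int(nchar(tseq) - read_len + 1L, 1L) - 1L
          frag <- substr(tseq, tpos + 1L, tpos + read_len)
          nmm <- min(rbinom(1L, read_len, mismatch_rate), 2L)
          if (nmm > 0L) {
            pos <- sample.int(read_len, nmm)
            fr <- strsplit(frag, "")[[1]]
            for (p in pos) fr[p] <- sample(setdiff(DNA_BASES, fr[p]), 1L)
            frag <- paste(fr, collapse = "")
          }
          if (runif(1) < 0.5) frag <- revcomp(frag)
          if (pad_head > 0L || pad_tail > 0L) {
            frag <- paste0(
              paste(sample(DNA_BASES, pad_head, replace = TRUE), collapse = ""),
              frag,
              paste(sample(DNA_BASES, pad_tail, replace = TRUE), collapse = ""))
          }
          ids[k] <- sprintf("%s_%06d", rep_id, k)
          seqs[k] <- frag
          pg[k] <- g; pi_[k] <- iso; pt[k] <- tpos; pm[k] <- nmm
          pj[k] <- crosses_boundary(tx$bounds[[iso]], tpos, read_len)
        }
      }
      path <- file.path(out_dir, paste0(rep_id, ".fasta"))
      writeLines(paste0(">", ids, "\n", seqs), path)
      paths[j] <- path
      prov[[j]] <- data.frame(read_id = ids, replicate_id = rep_id,
                              gene_id = pg, isoform_id = pi_, tpos = pt,
                              mismatches = pm, crosses_junction = pj,
                              seq = seqs, stringsAsFactors = FALSE)
    }
  })
  design$path <- paths
  truth$design <- design
  truth$mu <- mu
  truth$de_genes <- de_genes
  truth$counts_true <- counts
  truth$provenance <- do.call(rbind, prov)
  truth$read_params <- list(read_len = read_len, pad_head = pad_head,
                            pad_tail = pad_tail,
                            mismatch_rate = mismatch_rate,
                            de_fraction = de_fraction, fold = fold,
                            phi = phi, alpha = alpha, seed = seed)
  truth
}

# spliced transcript sequences and exon-boundary offsets from the truth table
synth_transcripts <- function(truth) {
  seqs <- list(); bounds <- list(); by_gene <- list()
  for (iso in unique(truth$exons$isoform_id)) {
    e <- truth$exons[truth$exons$isoform_id == iso, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    seq <- truth$sequences[[e$seq_id[1]]]
    tx <- paste(substring(seq, e$start + 1L, e$end), collapse = "")
    if (e$strand[1] == "-") tx <- revcomp(tx)
    seqs[[iso]] <- tx
    cuts <- cumsum(e$end - e$start)
    total <- cuts[length(cuts)]
    interior <- utils::head(cuts, -1L)
    # boundary offsets along the transcript's own 5'->3' orientation
    bounds[[iso]] <- if (e$strand[1] == "-") sort(total - interior) else interior
    g <- e$gene_id[1]
    by_gene[[g]] <- c(by_gene[[g]], iso)
  }
  list(seq = seqs, bounds = bounds, by_gene = by_gene)
}

crosses_boundary <- function(bounds, tpos, read_len) {
  any(bounds > tpos & bounds < tpos + read_len)
}

#' Simulate a count matrix under the NBP model
#'
#' Count-level companion to [make_reads()] for exercising the statistics
#' stage directly: per-gene means drawn log-uniformly, NBP noise via the
#' Gamma-Poisson mixture, a planted fold change in treatment 2, and optional
#' per-replicate depth factors to make thinning non-trivial.
#'
#' @param n_genes number of genes.
#' @param n_per_group replicates per treatment (treatments "A" and "B").
#' @param mean_range log-uniform range for per-gene means.
#' @param phi,alpha NBP noise parameters.
#' @param fold mean multiplier of planted genes in treatment "B" (1 = null).
#' @param de_fraction fraction of genes planted.
#' @param depth_factors per-replicate depth multipliers (length 2 *
#'   n_per_group); default 1 (equal libraries).
#' @param seed integer RNG seed.
#' @return a `count_matrix`; attributes `de_genes` and `mu0`.
#' @export
make_count_matrix <- function(n_genes = 2000L, n_per_group = 3L,
                              mean_range = c(10, 500), phi = 0.1, alpha = 2,
                              fold = 1, de_fraction = 0, depth_factors = NULL,
                              seed = 1L) {
  reps <- c(sprintf("A%d", seq_len(n_per_group)),
            sprintf("B%d", seq_len(n_per_group)))
  trts <- stats::setNames(rep(c("A", "B"), each = n_per_group), reps)
  if (is.null(depth_factors)) depth_factors <- rep(1, length(reps))
  genes <- sprintf("g%05d", seq_len(n_genes))
  with_seed(seed, {
    mu0 <- exp(runif(n_genes, log(mean_range[1]), log(mean_range[2])))
    de <- if (de_fraction > 0) sample(genes, round(de_fraction * n_genes))
          else character(0)
    m <- matrix(mu0, n_genes, length(reps), dimnames = list(genes, reps))
    m[de, trts == "B"] <- m[de, trts == "B"] * fold
    m <- sweep(m, 2, depth_factors, `*`)
    r <- m^(2 - alpha) / phi
    lam <- matrix(rgamma(length(m), shape = r, rate = r / m), nrow = n_genes)
    y <- matrix(rpois(length(m), lam), nrow = n_genes,
                dimnames = dimnames(m))
    out <- count_matrix(y, trts)
    attr(out, "de_genes") <- de
    attr(out, "mu0") <- mu0
    out
  })
}

#' Write a `synth_truth`'s genome and annotation to disk
#'
#' @param truth a `synth_truth`.
#' @param out_dir output directory; writes `genome.fasta` and
#'   `annotation.gff3`.
#' @return named character vector of the two paths.
#' @export
write_synth_reference <- function(truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "genome.fasta")
  writeLines(paste0(">", names(truth$sequences), "\n", truth$sequences), fa)
  gff <- file.path(out_dir, "annotation.gff3")
  writeLines(truth$gff3, gff)
  c(fasta = fa, gff3 = gff)
}
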