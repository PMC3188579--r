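two_rep_design <- function() {
  data.frame(replicate_id = c("x1", "x2", "y1", "y2"),
             treatment = c("T1", "T1", "T2", "T2"), stringsAsFactors = FALSE)
}

test_that("genome generation is byte-reproducible from the seed", {
  g1 <- make_genome(length = 5000L, seed = 21)
  g2 <- make_genome(length = 5000L, seed = 21)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$gff3, g2$gff3)
  g3 <- make_genome(length = 5000L, seed = 22)
  expect_false(identical(g1$sequences, g3$sequences))
})

test_that("read simulation is byte-reproducible from the seed", {
  g <- make_genome(length = 5000L, seed = 23)
  d1 <- tempfile(); d2 <- tempfile()
  t1 <- make_reads(g, two_rep_design(), d1, seed = 23)
  t2 <- make_reads(g, two_rep_design(), d2, seed = 23)
  expect_identical(t1$provenance, t2$provenance)
  expect_identical(t1$counts_true, t2$counts_true)
  for (i in seq_along(t1$design$path)) {
    expect_identical(readLines(t1$design$path[i]), readLines(t2$design$path[i]))
  }
})

test_that("the generated annotation is placed, parseable and reject-free", {
  g <- make_genome(length = 20000L, gene_density = 0.5, isoform_rate = 0.4,
                   seed = 24)
  expect_equal(nrow(g$genes), round(0.5 * 20000 / 1000))
  # genes do not overlap along the contig
  ord <- g$genes[order(g$genes$start), ]
  expect_true(all(utils::head(ord$end, -1) < utils::tail(ord$start, -1)))
  cat <- load_reference(g$sequences, g$gff3)
  expect_equal(nrow(cat$rejects), 0L)
  expect_setequal(cat$genes$gene_id, g$genes$gene_id)
})

test_that("isoform_rate 0 yields exactly one isoform per gene", {
  g <- make_genome(length = 8000L, isoform_rate = 0, seed = 25)
  iso_per_gene <- tapply(g$exons$isoform_id, g$exons$gene_id,
                         function(x) length(unique(x)))
  expect_true(all(iso_per_gene == 1L))
  expect_true(all(endsWith(unique(g$exons$isoform_id), ".1")))
})

test_that("every emitted read is accounted for in the provenance table", {
  g <- make_genome(length = 6000L, seed = 26)
  truth <- make_reads(g, two_rep_design(), tempfile(), de_fraction = 0.2,
                      fold = 4, seed = 26)
  prov <- truth$provenance
  expect_false(anyDuplicated(prov$read_id) > 0)
  # per-replicate read counts equal the drawn count totals
  by_rep <- table(prov$replicate_id)
  expect_equal(as.integer(by_rep[colnames(truth$counts_true)]),
               unname(colSums(truth$counts_true)))
  # and per (gene, replicate) cells match exactly, zero-count genes included
  cell <- as.matrix(table(factor(prov$gene_id,
                                 levels = rownames(truth$counts_true)),
                          prov$replicate_id))
  cell <- cell[, colnames(truth$counts_true), drop = FALSE]
  expect_equal(unname(cell), unname(truth$counts_true), ignore_attr = TRUE)
  # planted genes have their treatment-2 mean scaled by the fold
  t2 <- truth$design$replicate_id[truth$design$treatment == "T2"]
  t1 <- truth$design$replicate_id[truth$design$treatment == "T1"]
  expect_equal(truth$mu[truth$de_genes, t2[1]],
               truth$mu[truth$de_genes, t1[1]] * 4)
})

test_that("error-free reads are exact transcript substrings at their stated positions", {
  g <- make_genome(length = 6000L, isoform_rate = 0.5, seed = 27)
  truth <- make_reads(g, two_rep_design(), tempfile(), mismatch_rate = 0,
                      seed = 27)
  # transcripts reconstructed by the reference module from the written GFF3
  tx <- transcript_sequences(load_reference(truth$sequences, truth$gff3))
  L <- truth$read_params$read_len
  prov <- truth$provenance
  ok <- vapply(seq_len(nrow(prov)), function(i) {
    want <- substr(tx[[prov$isoform_id[i]]], prov$tpos[i] + 1L,
                   prov$tpos[i] + L)
    prov$seq[i] == want || prov$seq[i] == revcomp(want)
  }, logical(1))
  expect_true(all(ok))
  expect_true(all(prov$mismatches == 0L))
  # junction flags: a read crosses a boundary iff it is NOT a contiguous
  # genomic substring of its contig (error-free, so this is decidable)
  genome <- truth$sequences[[1]]
  contig_hit <- vapply(prov$seq, function(s)
    grepl(s, genome, fixed = TRUE) || grepl(revcomp(s), genome, fixed = TRUE),
    logical(1))
  expect_true(all(contig_hit[!prov$crosses_junction]))
})

test_that("simulated counts reproduce the quadratic mean-variance law", {
  m <- make_count_matrix(n_genes = 60, n_per_group = 300,
                         mean_range = c(20, 200), phi = 0.15, alpha = 2,
                         seed = 28)
  mu0 <- attr(m, "mu0")
  s2 <- apply(m$counts, 1, var)
  v <- mu0 + 0.15 * mu0^2
  ratio <- mean(s2 / v)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
  # and the variance grows super-linearly with the mean, unlike Poisson
  expect_gt(coef(lm(log(s2) ~ log(mu0)))[2], 1.5)
})

test_that("a null simulation plants nothing and depth factors scale libraries", {
  m <- make_count_matrix(n_genes = 2000, fold = 1, de_fraction = 0,
                         depth_factors = c(1, 1, 1, 2, 1, 1), seed = 29)
  expect_length(attr(m, "de_genes"), 0L)
  ls <- m$library_sizes
  expect_gt(ls[["B1"]] / ls[["A1"]], 1.9)
  expect_lt(ls[["B1"]] / ls[["A1"]], 2.1)
})

test_that("padded reads recover their aligned portion under fixed trimming", {
  g <- make_genome(length = 5000L, seed = 30)
  truth <- make_reads(g, two_rep_design(), tempfile(), read_len = 25L,
                      pad_head = 6L, pad_tail = 5L, seed = 30)
  prov <- truth$provenance
  expect_true(all(nchar(prov$seq) == 36L))
  trimmed <- trim_reads(prov$seq, head = 6L, tail = 5L)
  expect_equal(unname(as.character(trimmed)),
               substr(prov$seq, 7L, 31L))
})
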