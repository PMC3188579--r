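make_hit <- function(read_id, seq_id, pos, kind = "genome") {
  data.frame(read_id = read_id, seq_id = seq_id, pos = pos, strand = "+",
             mismatches = 0L, target_kind = kind, stringsAsFactors = FALSE)
}

test_that("reads are classified by the single-gene-locus rule", {
  cat <- toy_catalog()
  hits <- rbind(
    make_hit("u1", "chrT", 25L),                       # inside GA's shared exon
    make_hit("a1", "chrT", 25L), make_hit("a1", "chrT", 205L),  # GA and GB
    make_hit("i1", "chrT", 150L),                      # between the genes
    make_hit("j1", cat$junctions$junction_id[1], 3L, "junction"))
  cls <- classify_reads(hits, cat, read_lengths = c(u1 = 10L, a1 = 10L,
                                                    i1 = 10L, j1 = 10L))
  cls <- cls[match(c("u1", "a1", "i1", "j1"), cls$read_id), ]
  expect_equal(cls$status, c("unambiguous", "ambiguous", "intergenic",
                             "unambiguous"))
  expect_equal(cls$gene_id[1], "GA")
  expect_setequal(strsplit(cls$isoform_ids[1], ",")[[1]], c("GA.1", "GA.2"))
  expect_equal(cls$gene_id[4], cat$junctions$gene_id[1])
})

test_that("a read hitting both an exon and a junction of one gene stays unambiguous", {
  cat <- toy_catalog()
  jga <- cat$junctions$junction_id[cat$junctions$gene_id == "GA"][1]
  hits <- rbind(make_hit("r1", "chrT", 62L), make_hit("r1", jga, 0L, "junction"))
  cls <- classify_reads(hits, cat, read_lengths = c(r1 = 8L))
  expect_equal(cls$status, "unambiguous")
  expect_equal(cls$gene_id, "GA")
})

test_that("occurrences split equally across isoforms but genes count in full", {
  cls <- data.frame(read_id = c("r1", "r2"), status = "unambiguous",
                    gene_id = c("G", "H"),
                    isoform_ids = c("G.1,G.2", "H.1"),
                    stringsAsFactors = FALSE)
  occ <- matrix(c(4L, 3L), nrow = 2, dimnames = list(c("r1", "r2"), "repA"))
  out <- accumulate_counts(cls, occ, c(repA = "T1"))
  expect_equal(out$gene$counts["G", "repA"], 4)
  expect_equal(out$gene$counts["H", "repA"], 3)
  expect_equal(out$isoform["G.1", "repA"], 2)
  expect_equal(out$isoform["G.2", "repA"], 2)
  expect_equal(out$isoform["H.1", "repA"], 3)
})

test_that("gene totals conserve the unambiguous occurrence total", {
  set.seed(51)
  n <- 40
  cls <- data.frame(
    read_id = sprintf("r%02d", 1:n),
    status = sample(c("unambiguous", "ambiguous", "intergenic"), n,
                    replace = TRUE, prob = c(0.6, 0.2, 0.2)),
    gene_id = sample(sprintf("g%d", 1:8), n, replace = TRUE),
    isoform_ids = "x.1", stringsAsFactors = FALSE)
  occ <- matrix(rpois(2 * n, 3), nrow = n,
                dimnames = list(cls$read_id, c("a", "b")))
  out <- accumulate_counts(cls, occ, c(a = "T1", b = "T2"))
  un <- cls$status == "unambiguous"
  expect_equal(sum(out$gene$counts), sum(occ[un, ]))
  expect_equal(sum(out$isoform), sum(occ[un, ]))
})

test_that("the expression filter behaves exactly as specified on its three cases", {
  m <- rbind(keep1 = c(5, 2, 1, 0, 0, 0),
             drop1 = c(5, 0, 1, 0, 3, 0),
             drop2 = c(0, 0, 0, 0, 0, 0))
  colnames(m) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  cm <- count_matrix(m, stats::setNames(rep(c("A", "B"), each = 3),
                                        colnames(m)))
  kept <- expression_filter(cm)
  expect_equal(rownames(kept$counts), "keep1")
  # library sizes survive filtering unchanged
  expect_equal(kept$library_sizes, cm$library_sizes)
})

test_that("adding a replicate can only shrink the retained set", {
  set.seed(52)
  base <- matrix(rpois(200 * 4, 1), nrow = 200,
                 dimnames = list(sprintf("g%03d", 1:200),
                                 c("a1", "a2", "b1", "b2")))
  extra <- cbind(base, a3 = rpois(200, 1))
  trt4 <- stats::setNames(c("A", "A", "B", "B"), colnames(base))
  trt5 <- stats::setNames(c("A", "A", "B", "B", "A"), colnames(extra))
  kept4 <- rownames(expression_filter(count_matrix(base, trt4))$counts)
  kept5 <- rownames(expression_filter(count_matrix(extra, trt5))$counts)
  expect_true(all(kept5 %in% kept4))
})

test_that("the count-matrix TSV dialect round-trips", {
  m <- matrix(c(5, 0, 2, 7), nrow = 2,
              dimnames = list(c("g1", "g2"), c("r1", "r2")))
  cm <- count_matrix(m, c(r1 = "ctrl", r2 = "trt"))
  path <- tempfile(fileext = ".tsv")
  write_count_matrix(cm, path)
  header <- readLines(path, n = 1L)
  expect_equal(header, "gene_id\tr1|ctrl\tr2|trt")
  back <- read_count_matrix(path)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$treatments, cm$treatments)
})

test_that("unambiguous synthetic reads are credited to their source gene", {
  truth <- make_genome(length = 6000L, gene_density = 0.8, seed = 61)
  dirp <- tempfile()
  design <- data.frame(replicate_id = c("x1", "y1"),
                       treatment = c("T1", "T2"), stringsAsFactors = FALSE)
  truth <- make_reads(truth, design, dirp, mismatch_rate = 0, de_fraction = 0,
                      seed = 61)
  cat <- build_junctions(load_reference(truth$sequences, truth$gff3),
                         flank = 24L)
  store <- load_reads(read_design(truth$design), head = 0L, tail = 0L)
  refs <- reference_set(cat, "genome")
  idx <- build_index(refs, kinds = attr(refs, "kind"))
  hits <- align_reads(store$sequences, idx, max_mismatch = 2L)
  cls <- classify_reads(hits, cat, read_lengths = nchar(store$sequences))
  # map unique reads back to provenance by sequence
  prov_by_seq <- split(truth$provenance$gene_id, truth$provenance$seq)
  un <- cls[cls$status == "unambiguous", ]
  seqs <- store$sequences[un$read_id]
  truth_genes <- prov_by_seq[seqs]
  consistent <- mapply(function(g, tg) g %in% tg, un$gene_id, truth_genes)
  expect_gte(mean(consistent), 0.99)
})
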