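# 20-gene population; term T annotates 5 genes; every gene is annotated to
# the root so none is dropped.
tft_fixture <- function() {
  dag <- read_go_dag(c("R\troot\t", "T\tterm T\tR"))
  genes <- sprintf("G%02d", 1:20)
  ann <- c(paste0(genes, "\tR"), paste0(genes[1:5], "\tT"))
  list(dag = dag, genes = genes, ann = read_annotations(ann, dag))
}

test_that("term-for-term p equals the enumerated hypergeometric tail", {
  fx <- tft_fixture()
  study <- fx$genes[c(1, 2, 3, 6, 7)]      # 3 of 5 annotated to T
  res <- term_for_term(study, fx$genes, fx$dag, fx$ann)
  pT <- res$p_value[res$term_id == "T"]
  # direct enumeration: sum over x >= 3 of C(5,x) C(15,5-x) / C(20,5)
  direct <- sum(choose(5, 3:5) * choose(15, 2:0)) / choose(20, 5)
  expect_equal(direct, 1126 / 15504)
  expect_lt(abs(pT - direct), 1e-12)
  expect_equal(res$p_value[res$term_id == "R"], 1)   # m = n, M = N
})

test_that("a study with no hits on a term gives p = 1, and study = population too", {
  fx <- tft_fixture()
  res0 <- term_for_term(fx$genes[6:10], fx$genes, fx$dag, fx$ann)
  expect_equal(res0$p_value[res0$term_id == "T"], 1)
  resall <- term_for_term(fx$genes, fx$genes, fx$dag, fx$ann)
  expect_true(all(resall$p_value == 1))
})

test_that("term-for-term p-values are invariant to gene relabeling", {
  fx <- tft_fixture()
  study <- fx$genes[c(1, 2, 6, 7, 8)]
  res1 <- term_for_term(study, fx$genes, fx$dag, fx$ann)
  relabel <- stats::setNames(sprintf("X%02d", 20:1), fx$genes)
  ann2 <- lapply(fx$ann, identity)
  names(ann2) <- relabel[names(fx$ann)]
  res2 <- term_for_term(unname(relabel[study]), unname(relabel[fx$genes]),
                        fx$dag, ann2)
  expect_equal(res1[order(res1$term_id), c("term_id", "p_value")],
               res2[order(res2$term_id), c("term_id", "p_value")])
})

test_that("annotation closure agrees with naive reachability on a random DAG", {
  set.seed(101)
  n_terms <- 40
  ids <- sprintf("t%02d", 1:n_terms)
  lines <- vapply(seq_along(ids), function(i) {
    parents <- if (i == 1) character(0) else
      sample(ids[1:(i - 1)], min(i - 1, sample(1:2, 1)))
    paste(ids[i], "", paste(parents, collapse = ","), sep = "\t")
  }, character(1))
  dag <- read_go_dag(lines)
  genes <- sprintf("g%02d", 1:30)
  ann <- lapply(stats::setNames(genes, genes), function(g)
    sample(ids, sample(1:4, 1)))
  closed <- annotation_closure(ann, dag)
  for (g in genes) {
    want <- sort(unique(unlist(lapply(ann[[g]], naive_ancestors, dag = dag))))
    expect_equal(closed[[g]], want)
  }
})

test_that("the OBO-flavored reader and the TSV reader build the same DAG", {
  obo <- c("[Term]", "id: A", "name: alpha", "",
           "[Term]", "id: B", "name: beta", "is_a: A ! alpha", "",
           "[Term]", "id: C", "name: gamma", "is_a: B ! beta",
           "relationship: part_of A ! alpha")
  tsv <- c("A\talpha\t", "B\tbeta\tA", "C\tgamma\tB,A")
  d1 <- read_go_dag(obo)
  d2 <- read_go_dag(tsv)
  expect_equal(d1$terms, d2$terms)
  expect_equal(d1$parents, d2$parents)
})

test_that("cyclic parentage and unknown parents are rejected", {
  expect_error(read_go_dag(c("A\t\tB", "B\t\tA")), "cycle")
  expect_error(read_go_dag(c("A\t\tZ")), "not defined")
})

test_that("annotations to unknown terms are dropped with a warning", {
  dag <- read_go_dag(c("A\t\t"))
  expect_warning(ann <- read_annotations(c("g1\tA", "g2\tZZ"), dag), "dropped")
  expect_named(ann, "g1")
})

test_that("parent-child conditioning matches hand enumeration", {
  dag <- read_go_dag(c("R\t\t", "P\t\tR", "C\t\tP"))
  genes <- sprintf("g%02d", 1:20)
  ann_lines <- c(paste0(genes, "\tR"),          # everyone reaches the root
                 paste0(genes[1:10], "\tP"),    # 10 genes at the parent
                 paste0(genes[1:4], "\tC"))     # 4 of them refine to C
  ann <- read_annotations(ann_lines, dag)
  study <- genes[c(1, 2, 3, 5, 11, 12)]         # 4 in P-set, 3 of them in C
  res <- parent_child(study, genes, dag, ann)
  # conditioned universe: the 10 P-annotated genes, 4 carrying C; the study
  # contributes 4 genes inside the universe, 3 carrying C
  hand <- sum(vapply(3:4, function(x)
    choose(4, x) * choose(6, 4 - x), numeric(1))) / choose(10, 4)
  expect_equal(res$p_value[res$term_id == "C"], hand, tolerance = 1e-12)
  expect_equal(res$p_value[res$term_id == "R"], 1)   # root convention
  # P conditioned on R: universe 20, 10 annotated, study 6 with 4 hits
  handP <- sum(vapply(4:6, function(x)
    choose(10, x) * choose(10, 6 - x), numeric(1))) / choose(20, 6)
  expect_equal(res$p_value[res$term_id == "P"], handP, tolerance = 1e-12)
})

test_that("a term annotating exactly its parent's gene set cannot be enriched", {
  dag <- read_go_dag(c("R\t\t", "P\t\tR", "C\t\tP"))
  genes <- sprintf("g%02d", 1:12)
  ann <- read_annotations(c(paste0(genes, "\tR"), paste0(genes[1:6], "\tP"),
                            paste0(genes[1:6], "\tC")), dag)
  res <- parent_child(genes[1:4], genes, dag, ann)
  expect_equal(res$p_value[res$term_id == "C"], 1)
})

test_that("permutation enrichment is seed-reproducible and tracks the hypergeometric", {
  fx <- tft_fixture()
  study <- fx$genes[c(1, 2, 3, 6, 7)]
  r1 <- perm_enrichment(study, fx$genes, fx$dag, fx$ann, n_perm = 500,
                        seed = 9)
  r2 <- perm_enrichment(study, fx$genes, fx$dag, fx$ann, n_perm = 500,
                        seed = 9)
  expect_identical(r1, r2)
  n_perm <- 4000
  r3 <- perm_enrichment(study, fx$genes, fx$dag, fx$ann, n_perm = n_perm,
                        seed = 10)
  p_hyp <- 1126 / 15504
  se <- sqrt(p_hyp * (1 - p_hyp) / n_perm)
  expect_lt(abs(r3$p_value[r3$term_id == "T"] - p_hyp), 3 * se + 2 / n_perm)
  # a term hit by no study gene can never beat the +1 rule
  r0 <- perm_enrichment(fx$genes[6:10], fx$genes, fx$dag, fx$ann,
                        n_perm = 200, seed = 11)
  expect_equal(r0$p_value[r0$term_id == "T"], 1)
})

test_that("term-for-term p-values are super-uniform under random study sets", {
  set.seed(102)
  dag <- read_go_dag(c("R\t\t", "T1\t\tR", "T2\t\tR", "T3\t\tR"))
  genes <- sprintf("g%02d", 1:50)
  ann <- read_annotations(c(paste0(genes, "\tR"),
                            paste0(sample(genes, 12), "\tT1"),
                            paste0(sample(genes, 20), "\tT2"),
                            paste0(sample(genes, 6), "\tT3")), dag)
  hits <- replicate(500, {
    study <- sample(genes, 8)
    res <- term_for_term(study, genes, dag, ann)
    res$p_value[res$term_id %in% c("T1", "T2", "T3")] <= 0.05
  })
  frac <- mean(hits)
  se <- sqrt(0.05 * 0.95 / length(hits))
  expect_lte(frac, 0.05 + 3 * se)
})
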