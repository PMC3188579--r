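#' Pipeline configuration
#'
#' Assembles and validates the configuration shared by all pipeline stages.
#' Every run records the full configuration and the package version in the
#' store, so results are traceable to their settings.
#'
#' @param store directory acting as the persistent structured store (created
#'   if absent); all stages read and write their tables here.
#' @param fasta,gff3 reference inputs for the `build-ref` stage.
#' @param design path to the replicate manifest (replicate_id, treatment,
#'   path) for `load-reads`.
#' @param counts_tsv optional precomputed count-matrix TSV; supplying it lets
#'   `dge` run without stages 1-4.
#' @param trim_head,trim_tail,min_length read preprocessing parameters.
#' @param flank junction flank width; defaults to `read_length - 1` at
#'   build-ref time via `read_length`.
#' @param read_length expected post-trim read length (drives the default
#'   flank).
#' @param max_mismatch alignment mismatch allowance (0-2).
#' @param target alignment target: "genome", "transcriptome" or "both".
#' @param fdr FDR cutoff for the significant set.
#' @param seed top-level seed for all stochastic stages.
#' @param stats statistics method; only "nbp" is implemented (the count-matrix
#'   TSV is the hand-off point for external packages).
#' @param stability_iters iterations for the `stability` stage.
#' @param go_dag,go_annotations inputs for the `go` stage.
#' @param go_method one of "term_for_term", "parent_child", "permutation",
#'   or "all".
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(store, fasta = NULL, gff3 = NULL, design = NULL,
                            counts_tsv = NULL, trim_head = 6L, trim_tail = 5L,
                            min_length = 20L, read_length = 25L, flank = NULL,
                            max_mismatch = 2L,
                            target = c("genome", "transcriptome", "both"),
                            fdr = 0.05, seed = 1L, stats = "nbp",
                            stability_iters = 100L, go_dag = NULL,
                            go_annotations = NULL, go_method = "all") {
  abort_if(stats != "nbp", "only the 'nbp' statistics method is implemented")
  cfg <- list(store = store, fasta = fasta, gff3 = gff3, design = design,
              counts_tsv = counts_tsv, trim_head = trim_head,
              trim_tail = trim_tail, min_length = min_length,
              read_length = read_length,
              flank = if (is.null(flank)) read_length - 1L else flank,
              max_mismatch = max_mismatch, target = match.arg(target),
              fdr = fdr, seed = as.integer(seed), stats = stats,
              stability_iters = stability_iters, go_dag = go_dag,
              go_annotations = go_annotations, go_method = go_method)
  class(cfg) <- "pipeline_config"
  cfg
}

store_path <- function(cfg, ...) file.path(cfg$store, ...)

require_stage <- function(cfg, file, stage) {
  abort_if(!file.exists(store_path(cfg, file)),
           "missing upstream artifact '", file, "': run stage '", stage,
           "' first")
}

log_stage <- function(cfg, stage, msg) {
  dir.create(cfg$store, showWarnings = FALSE, recursive = TRUE)
  cat(sprintf("[%s] %s\n", stage, msg),
      file = store_path(cfg, "log.txt"), append = TRUE)
}

record_config <- function(cfg) {
  dir.create(cfg$store, showWarnings = FALSE, recursive = TRUE)
  rec <- cfg
  rec$package_version <- as.character(utils::packageVersion("seqdge"))
  jsonlite::write_json(rec[!vapply(rec, is.null, logical(1))],
                       store_path(cfg, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Stages, in their canonical order: `build-ref`, `load-reads`, `align`,
#' `count`, `assess`, `dge`, `stability`, `go`. Each stage writes its outputs
#' to the store; re-running a stage with an identical configuration and seed
#' overwrites its outputs byte-identically. A stage whose upstream artifacts
#' are missing fails naming the stage to run first; the `dge` stage accepts a
#' precomputed count-matrix TSV (`counts_tsv`) as an entry point that skips
#' stages 1-4.
#'
#' @param stage stage name.
#' @param cfg a [pipeline_config()].
#' @return invisibly, the stage's main result object.
#' @export
run_stage <- function(stage, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  record_config(cfg)
  switch(stage,
    "build-ref" = stage_build_ref(cfg),
    "load-reads" = stage_load_reads(cfg),
    "align" = stage_align(cfg),
    "count" = stage_count(cfg),
    "assess" = stage_assess(cfg),
    "dge" = stage_dge(cfg),
    "stability" = stage_stability(cfg),
    "go" = stage_go(cfg),
    stop("unknown stage '", stage, "'", call. = FALSE))
}

#' Run the full pipeline
#'
#' @param cfg a [pipeline_config()].
#' @param stages stages to run, in order.
#' @return invisibly, the result of the last stage.
#' @export
run_pipeline <- function(cfg, stages = c("build-ref", "load-reads", "align",
                                         "count", "assess", "dge")) {
  res <- NULL
  for (s in stages) res <- run_stage(s, cfg)
  invisible(res)
}

stage_build_ref <- function(cfg) {
  abort_if(is.null(cfg$fasta) || is.null(cfg$gff3),
           "build-ref needs fasta and gff3 inputs")
  cat_ <- load_reference(cfg$fasta, cfg$gff3)
  cat_ <- build_junctions(cat_, flank = cfg$flank)
  dir.create(store_path(cfg, "reference"), showWarnings = FALSE,
             recursive = TRUE)
  writeLines(paste0(">", names(cat_$sequences), "\n", cat_$sequences),
             store_path(cfg, "reference", "genome.fasta"))
  export_gff3(cat_, store_path(cfg, "reference", "catalog.gff3"))
  write_tsv(cat_$junctions, store_path(cfg, "reference", "junctions.tsv"))
  write_tsv(cat_$rejects, store_path(cfg, "reference", "rejects.tsv"))
  log_stage(cfg, "build-ref",
            sprintf("%d genes, %d junctions, %d rejects", nrow(cat_$genes),
                    nrow(cat_$junctions), nrow(cat_$rejects)))
  invisible(cat_)
}

load_store_catalog <- function(cfg) {
  require_stage(cfg, file.path("reference", "catalog.gff3"), "build-ref")
  cat_ <- load_reference(store_path(cfg, "reference", "genome.fasta"),
                         store_path(cfg, "reference", "catalog.gff3"))
  jn <- read_tsv(store_path(cfg, "reference", "junctions.tsv"),
                 colClasses = "character")
  if (nrow(jn)) {
    jn$donor_end <- as.integer(jn$donor_end)
    jn$acceptor_start <- as.integer(jn$acceptor_start)
    jn$short <- as.logical(jn$short)
    cat_$junctions <- jn
  }
  cat_
}

stage_load_reads <- function(cfg) {
  abort_if(is.null(cfg$design), "load-reads needs a design manifest")
  design <- read_design(cfg$design)
  store <- load_reads(design, head = cfg$trim_head, tail = cfg$trim_tail,
                      min_length = cfg$min_length)
  dir.create(store_path(cfg, "reads"), showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(read_id = names(store$sequences),
                       sequence = unname(store$sequences)),
            store_path(cfg, "reads", "unique_reads.tsv"))
  occ <- store$occurrences
  long <- data.frame(read_id = rep(rownames(occ), ncol(occ)),
                     replicate_id = rep(colnames(occ), each = nrow(occ)),
                     count = as.integer(occ))
  long <- long[long$count > 0, , drop = FALSE]
  write_tsv(long, store_path(cfg, "reads", "occurrences.tsv"))
  write_tsv(design[, c("replicate_id", "treatment")],
            store_path(cfg, "reads", "design.tsv"))
  write_tsv(data.frame(replicate_id = colnames(occ),
                       dropped = as.integer(store$dropped[colnames(occ)]),
                       ambiguous = as.integer(store$ambiguous[colnames(occ)])),
            store_path(cfg, "reads", "tallies.tsv"))
  log_stage(cfg, "load-reads",
            sprintf("%d unique reads over %d replicates",
                    length(store$sequences), ncol(occ)))
  invisible(store)
}

load_store_reads <- function(cfg) {
  require_stage(cfg, file.path("reads", "unique_reads.tsv"), "load-reads")
  ur <- read_tsv(store_path(cfg, "reads", "unique_reads.tsv"))
  long <- read_tsv(store_path(cfg, "reads", "occurrences.tsv"))
  design <- read_tsv(store_path(cfg, "reads", "design.tsv"))
  tallies <- read_tsv(store_path(cfg, "reads", "tallies.tsv"))
  occ <- matrix(0L, nrow(ur), nrow(design),
                dimnames = list(ur$read_id, design$replicate_id))
  occ[cbind(match(long$read_id, ur$read_id),
            match(long$replicate_id, design$replicate_id))] <- long$count
  structure(list(sequences = stats::setNames(ur$sequence, ur$read_id),
                 occurrences = occ,
                 ambiguous = stats::setNames(tallies$ambiguous,
                                             tallies$replicate_id),
                 dropped = stats::setNames(tallies$dropped,
                                           tallies$replicate_id),
                 design = design),
            class = "read_store")
}

stage_align <- function(cfg) {
  cat_ <- load_store_catalog(cfg)
  store <- load_store_reads(cfg)
  refs <- reference_set(cat_, cfg$target)
  idx <- build_index(refs, kinds = attr(refs, "kind"))
  hits <- align_reads(store$sequences, idx, max_mismatch = cfg$max_mismatch)
  write_sam(hits, store$sequences, stats::setNames(nchar(refs), names(refs)),
            store_path(cfg, "alignments.sam"))
  log_stage(cfg, "align",
            sprintf("%d hits for %d of %d unique reads", nrow(hits),
                    length(unique(hits$read_id)), length(store$sequences)))
  invisible(hits)
}

stage_count <- function(cfg) {
  require_stage(cfg, "alignments.sam", "align")
  cat_ <- load_store_catalog(cfg)
  store <- load_store_reads(cfg)
  hits <- read_sam(store_path(cfg, "alignments.sam"))
  cls <- classify_reads(hits, cat_,
                        read_lengths = nchar(store$sequences))
  cm <- accumulate_counts(cls, store$occurrences,
                          stats::setNames(store$design$treatment,
                                          store$design$replicate_id),
                          gene_ids = sort(cat_$genes$gene_id))
  write_tsv(cls, store_path(cfg, "classified.tsv"))
  write_count_matrix(cm$gene, store_path(cfg, "counts_gene.tsv"))
  if (!is.null(cm$isoform)) {
    write_tsv(data.frame(isoform_id = rownames(cm$isoform), cm$isoform,
                         check.names = FALSE),
              store_path(cfg, "counts_isoform.tsv"))
  }
  filtered <- expression_filter(cm$gene)
  write_count_matrix(filtered, store_path(cfg, "counts_gene_filtered.tsv"))
  log_stage(cfg, "count",
            sprintf("%d genes counted, %d retained by the expression filter",
                    nrow(cm$gene$counts), nrow(filtered$counts)))
  invisible(filtered)
}

stage_assess <- function(cfg) {
  require_stage(cfg, "counts_gene.tsv", "count")
  store <- load_store_reads(cfg)
  cat_ <- load_store_catalog(cfg)
  cls <- read_tsv(store_path(cfg, "classified.tsv"))
  cm <- read_count_matrix(store_path(cfg, "counts_gene.tsv"))
  sm <- summaries(store, cls, cat_)
  dir.create(store_path(cfg, "assess"), showWarnings = FALSE, recursive = TRUE)
  write_tsv(sm$replicates, store_path(cfg, "assess", "replicates.tsv"))
  if (!is.null(sm$feature_types)) {
    write_tsv(data.frame(ftype = names(sm$feature_types),
                         n = as.integer(sm$feature_types)),
              store_path(cfg, "assess", "feature_types.tsv"))
  }
  ic <- icc_report(cm)
  write_tsv(data.frame(treatment = names(ic), icc = as.numeric(ic)),
            store_path(cfg, "assess", "icc.tsv"))
  log_stage(cfg, "assess",
            paste("ICC:", paste(sprintf("%s=%.3f", names(ic), ic),
                                collapse = ", ")))
  invisible(list(summaries = sm, icc = ic))
}

stage_dge <- function(cfg) {
  cm <- if (!is.null(cfg$counts_tsv)) {
    read_count_matrix(cfg$counts_tsv)
  } else {
    require_stage(cfg, "counts_gene_filtered.tsv", "count")
    read_count_matrix(store_path(cfg, "counts_gene_filtered.tsv"))
  }
  res <- nbp_test(cm, seed = cfg$seed, fdr = cfg$fdr)
  write_dge(res, store_path(cfg, "dge.tsv"))
  write_tsv(ma_points(res$thinned, res$treatments),
            store_path(cfg, "ma.tsv"))
  jsonlite::write_json(list(phi = res$fit$phi, alpha = res$fit$alpha,
                            pi0 = res$pi0, seed = cfg$seed, fdr = cfg$fdr),
                       store_path(cfg, "dge_fit.json"), auto_unbox = TRUE,
                       digits = NA)
  log_stage(cfg, "dge",
            sprintf("%d significant at FDR <= %g",
                    sum(res$table$q_value <= cfg$fdr), cfg$fdr))
  invisible(res)
}

stage_stability <- function(cfg) {
  cm <- if (!is.null(cfg$counts_tsv)) {
    read_count_matrix(cfg$counts_tsv)
  } else {
    require_stage(cfg, "counts_gene_filtered.tsv", "count")
    read_count_matrix(store_path(cfg, "counts_gene_filtered.tsv"))
  }
  st <- thinning_stability(cm, n_iter = cfg$stability_iters, fdr = cfg$fdr,
                           seed = cfg$seed)
  write_tsv(st$per_gene, store_path(cfg, "stability_per_gene.tsv"))
  write_tsv(st$bins, store_path(cfg, "stability_bins.tsv"))
  log_stage(cfg, "stability",
            sprintf("%d reference-significant genes over %d iterations",
                    nrow(st$per_gene), cfg$stability_iters))
  invisible(st)
}

stage_go <- function(cfg) {
  require_stage(cfg, "dge.tsv", "dge")
  abort_if(is.null(cfg$go_dag) || is.null(cfg$go_annotations),
           "go stage needs go_dag and go_annotations inputs")
  dge <- read_tsv(store_path(cfg, "dge.tsv"))
  dag <- read_go_dag(cfg$go_dag)
  ann <- read_annotations(cfg$go_annotations, dag)
  study <- dge$gene_id[dge$q_value <= cfg$fdr]
  population <- dge$gene_id
  methods <- if (cfg$go_method == "all") {
    c("term_for_term", "parent_child", "permutation")
  } else cfg$go_method
  out <- list()
  for (m in methods) {
    res <- switch(m,
      term_for_term = term_for_term(study, population, dag, ann),
      parent_child = parent_child(study, population, dag, ann),
      permutation = perm_enrichment(study, population, dag, ann,
                                    seed = cfg$seed))
    write_tsv(res, store_path(cfg, paste0("go_", m, ".tsv")))
    out[[m]] <- res
  }
  log_stage(cfg, "go", paste("methods:", paste(methods, collapse = ", ")))
  invisible(out)
}

#' Export tables from a pipeline store
#'
#' @param cfg a `pipeline_config` (or a store path).
#' @param what one of "alignments", "counts", "counts-filtered", "dge", "gff3",
#'   "icc".
#' @return path of the exported file.
#' @export
export_store <- function(cfg, what) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(store = cfg)
  files <- c(alignments = "alignments.sam", counts = "counts_gene.tsv",
             `counts-filtered` = "counts_gene_filtered.tsv", dge = "dge.tsv",
             gff3 = file.path("reference", "catalog.gff3"),
             icc = file.path("assess", "icc.tsv"))
  abort_if(!what %in% names(files),
           "unknown table '", what, "'; available: ",
           paste(names(files), collapse = ", "))
  p <- store_path(cfg, files[[what]])
  abort_if(!file.exists(p), "table '", what, "' not present in the store")
  p
}
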