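#' Construct a count matrix object
#'
#' @param counts numeric matrix, genes x replicates (rownames = gene ids,
#'   colnames = replicate ids).
#' @param treatments character vector of treatment labels, one per replicate
#'   (named by replicate id or in column order).
#' @param library_sizes per-replicate totals of usable counts; defaults to the
#'   column sums of `counts` and is preserved across filtering.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, treatments, library_sizes = colSums(counts)) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  abort_if(any(counts < 0), "counts must be non-negative")
  if (is.null(names(treatments))) names(treatments) <- colnames(counts)
  treatments <- treatments[colnames(counts)]
  abort_if(anyNA(treatments), "every replicate needs a treatment label")
  structure(list(counts = counts, treatments = treatments,
                 library_sizes = stats::setNames(as.numeric(library_sizes),
                                                 colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Count matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "replicates; treatments:",
      paste(sprintf("%s=%d", names(table(x$treatments)),
                    as.integer(table(x$treatments))), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Classify aligned reads by gene-locus unambiguity
#'
#' A read is *unambiguous and usable* when every one of its best-stratum
#' alignments falls within annotated features of exactly one gene locus.
#' Genome hits are resolved by overlap with the catalog's typed feature
#' intervals; junction and transcript hits resolve through the junction or
#' isoform's gene. Reads whose alignments touch more than one locus are
#' `ambiguous`; reads aligning only outside annotation are `intergenic`.
#'
#' @param hits data.frame of best-stratum hits from [align_reads()] or
#'   [read_sam()] (read_id, seq_id, pos, strand, mismatches, target_kind).
#' @param catalog a `feature_catalog`.
#' @param read_lengths named integer vector (read_id -> length), needed for
#'   genome-hit overlap; defaults to `nchar` of a `seq` column if present.
#' @return data.frame: read_id, status
#'   ("unambiguous"/"ambiguous"/"intergenic"), gene_id, isoform_ids
#'   (comma-collapsed).
#' @export
classify_reads <- function(hits, catalog, read_lengths = NULL) {
  if (!nrow(hits)) {
    return(data.frame(read_id = character(0), status = character(0),
                      gene_id = character(0), isoform_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(read_lengths)) {
    abort_if(is.null(hits$seq), "read_lengths needed (or a seq column)")
    read_lengths <- tapply(nchar(hits$seq), hits$read_id, `[`, 1L)
  }
  if (!("target_kind" %in% names(hits))) {
    hits$target_kind <- ifelse(hits$seq_id %in% names(catalog$sequences),
                               "genome",
                        ifelse(hits$seq_id %in% catalog$junctions$junction_id,
                               "junction", "transcript"))
  }
  n <- nrow(hits)
  gene_per_hit <- vector("list", n)
  iso_per_hit <- vector("list", n)

  gi <- which(hits$target_kind == "genome")
  if (length(gi) && nrow(catalog$features)) {
    L <- as.integer(read_lengths[hits$read_id[gi]])
    q <- GenomicRanges::GRanges(hits$seq_id[gi],
                                IRanges::IRanges(start = hits$pos[gi] + 1L,
                                                 width = L))
    fts <- GenomicRanges::GRanges(catalog$features$seq_id,
                                  IRanges::IRanges(
                                    start = catalog$features$start + 1L,
                                    end = catalog$features$end))
    ov <- GenomicRanges::findOverlaps(q, fts, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (length(qh)) {
      gsplit <- split(catalog$features$gene_id[sh], qh)
      isplit <- split(catalog$features$isoform_ids[sh], qh)
      for (key in names(gsplit)) {
        j <- gi[as.integer(key)]
        gene_per_hit[[j]] <- unique(gsplit[[key]])
        iso_per_hit[[j]] <- unique(unlist(
          strsplit(isplit[[key]], ",", fixed = TRUE)))
      }
    }
  }
  ji <- which(hits$target_kind == "junction")
  if (length(ji)) {
    m <- match(hits$seq_id[ji], catalog$junctions$junction_id)
    for (idx in seq_along(ji)) {
      j <- ji[idx]
      if (is.na(m[idx])) next
      gene_per_hit[[j]] <- catalog$junctions$gene_id[m[idx]]
      iso_per_hit[[j]] <- strsplit(catalog$junctions$isoform_ids[m[idx]],
                                   ",", fixed = TRUE)[[1]]
    }
  }
  ti <- which(hits$target_kind == "transcript")
  if (length(ti)) {
    m <- match(hits$seq_id[ti], catalog$isoforms$isoform_id)
    for (idx in seq_along(ti)) {
      j <- ti[idx]
      if (is.na(m[idx])) next
      gene_per_hit[[j]] <- catalog$isoforms$gene_id[m[idx]]
      iso_per_hit[[j]] <- hits$seq_id[j]
    }
  }

  reads <- unique(hits$read_id)
  out <- data.frame(read_id = reads, status = "intergenic",
                    gene_id = NA_character_, isoform_ids = NA_character_,
                    stringsAsFactors = FALSE)
  hit_rows <- split(seq_len(n), hits$read_id)
  for (i in seq_along(reads)) {
    rows <- hit_rows[[reads[i]]]
    genes <- unique(unlist(gene_per_hit[rows]))
    if (is.null(genes) || !length(genes)) next
    any_orphan <- any(vapply(gene_per_hit[rows],
                             function(g) is.null(g) || !length(g), logical(1)))
    if (length(genes) == 1L && !any_orphan) {
      out$status[i] <- "unambiguous"
      out$gene_id[i] <- genes
      out$isoform_ids[i] <- paste(sort(unique(unlist(iso_per_hit[rows]))),
                                  collapse = ",")
    } else {
      out$status[i] <- "ambiguous"
    }
  }
  out
}

#' Accumulate gene- and isoform-level counts
#'
#' Each unambiguous unique read contributes its full per-replicate occurrence
#' count to its gene, once per occurrence regardless of how many placements it
#' has inside that locus. When the read maps to m isoforms of the gene, the
#' occurrences are split equally, 1/m to each isoform, so isoform counts may
#' be fractional while gene counts stay integral.
#'
#' @param classified output of [classify_reads()].
#' @param occurrences unique-read x replicate occurrence matrix (rownames =
#'   read ids), e.g. `store$occurrences`.
#' @param treatments named character vector replicate_id -> treatment.
#' @param gene_ids optional character vector fixing the gene universe (rows of
#'   the result); defaults to the genes observed.
#' @return list with `gene` (a `count_matrix`) and `isoform` (numeric matrix).
#' @export
accumulate_counts <- function(classified, occurrences, treatments,
                              gene_ids = NULL) {
  un <- classified[classified$status == "unambiguous", , drop = FALSE]
  reps <- colnames(occurrences)
  if (is.null(gene_ids)) gene_ids <- sort(unique(un$gene_id))
  gmat <- matrix(0, nrow = length(gene_ids), ncol = length(reps),
                 dimnames = list(gene_ids, reps))
  imat <- NULL
  if (nrow(un)) {
    occ <- occurrences[un$read_id, , drop = FALSE]
    gsum <- rowsum(occ, group = un$gene_id)
    gmat[rownames(gsum), ] <- gsum
    iso_list <- strsplit(un$isoform_ids, ",", fixed = TRUE)
    m <- lengths(iso_list)
    rep_rows <- rep(seq_len(nrow(un)), m)
    frac <- occ[rep_rows, , drop = FALSE] / m[rep_rows]
    imat <- rowsum(frac, group = unlist(iso_list))
  }
  list(gene = count_matrix(gmat, treatments),
       isoform = imat)
}

#' Expression filter
#'
#' A gene is retained when at least one treatment has a positive count in
#' every one of its replicates. Library sizes (column sums before filtering)
#' are carried through unchanged.
#'
#' @param mat a `count_matrix`.
#' @return the filtered `count_matrix`.
#' @export
expression_filter <- function(mat) {
  stopifnot(inherits(mat, "count_matrix"))
  keep <- rep(FALSE, nrow(mat$counts))
  for (t in unique(mat$treatments)) {
    cols <- names(mat$treatments)[mat$treatments == t]
    keep <- keep | apply(mat$counts[, cols, drop = FALSE] > 0, 1, all)
  }
  count_matrix(mat$counts[keep, , drop = FALSE], mat$treatments,
               mat$library_sizes)
}

#' Write a count matrix as TSV
#'
#' The header row carries treatment labels as `replicate|treatment`; this is
#' the hand-off format for external statistics packages.
#'
#' @param mat a `count_matrix`.
#' @param path output file.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat$counts), mat$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- paste(colnames(mat$counts), mat$treatments, sep = "|")
  write_tsv(df, path)
}

#' Read a count matrix TSV
#'
#' @param path file written by [write_count_matrix()] (gene_id column plus one
#'   `replicate|treatment` column per replicate).
#' @return a `count_matrix`.
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv(path)
  abort_if(names(df)[1] != "gene_id", "first column must be gene_id")
  cn <- names(df)[-1]
  parts <- strsplit(cn, "|", fixed = TRUE)
  abort_if(any(lengths(parts) != 2L),
           "column headers must be replicate|treatment")
  reps <- vapply(parts, `[`, "", 1L)
  trts <- vapply(parts, `[`, "", 2L)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df$gene_id, reps)
  count_matrix(m, stats::setNames(trts, reps))
}
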