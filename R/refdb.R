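#' Load a reference catalog from FASTA and GFF3
#'
#' Builds the feature catalog backing alignment and counting: contig
#' sequences, gene loci with their classifications, transcript isoforms, and
#' typed feature intervals (exons, UTRs, CDS, retained introns, ...).
#' Internally all coordinates are 0-based half-open; GFF3's 1-based inclusive
#' coordinates are converted on the way in and out.
#'
#' Record-level problems (malformed lines, features whose Parent transcript is
#' missing, transcripts whose Parent gene is missing) are collected in the
#' catalog's `rejects` table, never silently dropped. A feature placed on a
#' sequence absent from the FASTA is a hard error naming the offending seq_id.
#'
#' Gene class and transcript type vocabularies are open: whatever GFF3 column
#' 3 carries is kept. Feature records sharing coordinates, type and gene are
#' merged, accumulating the isoform ids that contain them.
#'
#' @param fasta_source path to a (multi-record) FASTA file, or a named
#'   character vector of sequences.
#' @param gff3_source path to a GFF3 file, or a character vector of GFF3
#'   lines.
#' @return an object of class `feature_catalog` with elements `sequences`,
#'   `genes`, `isoforms`, `features`, `junctions`, `rejects`.
#' @export
load_reference <- function(fasta_source, gff3_source) {
  sequences <- if (is.character(fasta_source) && length(fasta_source) == 1L &&
                   file.exists(fasta_source)) {
    ss <- Biostrings::readDNAStringSet(fasta_source)
    stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else {
    abort_if(is.null(names(fasta_source)), "FASTA sequences must be named")
    fasta_source
  }
  lines <- if (length(gff3_source) == 1L && file.exists(gff3_source)) {
    readLines(gff3_source)
  } else gff3_source

  rej_line <- integer(0); rej_reason <- character(0)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      rej_line <- c(rej_line, i); rej_reason <- c(rej_reason, "malformed line")
      next
    }
    st <- suppressWarnings(as.integer(f[4])); en <- suppressWarnings(as.integer(f[5]))
    if (is.na(st) || is.na(en) || st < 1L || en < st) {
      rej_line <- c(rej_line, i); rej_reason <- c(rej_reason, "bad coordinates")
      next
    }
    at <- parse_gff3_attributes(f[9])
    recs[[i]] <- list(line = i, seq_id = f[1], type = f[3],
                      start = st - 1L, end = en, strand = f[7],
                      id = at[["ID"]], parents = at[["Parent"]])
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]

  has_parent <- vapply(recs, function(r) !is.null(r$parents), logical(1))
  ids <- vapply(recs, function(r) if (is.null(r$id)) NA_character_ else r$id,
                character(1))
  gene_rec <- recs[!has_parent]
  gene_ids <- ids[!has_parent]
  bad <- is.na(gene_ids)
  for (r in gene_rec[bad]) {
    rej_line <- c(rej_line, r$line)
    rej_reason <- c(rej_reason, "top-level record without ID")
  }
  gene_rec <- gene_rec[!bad]; gene_ids <- gene_ids[!bad]

  missing_seq <- setdiff(vapply(gene_rec, `[[`, "", "seq_id"), names(sequences))
  abort_if(length(missing_seq) > 0,
           "GFF3 references sequence(s) absent from FASTA: ",
           paste(unique(missing_seq), collapse = ", "))

  genes <- data.frame(
    gene_id = gene_ids,
    class = vapply(gene_rec, `[[`, "", "type"),
    seq_id = vapply(gene_rec, `[[`, "", "seq_id"),
    start = vapply(gene_rec, function(r) r$start, integer(1)),
    end = vapply(gene_rec, function(r) r$end, integer(1)),
    strand = vapply(gene_rec, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  abort_if(anyDuplicated(genes$gene_id) > 0, "duplicate gene IDs in GFF3")

  # transcripts: children of genes
  tx_rec <- list(); tx_ids <- character(0); tx_gene <- character(0)
  feat_rec <- list()
  for (r in recs[has_parent]) {
    if (all(r$parents %in% genes$gene_id)) {
      if (is.null(r$id)) {
        rej_line <- c(rej_line, r$line)
        rej_reason <- c(rej_reason, "transcript without ID")
        next
      }
      if (length(r$parents) != 1L) {
        rej_line <- c(rej_line, r$line)
        rej_reason <- c(rej_reason, "transcript with multiple gene parents")
        next
      }
      tx_rec <- c(tx_rec, list(r)); tx_ids <- c(tx_ids, r$id)
      tx_gene <- c(tx_gene, r$parents)
    } else {
      feat_rec <- c(feat_rec, list(r))
    }
  }
  isoforms <- data.frame(isoform_id = tx_ids, gene_id = tx_gene,
                         type = vapply(tx_rec, `[[`, "", "type"),
                         stringsAsFactors = FALSE)
  abort_if(anyDuplicated(isoforms$isoform_id) > 0,
           "duplicate transcript IDs in GFF3")

  frows <- list()
  for (r in feat_rec) {
    known <- r$parents %in% isoforms$isoform_id
    if (!all(known)) {
      rej_line <- c(rej_line, r$line)
      rej_reason <- c(rej_reason,
                      paste0("feature parent not found: ",
                             paste(r$parents[!known], collapse = ",")))
      next
    }
    g <- unique(isoforms$gene_id[match(r$parents, isoforms$isoform_id)])
    if (length(g) != 1L) {
      rej_line <- c(rej_line, r$line)
      rej_reason <- c(rej_reason, "feature spans multiple gene loci")
      next
    }
    if (!(r$seq_id %in% names(sequences))) {
      stop("feature on sequence absent from FASTA: ", r$seq_id, call. = FALSE)
    }
    if (r$end > nchar(sequences[[r$seq_id]])) {
      rej_line <- c(rej_line, r$line)
      rej_reason <- c(rej_reason, "feature beyond sequence end")
      next
    }
    frows[[length(frows) + 1L]] <- data.frame(
      seq_id = r$seq_id, start = r$start, end = r$end, strand = r$strand,
      ftype = r$type, gene_id = g,
      isoform_ids = paste(sort(r$parents), collapse = ","),
      stringsAsFactors = FALSE)
  }
  features <- if (length(frows)) do.call(rbind, frows) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), ftype = character(0),
               gene_id = character(0), isoform_ids = character(0),
               stringsAsFactors = FALSE)
  features <- merge_shared_features(features)

  cat <- structure(list(
    sequences = sequences, genes = genes, isoforms = isoforms,
    features = features,
    junctions = empty_junctions(),
    rejects = data.frame(line = rej_line, reason = rej_reason,
                         stringsAsFactors = FALSE)
  ), class = "feature_catalog")
  cat
}

parse_gff3_attributes <- function(x) {
  out <- list()
  for (kv in strsplit(x, ";", fixed = TRUE)[[1]]) {
    kv <- trimws(kv)
    if (!nzchar(kv)) next
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    key <- substr(kv, 1L, eq - 1L)
    val <- substr(kv, eq + 1L, nchar(kv))
    out[[key]] <- strsplit(val, ",", fixed = TRUE)[[1]]
  }
  out
}

# merge duplicate feature records, unioning isoform id sets
merge_shared_features <- function(features) {
  if (!nrow(features)) return(features)
  key <- paste(features$seq_id, features$start, features$end, features$strand,
               features$ftype, features$gene_id, sep = "\r")
  iso <- tapply(features$isoform_ids, key, function(v) {
    paste(sort(unique(unlist(strsplit(v, ",", fixed = TRUE)))), collapse = ",")
  })
  first <- !duplicated(key)
  out <- features[first, , drop = FALSE]
  out$isoform_ids <- as.character(iso[key[first]])
  out <- out[order(out$seq_id, out$start, out$end, out$ftype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_junctions <- function() {
  data.frame(junction_id = character(0), gene_id = character(0),
             isoform_ids = character(0), seq = character(0),
             seq_id = character(0), strand = character(0),
             donor_end = integer(0), acceptor_start = integer(0),
             short = logical(0), stringsAsFactors = FALSE)
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat("Feature catalog:", length(x$sequences), "sequence(s),",
      nrow(x$genes), "genes,", nrow(x$isoforms), "isoforms,",
      nrow(x$features), "feature intervals,",
      nrow(x$junctions), "splice junctions\n")
  if (nrow(x$rejects)) cat("  ", nrow(x$rejects), "rejected GFF3 record(s)\n")
  invisible(x)
}

#' Derive splice-junction sequences for a catalog
#'
#' For each pair of exons adjacent within an isoform, concatenates the last
#' `flank` bases of the upstream exon with the first `flank` bases of the
#' downstream exon (genomic order), reverse-complementing the result for
#' minus-strand isoforms so the stored junction reads 5' to 3' along the
#' transcript. With `flank` set to one less than the read length, any read
#' crossing the junction fits entirely within the junction sequence. Exons
#' shorter than `flank` contribute their full length and the junction is
#' flagged `short`. Junctions with identical sequence within the same gene are
#' collapsed.
#'
#' @param catalog a `feature_catalog`.
#' @param flank bases taken from each side of the junction (>= 1).
#' @return the catalog with its `junctions` table populated.
#' @export
build_junctions <- function(catalog, flank = 24L) {
  stopifnot(inherits(catalog, "feature_catalog"), flank >= 1L)
  ex <- catalog$features[catalog$features$ftype == "exon", , drop = FALSE]
  rows <- list()
  for (iso in catalog$isoforms$isoform_id) {
    in_iso <- grepl(paste0("(^|,)", iso, "(,|$)"), ex$isoform_ids)
    e <- ex[in_iso, , drop = FALSE]
    if (nrow(e) < 2L) next
    e <- e[order(e$start), , drop = FALSE]
    gene <- e$gene_id[1]
    seq <- catalog$sequences[[e$seq_id[1]]]
    strand <- e$strand[1]
    for (j in seq_len(nrow(e) - 1L)) {
      up <- e[j, ]; dn <- e[j + 1L, ]
      f_up <- min(flank, up$end - up$start)
      f_dn <- min(flank, dn$end - dn$start)
      left <- substr(seq, up$end - f_up + 1L, up$end)          # 1-based substr
      right <- substr(seq, dn$start + 1L, dn$start + f_dn)
      jseq <- paste0(left, right)
      if (strand == "-") jseq <- revcomp(jseq)
      rows[[length(rows) + 1L]] <- data.frame(
        junction_id = NA_character_, gene_id = gene, isoform_ids = iso,
        seq = jseq, seq_id = up$seq_id[1], strand = strand,
        donor_end = up$end, acceptor_start = dn$start,
        short = (f_up < flank || f_dn < flank), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    catalog$junctions <- empty_junctions()
    return(catalog)
  }
  jn <- do.call(rbind, rows)
  # collapse duplicates (same gene, same sequence), unioning isoform ids
  key <- paste(jn$gene_id, jn$seq, sep = "\r")
  iso <- tapply(jn$isoform_ids, key, function(v)
    paste(sort(unique(v)), collapse = ","))
  first <- !duplicated(key)
  jn <- jn[first, , drop = FALSE]
  jn$isoform_ids <- as.character(iso[key[first]])
  jn <- jn[order(jn$gene_id, jn$donor_end, jn$acceptor_start), , drop = FALSE]
  cnt <- stats::ave(seq_len(nrow(jn)), jn$gene_id, FUN = seq_along)
  jn$junction_id <- paste0(jn$gene_id, ".J", cnt)
  rownames(jn) <- NULL
  catalog$junctions <- jn
  catalog
}

#' Export a catalog's annotation as GFF3
#'
#' Inverse of [load_reference()]: writes gene, transcript and feature records
#' (1-based inclusive coordinates) with ID/Parent attributes such that
#' re-loading yields an identical catalog.
#'
#' @param catalog a `feature_catalog`.
#' @param path optional output file.
#' @return invisibly, the character vector of GFF3 lines.
#' @export
export_gff3 <- function(catalog, path = NULL) {
  g <- catalog$genes
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$seq_id[i], "seqdge", g$class[i],
                              g$start[i] + 1L, g$end[i], g$strand[i],
                              g$gene_id[i]))
    iso <- catalog$isoforms[catalog$isoforms$gene_id == g$gene_id[i], ,
                            drop = FALSE]
    for (j in seq_len(nrow(iso))) {
      fe <- catalog$features[
        grepl(paste0("(^|,)", iso$isoform_id[j], "(,|$)"),
              catalog$features$isoform_ids), , drop = FALSE]
      tx_start <- if (nrow(fe)) min(fe$start) else g$start[i]
      tx_end <- if (nrow(fe)) max(fe$end) else g$end[i]
      lines <- c(lines, sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                                g$seq_id[i], "seqdge", iso$type[j],
                                tx_start + 1L, tx_end, g$strand[i],
                                iso$isoform_id[j], g$gene_id[i]))
    }
    ge_feats <- catalog$features[catalog$features$gene_id == g$gene_id[i], ,
                                 drop = FALSE]
    for (j in seq_len(nrow(ge_feats))) {
      lines <- c(lines, sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
                                ge_feats$seq_id[j], "seqdge",
                                ge_feats$ftype[j], ge_feats$start[j] + 1L,
                                ge_feats$end[j], ge_feats$strand[j],
                                ge_feats$isoform_ids[j]))
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Reference sequence set for alignment
#'
#' Assembles the named sequences the aligner should index: genome contigs
#' and/or spliced transcript sequences, plus the catalog's splice-junction
#' sequences, each tagged with its kind.
#'
#' @param catalog a `feature_catalog`.
#' @param target "genome", "transcriptome", or "both".
#' @return named character vector with attribute `kind` ("genome",
#'   "transcript" or "junction" per sequence).
#' @export
reference_set <- function(catalog,
                          target = c("genome", "transcriptome", "both")) {
  target <- match.arg(target)
  seqs <- character(0); kind <- character(0)
  if (target %in% c("genome", "both")) {
    seqs <- c(seqs, catalog$sequences)
    kind <- c(kind, rep("genome", length(catalog$sequences)))
  }
  if (target %in% c("transcriptome", "both")) {
    tx <- transcript_sequences(catalog)
    seqs <- c(seqs, tx)
    kind <- c(kind, rep("transcript", length(tx)))
  }
  if (nrow(catalog$junctions)) {
    jn <- stats::setNames(catalog$junctions$seq, catalog$junctions$junction_id)
    seqs <- c(seqs, jn)
    kind <- c(kind, rep("junction", length(jn)))
  }
  attr(seqs, "kind") <- stats::setNames(kind, names(seqs))
  seqs
}

#' Spliced transcript sequences
#'
#' @param catalog a `feature_catalog`.
#' @return named character vector, one entry per isoform (exon concatenation,
#'   reverse-complemented for minus-strand isoforms).
#' @export
transcript_sequences <- function(catalog) {
  ex <- catalog$features[catalog$features$ftype == "exon", , drop = FALSE]
  out <- character(0)
  for (iso in catalog$isoforms$isoform_id) {
    e <- ex[grepl(paste0("(^|,)", iso, "(,|$)"), ex$isoform_ids), ,
            drop = FALSE]
    if (!nrow(e)) next
    e <- e[order(e$start), , drop = FALSE]
    seq <- catalog$sequences[[e$seq_id[1]]]
    tx <- paste(substring(seq, e$start + 1L, e$end), collapse = "")
    if (e$strand[1] == "-") tx <- revcomp(tx)
    out[iso] <- tx
  }
  out
}
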