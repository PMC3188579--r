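#' Reads-per-quarter-million log transform
#'
#' Scales a column of counts to reads per 250,000, adds one to handle zeroes,
#' and takes the natural log: `ln(count * 250000 / library_size + 1)`.
#'
#' @param counts numeric vector of raw counts.
#' @param library_size positive library total for the column.
#' @return transformed numeric vector.
#' @export
rpqm_log <- function(counts, library_size) {
  abort_if(library_size <= 0, "library_size must be positive")
  log(counts * 250000 / library_size + 1)
}

#' Intraclass correlation coefficient for replicate agreement
#'
#' One-way random-effects, single-rater ICC over a genes x replicates matrix
#' of transformed counts: `(MSB - MSW) / (MSB + (k - 1) * MSW)` with rows
#' (genes) as the grouping factor and k replicates. Values near 1 indicate
#' close replicate agreement; values at or below 0 indicate no between-gene
#' signal relative to replicate noise and are flagged.
#'
#' @param mat numeric matrix (genes x replicates), already transformed (see
#'   [rpqm_log()]).
#' @return the ICC value; attribute `flag` is set to "no between-gene
#'   variance" when MSB <= MSW.
#' @export
icc <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L, nrow(mat) >= 2L)
  n <- nrow(mat); k <- ncol(mat)
  row_means <- rowMeans(mat)
  grand <- mean(mat)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((mat - row_means)^2) / (n * (k - 1))
  val <- (msb - msw) / (msb + (k - 1) * msw)
  if (msb <= msw) attr(val, "flag") <- "no between-gene variance"
  val
}

#' Per-treatment ICC report
#'
#' Applies the quarter-million log transform column-wise and computes one ICC
#' per treatment having at least two replicates.
#'
#' @param mat a `count_matrix` (raw counts; library sizes from the object).
#' @return named numeric vector, one ICC per eligible treatment.
#' @export
icc_report <- function(mat) {
  stopifnot(inherits(mat, "count_matrix"))
  tf <- mat$counts
  for (j in seq_len(ncol(tf))) {
    tf[, j] <- rpqm_log(mat$counts[, j], mat$library_sizes[j])
  }
  out <- numeric(0)
  for (t in unique(mat$treatments)) {
    cols <- names(mat$treatments)[mat$treatments == t]
    if (length(cols) < 2L) next
    out[t] <- as.numeric(icc(tf[, cols, drop = FALSE]))
  }
  out
}

#' MA coordinates for a two-treatment comparison
#'
#' With per-treatment means of normalized counts m1 and m2 (one is added
#' before the log to keep every point finite):
#' `M = log2(m1 + 1) - log2(m2 + 1)` and
#' `A = (log2(m1 + 1) + log2(m2 + 1)) / 2`.
#'
#' @param mat a `count_matrix` of normalized counts with exactly two
#'   treatments.
#' @param treatment_order optional length-2 character vector fixing which
#'   treatment is "1" (numerator) and which is "2".
#' @return data.frame gene_id, M, A.
#' @export
ma_points <- function(mat, treatment_order = NULL) {
  stopifnot(inherits(mat, "count_matrix"))
  trts <- if (is.null(treatment_order)) unique(mat$treatments) else
    treatment_order
  abort_if(length(trts) != 2L, "exactly two treatments required")
  m1 <- rowMeans(mat$counts[, names(mat$treatments)[mat$treatments == trts[1]],
                            drop = FALSE])
  m2 <- rowMeans(mat$counts[, names(mat$treatments)[mat$treatments == trts[2]],
                            drop = FALSE])
  data.frame(gene_id = rownames(mat$counts),
             M = log2(m1 + 1) - log2(m2 + 1),
             A = (log2(m1 + 1) + log2(m2 + 1)) / 2,
             stringsAsFactors = FALSE)
}

#' Replicate and alignment summaries
#'
#' Per-replicate bookkeeping across the preprocessing, alignment and counting
#' stages: raw read totals, retention after trimming and ambiguity exclusion,
#' alignment and unambiguous-usable percentages, and per-feature-type tallies
#' of the catalog.
#'
#' @param store a `read_store`.
#' @param classified output of [classify_reads()] (may be NULL before
#'   counting).
#' @param catalog optional `feature_catalog` for feature-type tallies.
#' @return list with `replicates` (data.frame) and `feature_types` (table).
#' @export
summaries <- function(store, classified = NULL, catalog = NULL) {
  occ <- store$occurrences
  raw <- colSums(occ) + store$dropped[colnames(occ)] +
    store$ambiguous[colnames(occ)]
  df <- data.frame(replicate_id = colnames(occ),
                   raw_reads = as.integer(raw),
                   dropped_short = as.integer(store$dropped[colnames(occ)]),
                   ambiguous_base = as.integer(store$ambiguous[colnames(occ)]),
                   retained = as.integer(colSums(occ)),
                   stringsAsFactors = FALSE)
  if (!is.null(classified)) {
    aligned_ids <- classified$read_id
    un_ids <- classified$read_id[classified$status == "unambiguous"]
    present <- intersect(aligned_ids, rownames(occ))
    df$aligned <- as.integer(colSums(occ[present, , drop = FALSE]))
    df$unambiguous <- as.integer(colSums(
      occ[intersect(un_ids, rownames(occ)), , drop = FALSE]))
    df$pct_aligned <- 100 * df$aligned / pmax(df$retained, 1L)
    df$pct_unambiguous <- 100 * df$unambiguous / pmax(df$retained, 1L)
  }
  ft <- if (!is.null(catalog)) {
    c(table(catalog$features$ftype),
      splice_junction = nrow(catalog$junctions))
  } else NULL
  list(replicates = df, feature_types = ft)
}
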