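#' Normalize a count matrix by random thinning
#'
#' Downsamples every replicate binomially to the smallest library size N:
#' each count c in a replicate with library size L is replaced by a
#' Binomial(c, N/L) draw, so all column totals match N in expectation and the
#' exact test's equal-library assumption holds. Replicates already at the
#' minimum are untouched. One top-level seed deterministically derives one
#' RNG substream per replicate, so a run is bit-reproducible.
#'
#' @param mat a `count_matrix` with integral counts.
#' @param seed integer seed controlling the thinning draws.
#' @return a `count_matrix` of thinned counts; attribute `target_size` is N.
#' @export
thin_counts <- function(mat, seed) {
  stopifnot(inherits(mat, "count_matrix"))
  abort_if(any(mat$counts != round(mat$counts)),
           "thinning requires integral gene-level counts")
  L <- mat$library_sizes
  abort_if(any(L <= 0), "library sizes must be positive")
  N <- min(L)
  out <- mat$counts
  sub <- derive_seeds(seed, ncol(out))
  for (j in seq_len(ncol(out))) {
    if (L[j] == N) next
    out[, j] <- with_seed(sub[j], rbinom(nrow(out), size = out[, j],
                                         prob = N / L[j]))
  }
  res <- count_matrix(out, mat$treatments, colSums(out))
  attr(res, "target_size") <- N
  res
}

#' Fit the NBP dispersion model
#'
#' The NBP model is a negative binomial whose dispersion depends on the mean:
#' `Var(Y) = mu + phi * mu^alpha`, equivalently NB size
#' `r(mu) = mu^(2 - alpha) / phi`. `alpha = 2` recovers the classical NB with
#' a constant dispersion phi. The two shape parameters are estimated by
#' maximizing the Cox-Reid adjusted profile log-likelihood pooled over all
#' genes, with each gene's mean fixed at its sample mean within each
#' treatment group (so genuinely differentially expressed genes do not
#' masquerade as dispersion) and alpha constrained to [1.2, 3]. The Cox-Reid
#' term (half the log Fisher information of every profiled-out group mean)
#' removes the downward dispersion bias that plugging in estimated means
#' would otherwise cause. Genes whose group mean is zero contribute nothing
#' for that group.
#'
#' @param mat a `count_matrix` of thinned counts (filtered; >= 2 replicates).
#' @param alpha_bounds search interval for alpha.
#' @return object of class `nbp_fit`: list with `phi`, `alpha`, `mu_hat`
#'   (pooled per-gene means, the null estimate used by the exact test),
#'   `logLik`, `convergence`.
#' @export
fit_nbp <- function(mat, alpha_bounds = c(1.2, 3)) {
  stopifnot(inherits(mat, "count_matrix"), ncol(mat$counts) >= 2L)
  y <- mat$counts
  mu <- rowMeans(y)
  groups <- unique(mat$treatments)
  mm <- y * 0
  n_in_group <- stats::setNames(numeric(length(groups)), groups)
  for (g in groups) {
    cols <- names(mat$treatments)[mat$treatments == g]
    n_in_group[g] <- length(cols)
    mm[, cols] <- rowMeans(y[, cols, drop = FALSE])
  }
  pos <- mm > 0                                  # cells with a usable mean
  yy <- y[pos]; mmv <- mm[pos]
  # one Cox-Reid term per profiled-out (gene, group) mean
  cr_mu <- cr_n <- numeric(0)
  for (g in groups) {
    col1 <- names(mat$treatments)[mat$treatments == g][1]
    gm <- mm[, col1]
    cr_mu <- c(cr_mu, gm[gm > 0])
    cr_n <- c(cr_n, rep(n_in_group[g], sum(gm > 0)))
  }
  negll <- function(par) {
    phi <- exp(par[1]); alpha <- par[2]
    size <- mmv^(2 - alpha) / phi
    ll <- sum(dnbinom(yy, size = size, mu = mmv, log = TRUE))
    cr <- -0.5 * sum(log(cr_n / (cr_mu + phi * cr_mu^alpha)))
    -(ll + cr)
  }
  fit <- tryCatch(
    optim(c(log(0.1), 2), negll, method = "L-BFGS-B",
          lower = c(-12, alpha_bounds[1]), upper = c(5, alpha_bounds[2])),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) {
    warning("joint (phi, alpha) optimization did not converge; ",
            "falling back to the alpha = 2 profile")
    prof <- stats::optimize(function(lp) negll(c(lp, 2)), c(-12, 5))
    fit <- list(par = c(prof$minimum, 2), value = prof$objective,
                convergence = 1L)
  }
  structure(list(phi = exp(fit$par[1]), alpha = fit$par[2],
                 mu_hat = mu, logLik = -fit$value,
                 convergence = fit$convergence),
            class = "nbp_fit")
}

#' @export
print.nbp_fit <- function(x, ...) {
  cat(sprintf("NBP dispersion fit: phi = %.4g, alpha = %.4g (logLik %.2f)\n",
              x$phi, x$alpha, x$logLik))
  cat("  variance function: mu + phi * mu^alpha over", length(x$mu_hat),
      "genes\n")
  invisible(x)
}

#' Exact two-group test under the NBP model
#'
#' Conditional exact test of equal group means for one gene. Under the null
#' each replicate count is NB with mean mu and size r = mu^(2-alpha)/phi, so
#' the group sums are NB(n_A * r, p) and NB(n_B * r, p) with a common p.
#' Conditional on the total S, P(S_A = s | S) is proportional to
#' f(s; n_A r) * f(S - s; n_B r), and the two-sided p-value is the sum of the
#' conditional probabilities of all outcomes no more likely than the observed
#' one (the "sum of <=-likely outcomes" rule, with the conventional 1e-7
#' relative tolerance for floating-point ties). As phi tends to 0 the
#' conditional law tends to Binomial(S, n_A/(n_A+n_B)); sizes beyond 1e8 are
#' computed on that limit directly.
#'
#' @param y_a,y_b integer count vectors for the two groups (thinned to a
#'   common library size).
#' @param phi,alpha NBP dispersion parameters (see [fit_nbp()]).
#' @param mu pooled null mean estimate; defaults to the mean of all counts.
#' @return the two-sided p-value in (0, 1]. S = 0 gives p = 1.
#' @export
nbp_exact_test <- function(y_a, y_b, phi, alpha, mu = mean(c(y_a, y_b))) {
  sa <- sum(y_a); sb <- sum(y_b); S <- sa + sb
  if (S == 0 || mu <= 0) return(1)
  na <- length(y_a); nb <- length(y_b)
  r <- mu^(2 - alpha) / phi
  s <- 0:S
  logp <- if (!is.finite(r) || r > 1e8) {
    dbinom(s, S, na / (na + nb), log = TRUE)
  } else {
    dnbinom(s, size = na * r, mu = na * mu, log = TRUE) +
      dnbinom(S - s, size = nb * r, mu = nb * mu, log = TRUE)
  }
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p <- sum(pr[pr <= pr[sa + 1L] * (1 + 1e-7)])
  min(max(p, .Machine$double.xmin), 1)
}

#' Storey q-values
#'
#' Converts p-values to q-values with the proportion of true nulls pi0
#' estimated by the lambda-smoother: pi0(lambda) = #{p > lambda} /
#' (m (1 - lambda)) over lambda = 0.05, ..., 0.95, smoothed with a cubic
#' smoothing spline and read off at the largest lambda. With pi0 forced to 1
#' the result is exactly the Benjamini-Hochberg step-up adjustment. Fewer than
#' 100 p-values make the pi0 estimate unstable, so pi0 is then fixed at 1 with
#' a warning.
#'
#' @param p vector of p-values in (0, 1].
#' @param pi0 optionally override the null-proportion estimate.
#' @return vector of q-values (monotone in p-rank); attribute `pi0`.
#' @export
qvalues <- function(p, pi0 = NULL) {
  abort_if(any(p <= 0 | p > 1 | is.na(p)), "p-values must be in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100L) {
      warning("fewer than 100 p-values; fixing pi0 = 1")
      pi0 <- 1
    } else {
      lambda <- seq(0.05, 0.95, 0.05)
      pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      sp <- smooth.spline(lambda, pi0l, df = 3)
      pi0 <- predict(sp, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)
  structure(q[ro], pi0 = pi0)
}

#' Differential expression test under the NBP model
#'
#' The statistics stage in one call: thins the counts to the smallest library,
#' fits the NBP dispersion model, runs the per-gene conditional exact test of
#' the two treatments, and converts p-values to Storey q-values. Genes with
#' q-value at or below `fdr` form the significant set.
#'
#' @param mat a `count_matrix` with exactly two treatments (integral,
#'   expression-filtered gene-level counts).
#' @param seed integer seed for the thinning draws.
#' @param fdr false discovery rate cutoff used by the summary and plot
#'   methods (default 0.05).
#' @param treatment_order optional length-2 vector; the first treatment is the
#'   fold-change numerator ("induced" means higher there).
#' @return object of class `nbp_dge`: list with `table` (gene_id, counts
#'   means, normalized means, fold_change, direction, p_value, q_value),
#'   `fit` (the `nbp_fit`), `thinned` (the normalized `count_matrix`), `fdr`,
#'   `seed`, `treatments`.
#' @export
nbp_test <- function(mat, seed = 1L, fdr = 0.05, treatment_order = NULL) {
  stopifnot(inherits(mat, "count_matrix"))
  trts <- if (is.null(treatment_order)) unique(mat$treatments) else
    treatment_order
  abort_if(length(trts) != 2L, "exactly two treatments required")
  abort_if(any(mat$counts != round(mat$counts)),
           "gene-level integral counts required (isoform matrices are not accepted)")
  thinned <- thin_counts(mat, seed)
  fit <- fit_nbp(thinned)
  y <- thinned$counts
  colsA <- names(mat$treatments)[mat$treatments == trts[1]]
  colsB <- names(mat$treatments)[mat$treatments == trts[2]]
  pv <- vapply(seq_len(nrow(y)), function(i) {
    nbp_exact_test(y[i, colsA], y[i, colsB], fit$phi, fit$alpha,
                   mu = fit$mu_hat[i])
  }, numeric(1))
  qv <- qvalues(pv)
  mA <- rowMeans(y[, colsA, drop = FALSE])
  mB <- rowMeans(y[, colsB, drop = FALSE])
  tab <- data.frame(
    gene_id = rownames(y),
    mean_raw_1 = rowMeans(mat$counts[, colsA, drop = FALSE]),
    mean_raw_2 = rowMeans(mat$counts[, colsB, drop = FALSE]),
    mean_norm_1 = mA, mean_norm_2 = mB,
    fold_change = (mA + 1) / (mB + 1),
    direction = ifelse(mA >= mB, "induced", "repressed"),
    p_value = pv, q_value = as.numeric(qv),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, fit = fit, thinned = thinned, fdr = fdr,
                 seed = seed, treatments = trts,
                 pi0 = attr(qv, "pi0")),
            class = "nbp_dge")
}

#' @export
print.nbp_dge <- function(x, ...) {
  sig <- x$table$q_value <= x$fdr
  cat(sprintf(
    "NBP exact test: %d genes, %s vs %s (thinning seed %d)\n",
    nrow(x$table), x$treatments[1], x$treatments[2], x$seed))
  cat(sprintf("  dispersion: phi = %.4g, alpha = %.4g; pi0 = %.3f\n",
              x$fit$phi, x$fit$alpha, x$pi0))
  cat(sprintf("  significant at FDR <= %.2g: %d (%d induced, %d repressed)\n",
              x$fdr, sum(sig), sum(sig & x$table$direction == "induced"),
              sum(sig & x$table$direction == "repressed")))
  invisible(x)
}

#' @export
summary.nbp_dge <- function(object, fdr = object$fdr, ...) {
  tab <- object$table
  sig <- tab[tab$q_value <= fdr, , drop = FALSE]
  sig <- sig[order(sig$q_value, sig$p_value), , drop = FALSE]
  structure(list(fdr = fdr, n_genes = nrow(tab), significant = sig,
                 fit = object$fit, pi0 = object$pi0),
            class = "summary.nbp_dge")
}

#' @export
print.summary.nbp_dge <- function(x, ...) {
  cat(sprintf("%d of %d genes significant at FDR <= %.2g\n",
              nrow(x$significant), x$n_genes, x$fdr))
  print(x$fit)
  if (nrow(x$significant)) {
    print(utils::head(x$significant[, c("gene_id", "fold_change", "direction",
                                        "p_value", "q_value")], 10L),
          row.names = FALSE)
    if (nrow(x$significant) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' MA plot of an NBP test result
#'
#' @param x an `nbp_dge` object.
#' @param fdr highlight genes with q-value at or below this cutoff.
#' @param ... passed to [plot()].
#' @export
plot.nbp_dge <- function(x, fdr = x$fdr, ...) {
  ma <- ma_points(x$thinned, x$treatments)
  sig <- x$table$q_value <= fdr
  up <- sig & x$table$direction == "induced"
  dn <- sig & x$table$direction == "repressed"
  graphics::plot(ma$A, ma$M, pch = 20, cex = 0.5,
                 col = ifelse(up, "red", ifelse(dn, "darkgreen", "grey50")),
                 xlab = "A (mean log2 abundance)",
                 ylab = "M (log2 fold difference)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' @export
as.data.frame.nbp_dge <- function(x, ...) x$table

#' Stability of detections under repeated random thinning
#'
#' Re-runs the whole statistics stage (thin, fit, test, q-values) `n_iter`
#' times with fresh derived seeds, and reports, for every gene significant in
#' the reference run, the percentage of iterations in which it was detected
#' again at the same FDR, binned by the reference q-values in increments of
#' 0.005.
#'
#' @param mat a `count_matrix` (two treatments).
#' @param n_iter number of re-thinning iterations.
#' @param fdr significance cutoff applied in every run.
#' @param seed top-level seed: the reference run uses it directly and the
#'   iterations use substreams derived from it.
#' @param bin_width q-value bin width for the summary (default 0.005).
#' @return list with `reference` (the reference `nbp_dge`), `per_gene`
#'   (gene_id, q_ref, detection_pct for reference-significant genes) and
#'   `bins` (q_bin, mean_detection_pct, n_genes).
#' @export
thinning_stability <- function(mat, n_iter = 1000L, fdr = 0.05, seed = 1L,
                               bin_width = 0.005) {
  ref <- nbp_test(mat, seed = seed, fdr = fdr)
  sig_ref <- ref$table$q_value <= fdr
  genes <- ref$table$gene_id[sig_ref]
  seeds <- derive_seeds(seed + 1L, n_iter)
  det <- stats::setNames(numeric(length(genes)), genes)
  for (it in seq_len(n_iter)) {
    res <- nbp_test(mat, seed = seeds[it], fdr = fdr)
    hit <- res$table$gene_id[res$table$q_value <= fdr]
    det[genes %in% hit] <- det[genes %in% hit] + 1
  }
  per_gene <- data.frame(gene_id = genes,
                         q_ref = ref$table$q_value[sig_ref],
                         detection_pct = 100 * det / n_iter,
                         stringsAsFactors = FALSE)
  bins <- if (nrow(per_gene)) {
    bin <- floor(per_gene$q_ref / bin_width) * bin_width
    agg <- stats::aggregate(per_gene$detection_pct, list(q_bin = bin),
                            function(v) c(mean = mean(v), n = length(v)))
    data.frame(q_bin = agg$q_bin,
               mean_detection_pct = agg$x[, "mean"],
               n_genes = as.integer(agg$x[, "n"]))
  } else {
    data.frame(q_bin = numeric(0), mean_detection_pct = numeric(0),
               n_genes = integer(0))
  }
  list(reference = ref, per_gene = per_gene, bins = bins)
}

#' Write an NBP test result as TSV
#'
#' @param x an `nbp_dge`.
#' @param path output file.
#' @export
write_dge <- function(x, path) {
  stopifnot(inherits(x, "nbp_dge"))
  write_tsv(x$table, path)
}
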