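test_that("thinning preserves expected counts and is seed-deterministic", {
  m <- matrix(c(10L, 20L), nrow = 1, dimnames = list("g1", c("a", "b")))
  cm <- count_matrix(m, c(a = "A", b = "B"),
                     library_sizes = c(a = 100, b = 200))
  draws <- vapply(1:10000, function(s) thin_counts(cm, s)$counts[1, "b"],
                  numeric(1))
  expect_equal(attr(thin_counts(cm, 1), "target_size"), 100)
  e <- 20 * 100 / 200            # c * N / L
  se <- sqrt(20 * 0.5 * 0.5) / sqrt(10000)
  expect_lt(abs(mean(draws) - e), 3 * se)
  # the minimum-size replicate is untouched
  expect_true(all(vapply(1:50, function(s)
    thin_counts(cm, s)$counts[1, "a"] == 10, logical(1))))
  expect_identical(thin_counts(cm, 7)$counts, thin_counts(cm, 7)$counts)
})

test_that("equal library sizes make thinning the identity", {
  set.seed(81)
  m <- matrix(rpois(40, 30), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), c("a1", "a2", "b1", "b2")))
  m <- cbind(m[, 1, drop = FALSE], m[, 1, drop = FALSE],
             m[, 1, drop = FALSE], m[, 1, drop = FALSE])
  colnames(m) <- c("a1", "a2", "b1", "b2")
  cm <- count_matrix(m, stats::setNames(c("A", "A", "B", "B"), colnames(m)))
  expect_identical(thin_counts(cm, 3)$counts, m)
})

test_that("fractional counts are refused by the statistics entry points", {
  m <- matrix(c(1.5, 2, 3, 4), nrow = 1,
              dimnames = list("g1", c("a1", "a2", "b1", "b2")))
  cm <- count_matrix(m, stats::setNames(c("A", "A", "B", "B"), colnames(m)))
  expect_error(thin_counts(cm, 1), "integral")
  expect_error(nbp_test(cm), "integral")
})

test_that("exact-test p-values match independent conditional enumeration", {
  set.seed(82)
  worst <- 0
  for (i in 1:300) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    repeat {
      ya <- rpois(na, sample(3:25, 1)); yb <- rpois(nb, sample(3:25, 1))
      if (sum(ya) + sum(yb) <= 200) break
    }
    phi <- runif(1, 0.01, 0.5); alpha <- runif(1, 1.5, 2.5)
    p1 <- nbp_exact_test(ya, yb, phi, alpha)
    p2 <- oracle_exact_p(ya, yb, phi, alpha)
    worst <- max(worst, abs(p1 - p2))
  }
  expect_lt(worst, 1e-12)
})

test_that("a perfectly balanced observation gives p = 1 and S = 0 gives p = 1", {
  expect_equal(nbp_exact_test(c(10, 10), c(10, 10), 0.1, 2), 1)
  expect_equal(nbp_exact_test(c(0, 0), c(0, 0), 0.1, 2), 1)
})

test_that("the phi -> 0 limit agrees with the exact binomial test", {
  set.seed(83)
  for (i in 1:50) {
    na <- sample(2:3, 1); nb <- sample(2:3, 1)
    ya <- rpois(na, 15); yb <- rpois(nb, 15)
    if (sum(ya) + sum(yb) == 0) next
    p_pkg <- nbp_exact_test(ya, yb, phi = 1e-12, alpha = 2)
    p_bin <- binom.test(sum(ya), sum(ya) + sum(yb),
                        na / (na + nb))$p.value
    expect_lt(abs(p_pkg - p_bin), 1e-9)
  }
})

test_that("swapping the groups leaves p unchanged and flips the direction", {
  set.seed(84)
  m <- make_count_matrix(n_genes = 150, n_per_group = 3, phi = 0.1, alpha = 2,
                         fold = 3, de_fraction = 0.2, seed = 84)
  r1 <- suppressWarnings(nbp_test(m, seed = 5, treatment_order = c("A", "B")))
  r2 <- suppressWarnings(nbp_test(m, seed = 5, treatment_order = c("B", "A")))
  expect_equal(r1$table$p_value, r2$table$p_value)
  moved <- r1$table$mean_norm_1 != r1$table$mean_norm_2
  expect_true(all(r1$table$direction[moved] != r2$table$direction[moved]))
  # the same thinning seed makes the normalized means identical, so the two
  # orderings' fold changes are exact reciprocals
  expect_equal(r1$table$fold_change * r2$table$fold_change,
               rep(1, nrow(r1$table)))
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 is 1", {
  q <- qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)
  expect_equal(as.numeric(q), rep(0.04, 4))
  p <- c(0.001, 0.01, 0.2, 0.8, 1)
  expect_equal(as.numeric(qvalues(p, pi0 = 1)), p.adjust(p, "BH"))
  expect_equal(as.numeric(qvalues(rep(1, 5), pi0 = 1)), rep(1, 5))
})

test_that("few p-values force pi0 = 1 with a warning", {
  expect_warning(q <- qvalues(runif(20)), "pi0")
  expect_equal(attr(q, "pi0"), 1)
})

test_that("the pi0 smoother is calibrated on uniform p-values", {
  set.seed(85)
  q <- qvalues(runif(5000))
  expect_gte(attr(q, "pi0"), 0.9)
  expect_lte(attr(q, "pi0"), 1)
})

test_that("q-values are monotone in p-rank", {
  set.seed(86)
  p <- c(runif(300), rbeta(100, 0.2, 5))
  q <- as.numeric(qvalues(p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= 0))
})

test_that("dispersion parameters are recovered on simulated data", {
  m <- make_count_matrix(n_genes = 1000, n_per_group = 3, phi = 0.1,
                         alpha = 2, seed = 87)
  fit <- fit_nbp(thin_counts(m, 1))
  expect_lt(abs(fit$alpha - 2), 0.15)
  expect_lt(abs(fit$phi - 0.1) / 0.1, 0.2)
})

test_that("Poisson data drives the fitted dispersion toward zero", {
  set.seed(88)
  y <- matrix(rpois(1000 * 6, rep(exp(runif(1000, log(10), log(200))), 6)),
              ncol = 6,
              dimnames = list(sprintf("g%04d", 1:1000),
                              c("a1", "a2", "a3", "b1", "b2", "b3")))
  cm <- count_matrix(y, stats::setNames(rep(c("A", "B"), each = 3),
                                        colnames(y)))
  fit <- fit_nbp(cm)
  # implied extra-Poisson variance at a typical mean is negligible
  mu <- 50
  expect_lt(fit$phi * mu^fit$alpha / mu, 0.05)
})

test_that("duplicating every replicate keeps the shape and weakens the adjustment", {
  m <- make_count_matrix(n_genes = 800, n_per_group = 3, phi = 0.1, alpha = 2,
                         seed = 89)
  f1 <- fit_nbp(m)
  y2 <- cbind(m$counts, m$counts)
  colnames(y2) <- c(colnames(m$counts), paste0(colnames(m$counts), "d"))
  t2 <- stats::setNames(rep(m$treatments, 2), colnames(y2))
  f2 <- fit_nbp(count_matrix(y2, t2))
  expect_lt(abs(f1$alpha - f2$alpha), 0.15)
  # duplicating the data doubles the likelihood but not the adjustment term,
  # so the duplicated fit sits closer to the unadjusted (downward-biased)
  # dispersion estimate: phi drops, though not drastically
  expect_lt(f2$phi, f1$phi)
  expect_lt(abs(log(f1$phi / f2$phi)), 0.7)
})

test_that("detection at FDR 5% increases strictly with the planted fold change", {
  det <- vapply(c(1, 1.5, 2, 4), function(f) {
    m <- make_count_matrix(n_genes = 2000, n_per_group = 8, phi = 0.1,
                           alpha = 2, fold = f, de_fraction = 0.1, seed = 7)
    r <- nbp_test(m, seed = 7)
    de <- attr(m, "de_genes")
    mean(de %in% r$table$gene_id[r$table$q_value <= 0.05])
  }, numeric(1))
  expect_true(all(diff(det) > 0))
})

test_that("repeat-thinning stability reports full detection for equal libraries", {
  m <- make_count_matrix(n_genes = 300, n_per_group = 3, phi = 0.05,
                         alpha = 2, fold = 6, de_fraction = 0.1, seed = 90)
  # force exactly equal library sizes so every thinning pass is the identity
  m <- count_matrix(m$counts, m$treatments,
                    library_sizes = stats::setNames(
                      rep(max(colSums(m$counts)), ncol(m$counts)),
                      colnames(m$counts)))
  st <- thinning_stability(m, n_iter = 20, seed = 90)
  # equal libraries: thinning is the identity, so every iteration repeats the
  # reference run exactly
  expect_true(all(st$per_gene$detection_pct == 100))
  expect_true(all(st$bins$q_bin <= 0.05))
})

test_that("detection frequency does not increase with reference q-value", {
  m <- make_count_matrix(n_genes = 400, n_per_group = 3, phi = 0.1,
                         alpha = 2, fold = 4, de_fraction = 0.15, seed = 91,
                         depth_factors = c(1, 1.15, 0.9, 1.05, 0.95, 1.2))
  st <- thinning_stability(m, n_iter = 60, seed = 91)
  expect_lte(suppressWarnings(
    cor(st$per_gene$q_ref, st$per_gene$detection_pct, method = "spearman")),
    0.1)
})
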