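# Moderated t, FDR, p-value combination, ranking and top-fragment selection.

random_levels <- function(n_sites = 200, n_per_group = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(pmin(pmax(stats::rnorm(n_sites * 2 * n_per_group, 0.5, 0.15),
                        0), 1),
              nrow = n_sites)
  rownames(m) <- paste("frag", seq_len(n_sites))
  list(levels = m, groups = rep(c("g1", "g2"), each = n_per_group))
}

test_that("with a zero prior the moderated t is the textbook pooled t", {
  d <- random_levels(seed = 2)
  res <- moderated_t_test(d$levels, d$groups, prior_df = 0)
  for (i in c(1, 50, 200)) {
    o <- oracle_pooled_t(d$levels[i, 1:4], d$levels[i, 5:8])
    expect_equal(res$t_statistic[i], o$t, tolerance = 1e-10)
    expect_equal(res$p_value[i], o$p, tolerance = 1e-10)
  }
  expect_true(max(abs(res$t_statistic - vapply(seq_len(200), function(i)
    oracle_pooled_t(d$levels[i, 1:4], d$levels[i, 5:8])$t, 0))) < 1e-10)
})

test_that("identical group means give t = 0 and p = 1", {
  m <- rbind(site1 = c(0.3, 0.5, 0.4, 0.4))
  res <- moderated_t_test(m, c("g1", "g1", "g2", "g2"), prior_df = 0)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("moderated t agrees with the limma implementation", {
  skip_if_not_installed("limma")
  d <- random_levels(n_sites = 500, seed = 3)
  res <- moderated_t_test(d$levels, d$groups)
  design <- stats::model.matrix(~ 0 + factor(d$groups))
  colnames(design) <- c("g1", "g2")
  fit <- limma::lmFit(d$levels, design)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(g1 - g2,
                                                        levels = design))
  fit <- limma::eBayes(fit)
  expect_equal(attr(res, "prior_df"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "prior_var"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_statistic, unname(fit$t[, 1]), tolerance = 1e-8)
  expect_equal(res$p_value, unname(fit$p.value[, 1]), tolerance = 1e-8)
})

test_that("sites without replication are skipped or refused", {
  m <- rbind(a = c(0.1, NA, 0.5, 0.6), b = c(0.1, 0.2, 0.5, 0.6))
  res <- moderated_t_test(m, c("g1", "g1", "g2", "g2"))
  expect_equal(res$site, "b")
  expect_error(moderated_t_test(m[1, , drop = FALSE],
                                c("g1", "g1", "g2", "g2")),
               "insufficient replication")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.42), 0.42)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  set.seed(4)
  for (i in 1:20) {
    p <- stats::runif(sample(1:300, 1))
    expect_equal(adjust_fdr(p), oracle_bh(p))
  }
  # stable under input reordering
  p <- stats::runif(100)
  o <- sample(100)
  expect_equal(adjust_fdr(p)[o], adjust_fdr(p[o]))
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("p-value combination matches chi-squared oracles", {
  # single site: identity for both methods
  expect_equal(combine_fragment_pvalues(0.123, method = "fisher"), 0.123)
  expect_equal(combine_fragment_pvalues(0.123, weights = 1,
                                        method = "weighted"), 0.123)
  # Fisher of two p = 0.05: X = -2(ln .05 + ln .05) ~ chi-squared df 4
  x <- -2 * (log(0.05) + log(0.05))
  expect_equal(combine_fragment_pvalues(c(0.05, 0.05), method = "fisher"),
               pchisq(x, 4, lower.tail = FALSE))
  expect_equal(combine_fragment_pvalues(c(0.05, 0.05), method = "fisher"),
               0.0175, tolerance = 2e-3)
  # equal weights: the weighted statistic is monotone in Fisher's
  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    p1 <- stats::runif(k); p2 <- stats::runif(k)
    f1 <- combine_fragment_pvalues(p1, method = "fisher")
    f2 <- combine_fragment_pvalues(p2, method = "fisher")
    w1 <- combine_fragment_pvalues(p1, method = "weighted")
    w2 <- combine_fragment_pvalues(p2, method = "weighted")
    if (k == length(p2)) expect_equal(sign(rank(c(f1, f2))),
                                      sign(rank(c(w1, w2))))
  }
  # monotonicity: decreasing any member p never increases the combination
  p <- c(0.2, 0.5, 0.8)
  w <- c(3, 1, 2)
  for (j in 1:3) {
    q <- p; q[j] <- p[j] / 2
    expect_lte(combine_fragment_pvalues(q, w), combine_fragment_pvalues(p, w))
    expect_lte(combine_fragment_pvalues(q, method = "fisher"),
               combine_fragment_pvalues(p, method = "fisher"))
  }
  expect_message(z <- combine_fragment_pvalues(c(0, 0.5)), "clamped")
  expect_gt(z, 0)
})

test_that("fragment ranking takes the worst of three competition ranks", {
  site_results <- data.frame(
    site = paste(c("fA", "fB", "fC"), 0),
    mean_group1 = c(0.9, 0.5, 0.52),
    mean_group2 = c(0.5, 0.1, 0.5),
    diff = c(0.4, 0.4, 0.02),
    log_fold_change = log2(c(0.91 / 0.51, 0.51 / 0.11, 0.53 / 0.51)),
    t_statistic = c(5, 4, 1), df_total = 6,
    p_value = c(0.001, 0.002, 0.4),
    adjusted_p = c(0.003, 0.003, 0.4))
  ranked <- rank_fragments(site_results)
  oracle <- oracle_rank_fragments(
    p = vapply(site_results$adjusted_p, combine_fragment_pvalues, 0),
    lfc = site_results$log_fold_change,
    diff = site_results$diff)
  expect_equal(ranked$combined_rank[match(c("fA", "fB", "fC"),
                                          ranked$fragment_id)], oracle)
  expect_equal(ranked$combined_rank,
               pmax(ranked$rank_p, ranked$rank_lfc, ranked$rank_diff))
  # a fragment best in all three gets combined rank 1
  expect_equal(ranked$combined_rank[1], 1L)
})

test_that("top-fragment gates are strict at their boundaries", {
  genome <- concatenate_genome(data.frame(
    sequence = c("ACGTACGTAA", "TTGCAGCTAG", "GGATCCGGTA"),
    n_reads = 3:1, strand_merged = FALSE))
  ranked <- data.frame(
    fragment_id = genome$fragments$fragment_id,
    combined_p = c(0.049, 0.049, 0.05),
    mean_diff = c(0.3, -0.2, 0.4),
    log_fold_change = c(1, -1, 2),
    mean_coverage = c(2.0, 2.5, 10),
    n_sites = 1L, rank_p = 1:3, rank_lfc = 1:3, rank_diff = 1:3,
    combined_rank = 1:3)
  top <- select_top_fragments(ranked, genome)
  # coverage exactly 2 excluded; adjusted p exactly 0.05 excluded
  expect_equal(nrow(top$hyper_group1), 0L)
  expect_equal(top$hyper_group2$fragment_id, ranked$fragment_id[2])
  expect_equal(top$hyper_group2$sequence, genome$fragments$sequence[2])
  # fewer than n eligible: all returned; none eligible: warning
  top2 <- select_top_fragments(ranked, genome, n = 500)
  expect_equal(nrow(top2$hyper_group1) + nrow(top2$hyper_group2), 1L)
  expect_warning(select_top_fragments(ranked[3, ], genome), "no fragments")
})

test_that("an all-null design keeps the type-I error near nominal", {
  nul <- simulate_differential_levels(n_fragments = 600, n_planted = 0,
                                      sites_per_fragment = c(1, 1), seed = 6)
  res <- moderated_t_test(nul$levels, nul$groups)
  expect_lt(abs(mean(res$p_value < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / nrow(res)))
})
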