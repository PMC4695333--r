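# Differential methylation: moderated two-group t-statistics with an
# empirical-Bayes variance prior, FDR adjustment, weighted p-value
# combination per fragment and worst-of-three priority ranking.

# Newton inversion of the trigamma function (for the variance-prior df)
trigamma_inverse <- function(x) {
  out <- x
  hi <- x > 1e7
  lo <- x < 1e-6
  out[hi] <- 1 / sqrt(x[hi])
  out[lo] <- 1 / x[lo]
  mid <- which(!hi & !lo)
  y <- 0.5 + 1 / x[mid]
  for (i in seq_len(50L)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-8) break
  }
  out[mid] <- y
  out
}

# Moment matching of the scaled-F distribution of residual variances on the
# log scale: returns the prior df d0 (possibly Inf) and prior variance s02.
estimate_variance_prior <- function(s2, df) {
  ok <- df > 0 & is.finite(s2)
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2L) return(list(prior_df = 0, prior_var = mean(s2)))
  med <- stats::median(s2)
  if (med == 0) med <- 1 # degenerate: all variances zero
  s2 <- pmax(s2, 1e-5 * med) # keep log finite at zero sample variances
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1L) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    list(prior_df = d0, prior_var = s02)
  } else {
    # no excess dispersion beyond sampling: variances share one value
    list(prior_df = Inf, prior_var = mean(s2))
  }
}

#' Moderated two-group t-test per site
#'
#' Fits the ordinary two-group linear model to each site's methylation
#' levels, shrinks the residual variances towards a common prior by
#' empirical Bayes — the posterior variance is
#' `(d0 s0^2 + d s^2) / (d0 + d)` with `(d0, s0^2)` estimated across sites by
#' moment matching of the scaled-F distribution of the residual variances —
#' and tests the group difference with a t-statistic on `d0 + d` degrees of
#' freedom. Sites with fewer than two observations in either group are
#' skipped.
#'
#' @param levels sites x samples matrix of methylation levels (NAs allowed).
#' @param groups factor/character of length `ncol(levels)` with exactly two
#'   levels; the difference is group 1 minus group 2 (first factor level
#'   first).
#' @param prior_df override for the prior degrees of freedom d0; `NULL`
#'   (default) estimates it from the data, `0` gives the ordinary pooled t.
#' @param epsilon additive constant for the log fold change
#'   `log2((mean1 + eps) / (mean2 + eps))` (default 0.01).
#' @return data.frame with one row per tested site: `site`, `mean_group1`,
#'   `mean_group2`, `diff`, `log_fold_change`, `t_statistic`, `df_total`,
#'   `p_value`, `adjusted_p`, plus attributes `prior_df` and `prior_var`.
#' @export
moderated_t_test <- function(levels, groups, prior_df = NULL, epsilon = 0.01) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stopf("exactly two groups required, got %d",
                                   nlevels(groups))
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  x1 <- levels[, g1, drop = FALSE]
  x2 <- levels[, g2, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  testable <- n1 >= 2L & n2 >= 2L
  if (!any(testable)) stopf("insufficient replication: no site has >= 2 observations per group")
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  ss <- rowSums((x1 - m1)^2, na.rm = TRUE) + rowSums((x2 - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  s2 <- ifelse(df > 0, ss / df, NA_real_)
  idx <- which(testable)
  prior <- if (is.null(prior_df)) {
    estimate_variance_prior(s2[idx], df[idx])
  } else if (prior_df == 0) {
    list(prior_df = 0, prior_var = 1) # unused at weight 0
  } else {
    list(prior_df = prior_df,
         prior_var = estimate_variance_prior(s2[idx], df[idx])$prior_var)
  }
  d0 <- prior$prior_df
  s02 <- prior$prior_var
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + df * s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  # total df capped at the summed residual df across tested sites
  df_total <- pmin(d0 + df, sum(df[idx]))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  site <- rownames(levels) %||% as.character(seq_len(nrow(levels)))
  out <- data.frame(
    site = site[idx],
    mean_group1 = m1[idx],
    mean_group2 = m2[idx],
    diff = (m1 - m2)[idx],
    log_fold_change = log2((m1[idx] + epsilon) / (m2[idx] + epsilon)),
    t_statistic = tstat[idx],
    df_total = df_total[idx],
    p_value = p[idx])
  out$adjusted_p <- adjust_fdr(out$p_value)
  rownames(out) <- NULL
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  attr(out, "groups") <- levels(groups)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: `adjusted_i = min over j >= rank(i) of m p_(j) / j`,
#' capped at 1; stable with respect to input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
adjust_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Combine site p-values into a fragment p-value
#'
#' `method = "fisher"`: `X = -2 sum(log p)` against chi-squared with `2k`
#' degrees of freedom. `method = "weighted"` (default): the weighted
#' statistic `K = sum w_i (-2 log p_i)` with weights normalized to sum 1
#' (site coverage in the pipeline), with null approximated by a scaled
#' chi-squared matched to mean 2 and variance `4 sum(w_i^2)`. With a single
#' site both methods return the site's p.
#'
#' @param p site p-values in `(0, 1]` (zeros are clamped to the smallest
#'   positive double with a message).
#' @param weights positive site weights (default equal).
#' @param method `"weighted"` or `"fisher"`.
#' @return the combined p-value.
#' @export
combine_fragment_pvalues <- function(p, weights = NULL,
                                     method = c("weighted", "fisher")) {
  method <- match.arg(method)
  if (any(p <= 0)) {
    message(sprintf("%d zero p-value(s) clamped to the smallest positive double",
                    sum(p <= 0)))
    p[p <= 0] <- .Machine$double.xmin
  }
  stopifnot(all(p <= 1))
  k <- length(p)
  if (method == "fisher") {
    x <- -2 * sum(log(p))
    return(stats::pchisq(x, df = 2 * k, lower.tail = FALSE))
  }
  if (is.null(weights)) weights <- rep(1, k)
  stopifnot(length(weights) == k, all(weights > 0))
  w <- weights / sum(weights)
  K <- sum(w * (-2 * log(p)))
  sw2 <- sum(w^2)
  # scaled chi-squared: c * chisq(f) with c f = 2 and 2 c^2 f = 4 sum(w^2)
  cc <- sw2
  f <- 2 / sw2
  stats::pchisq(K / cc, df = f, lower.tail = FALSE)
}

#' Rank fragments by combined significance and effect size
#'
#' Combines the member sites' adjusted p-values per fragment (coverage
#' weighted), computes the fragment mean difference and log fold change from
#' coverage-weighted group means, ranks fragments separately by p-value,
#' absolute log fold change and absolute mean difference (competition
#' ranking, rank 1 best, ties share the minimum rank), and assigns each
#' fragment the worst of its three ranks. The output is ordered by combined
#' rank, ties broken by combined p, then fragment id.
#'
#' @param site_results data.frame from [moderated_t_test()]; `site` must be
#'   `"fragment_id position"` keys as produced by
#'   [build_methylation_matrix()].
#' @param site_coverage optional numeric vector (same order as
#'   `site_results`) of mean per-site coverage used as combination weights;
#'   default equal weights.
#' @param method combination method, see [combine_fragment_pvalues()].
#' @param epsilon additive constant for the fragment log fold change.
#' @return data.frame: `fragment_id`, `combined_p`, `mean_diff`,
#'   `log_fold_change`, `mean_coverage`, `n_sites`, `rank_p`, `rank_lfc`,
#'   `rank_diff`, `combined_rank`.
#' @export
rank_fragments <- function(site_results, site_coverage = NULL,
                           method = c("weighted", "fisher"), epsilon = 0.01) {
  method <- match.arg(method)
  frag <- sub("\\s+\\S+$", "", site_results$site)
  w <- site_coverage %||% rep(1, nrow(site_results))
  idx <- split(seq_len(nrow(site_results)), frag)
  rows <- lapply(names(idx), function(f) {
    i <- idx[[f]]
    wi <- w[i]
    cp <- combine_fragment_pvalues(site_results$adjusted_p[i], weights = wi,
                                   method = method)
    gm1 <- sum(wi * site_results$mean_group1[i]) / sum(wi)
    gm2 <- sum(wi * site_results$mean_group2[i]) / sum(wi)
    data.frame(fragment_id = f, combined_p = cp,
               mean_diff = gm1 - gm2,
               log_fold_change = log2((gm1 + epsilon) / (gm2 + epsilon)),
               mean_coverage = mean(wi), n_sites = length(i))
  })
  out <- do.call(rbind, rows)
  out$rank_p <- rank(out$combined_p, ties.method = "min")
  out$rank_lfc <- rank(-abs(out$log_fold_change), ties.method = "min")
  out$rank_diff <- rank(-abs(out$mean_diff), ties.method = "min")
  out$combined_rank <- pmax(out$rank_p, out$rank_lfc, out$rank_diff)
  out <- out[order(out$combined_rank, out$combined_p, out$fragment_id), ]
  rownames(out) <- NULL
  out
}

#' Select top differentially methylated fragments for interpretation
#'
#' Applies the coverage gate (mean coverage strictly greater than
#' `min_mean_coverage`) and the significance gate (combined adjusted p
#' strictly below `max_adjusted_p`), takes the top `n` fragments by combined
#' rank, and splits them by the direction of the methylation difference
#' (hypermethylated in group 1 vs in group 2).
#'
#' @param ranked data.frame from [rank_fragments()].
#' @param genome the `deduced_genome` (source of fragment sequences).
#' @param n maximum fragments retained (default 500).
#' @param min_mean_coverage exclusive lower coverage bound (default 2).
#' @param max_adjusted_p exclusive upper p bound (default 0.05).
#' @return list with data.frames `hyper_group1` and `hyper_group2` (columns
#'   of `ranked` plus `sequence`). Zero passing fragments yields empty frames
#'   with a warning.
#' @export
select_top_fragments <- function(ranked, genome, n = 500L,
                                 min_mean_coverage = 2,
                                 max_adjusted_p = 0.05) {
  eligible <- ranked[ranked$mean_coverage > min_mean_coverage &
                       ranked$combined_p < max_adjusted_p, , drop = FALSE]
  if (nrow(eligible) == 0L) {
    warnf("no fragments pass the coverage/significance gates")
  }
  top <- utils::head(eligible, n)
  top$sequence <- genome$fragments$sequence[
    match(top$fragment_id, genome$fragments$fragment_id)]
  list(hyper_group1 = top[top$mean_diff > 0, , drop = FALSE],
       hyper_group2 = top[top$mean_diff < 0, , drop = FALSE])
}

#' Write the top differential fragments as FASTA, one file per direction
#'
#' @param top output of [select_top_fragments()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_top_fragments <- function(top, dir, prefix = "top_fragments") {
  paths <- file.path(dir, paste0(prefix, "_", names(top), ".fa"))
  for (i in seq_along(top)) {
    seqs <- stats::setNames(top[[i]]$sequence, top[[i]]$fragment_id)
    write_fasta(seqs, paths[i])
  }
  invisible(paths)
}
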