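# PWM scoring, rank-sum enrichment, Markov backgrounds, shuffle control.

test_that("average odds scoring matches hand-computed values", {
  m <- motif_matrix("m1", matrix(c(0.5, 0.5 / 3, 0.5 / 3, 0.5 / 3), 4, 1))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  # "AA": forward offsets score 2 each, reverse strand sees TT at 2/3 each
  expect_equal(average_odds_score(m, "AA", bg),
               mean(c(2, 2, (0.5 / 3) / 0.25, (0.5 / 3) / 0.25)))
  # motif equal to background scores 1 on any sequence
  flat <- motif_matrix("flat", matrix(0.25, 4, 3))
  expect_equal(average_odds_score(flat, "ACGTTGCA", bg), 1)
  # N positions contribute an odds factor of 1
  expect_equal(average_odds_score(m, "ANA", bg),
               mean(c(2, 1, 2, (0.5 / 3) / 0.25, 1, (0.5 / 3) / 0.25)))
  # doubling a homopolymer leaves the mean over identical offsets unchanged
  expect_equal(average_odds_score(m, strrep("A", 10), bg),
               average_odds_score(m, strrep("A", 20), bg))
  # too-short sequences are excluded
  wide <- motif_matrix("w", matrix(0.25, 4, 5))
  expect_true(is.na(average_odds_score(wide, "ACG", bg)))
})

test_that("rank-sum enrichment is exact for small samples and directional", {
  expect_equal(ranksum_enrichment(c(3, 4), c(1, 2)), 1 / 6)
  # identical multisets: p near 0.5
  x <- c(1, 2, 3, 4, 5)
  expect_lt(abs(ranksum_enrichment(x, x) - 0.5), 0.12)
  # fg stochastically smaller: far from significance
  expect_gte(ranksum_enrichment(c(1, 2), c(3, 4)), 0.9)
  # exact enumeration vs normal approximation within 0.02 at n = 20
  set.seed(8)
  for (i in 1:15) {
    fg <- stats::rnorm(20); bg <- stats::rnorm(20)
    exact <- suppressWarnings(stats::wilcox.test(fg, bg, "greater",
                                                 exact = TRUE)$p.value)
    approx <- suppressWarnings(stats::wilcox.test(fg, bg, "greater",
                                                  exact = FALSE)$p.value)
    expect_lt(abs(exact - approx), 0.02)
    expect_equal(ranksum_enrichment(fg, bg), exact)
  }
})

test_that("Markov models recover their generating frequencies", {
  m0 <- fit_markov_model("AACC", order = 0L)
  expect_equal(unname(m0$initial), c(0.5, 0.5, 0, 0))
  m1 <- fit_markov_model("ACACAC", order = 1L)
  expect_equal(m1$transitions["A", "C"], 1)
  expect_equal(m1$transitions["C", "A"], 1)
  expect_equal(unname(m1$transitions["G", ]), rep(0.25, 4)) # unseen context
  # consistency: a model refit on its own output converges to the generator
  gen <- structure(list(order = 1L,
                        initial = c(A = 0.3, C = 0.2, G = 0.3, T = 0.2),
                        transitions = matrix(c(0.5, 0.2, 0.2, 0.1,
                                               0.1, 0.3, 0.5, 0.1,
                                               0.25, 0.25, 0.25, 0.25,
                                               0.1, 0.4, 0.1, 0.4),
                                             4, 4, byrow = TRUE,
                                             dimnames = list(c("A", "C", "G", "T"),
                                                             c("A", "C", "G", "T")))),
                   class = "markov_model")
  seqs <- generate_background(gen, n_sequences = 100L, lengths = 1000L,
                              seed = 9)
  refit <- fit_markov_model(seqs, order = 1L)
  kl <- 0
  for (b in rownames(gen$transitions)) {
    p <- gen$transitions[b, ]; q <- pmax(refit$transitions[b, ], 1e-12)
    kl <- kl + sum(p[p > 0] * log(p[p > 0] / q[p > 0]))
  }
  expect_lt(kl, 0.01)
})

test_that("generated backgrounds are seeded and composition-faithful", {
  a_only <- structure(list(order = 0L, initial = c(A = 1, C = 0, G = 0, T = 0)),
                      class = "markov_model")
  out <- generate_background(a_only, 5, 20, seed = 1)
  expect_true(all(out == strrep("A", 20)))
  m <- structure(list(order = 0L,
                      initial = c(A = 0.4, C = 0.1, G = 0.2, T = 0.3)),
                 class = "markov_model")
  x <- generate_background(m, 500, 50, seed = 2)
  expect_identical(x, generate_background(m, 500, 50, seed = 2))
  freq <- table(factor(strsplit(paste(x, collapse = ""), "")[[1]],
                       c("A", "C", "G", "T"))) / (500 * 50)
  for (b in names(m$initial)) {
    se <- sqrt(m$initial[[b]] * (1 - m$initial[[b]]) / (500 * 50))
    expect_lt(abs(freq[[b]] - m$initial[[b]]), 4 * se)
  }
  # lengths are matched per sequence
  y <- generate_background(m, 3, c(10, 20, 30), seed = 3)
  expect_equal(nchar(y), c(10, 20, 30))
})

test_that("a planted motif is reported differential by the shuffle control", {
  pm <- methdeduce:::planted_motif_library()
  unif <- fit_markov_model("ACGT", 0L)
  set.seed(12)
  fg <- generate_background(unif, 50, 50)
  bg <- generate_background(unif, 50, 50)
  fg[1:25] <- vapply(fg[1:25], function(s)
    paste0(substr(s, 1, 20), "TGACGTCATT", substr(s, 31, 50)), "")
  res <- differential_motif_analysis(fg, bg, pm,
                                     shuffle_params(n_iterations = 3,
                                                    seed = 13))
  expect_equal(res$verdict[res$motif_id == "planted_CREB_like"],
               "differential")
  expect_true(all(res$verdict[res$motif_id != "planted_CREB_like"] !=
                    "differential"))
  expect_error(differential_motif_analysis(fg, bg, list()), "empty")
})

test_that("the artifact rule is boundary-exact and monotone in its threshold", {
  params60 <- shuffle_params()
  v_at <- methdeduce:::motif_verdicts(
    primary_sig = c(TRUE, TRUE, TRUE, FALSE),
    artifact_fraction = c(0.60, 0.61, 0.59, 0.99),
    shared_fg = rep(0, 4), shared_bg = rep(0, 4), params60)
  # significant in exactly 60% of iterations: kept ("more than 60%" removes)
  expect_equal(v_at, c("differential", "composition-bias-artifact",
                       "differential", "ns"))
  # shared rule is inclusive at 95%
  v_sh <- methdeduce:::motif_verdicts(
    primary_sig = rep(FALSE, 3),
    artifact_fraction = rep(0, 3),
    shared_fg = c(0.95, 0.94, 1), shared_bg = c(0.95, 1, 0.94), params60)
  expect_equal(v_sh, c("shared", "ns", "ns"))
  # raising the artifact threshold never removes more motifs
  fractions <- seq(0, 1, by = 0.05)
  removed <- function(thr) {
    p <- shuffle_params(artifact_threshold = thr)
    sum(methdeduce:::motif_verdicts(rep(TRUE, length(fractions)), fractions,
                                    rep(0, length(fractions)),
                                    rep(0, length(fractions)), p) ==
          "composition-bias-artifact")
  }
  expect_true(all(diff(vapply(c(0.2, 0.4, 0.6, 0.8), removed, 0)) <= 0))
})
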