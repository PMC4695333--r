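# Reference-free motif enrichment: average-odds PWM scoring on both strands,
# rank-sum enrichment testing, and Markov-shuffled background control to
# separate genuine differential enrichment from base-composition bias.

#' Shuffle-control parameters
#'
#' Houses the iteration and threshold constants of the composition-bias
#' control: 50 shuffle iterations per Markov order, removal of motifs
#' significant in more than 60% of all iterations as composition artifacts,
#' and reporting of motifs enriched against their own shuffles in at least
#' 95% of iterations as shared.
#'
#' @param n_iterations shuffle iterations per Markov order (default 50; the
#'   0th- and 1st-order iterations are pooled when applying the fractions).
#' @param artifact_threshold fraction (exclusive) above which a motif is a
#'   composition artifact (default 0.60).
#' @param shared_threshold fraction (inclusive) at which a motif is reported
#'   as enriched in both directions (default 0.95).
#' @param n_sequences maximum shuffled sequences per set (default 500);
#'   each shuffled set matches the original set's size and per-sequence
#'   lengths up to this cap.
#' @param seed integer PRNG seed.
#' @return a list of class `shuffle_params`.
#' @export
shuffle_params <- function(n_iterations = 50L, artifact_threshold = 0.60,
                           shared_threshold = 0.95, n_sequences = 500L,
                           seed = 1L) {
  stopifnot(n_iterations >= 1, artifact_threshold > 0, artifact_threshold <= 1,
            shared_threshold > 0, shared_threshold <= 1, n_sequences >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 artifact_threshold = artifact_threshold,
                 shared_threshold = shared_threshold,
                 n_sequences = as.integer(n_sequences),
                 seed = as.integer(seed)),
            class = "shuffle_params")
}

#' Average odds score of a motif on a sequence
#'
#' At each offset the odds are the product over motif positions of
#' (motif frequency of the observed base / background frequency of that
#' base); the score is the mean of the odds over all offsets on both strands
#' (the reverse strand is scanned with the reverse-complemented matrix).
#' Positions holding N contribute an odds factor of 1. Sequences shorter
#' than the motif are excluded (NA).
#'
#' @param motif a [motif_matrix()].
#' @param sequence DNA string.
#' @param background strictly positive base probabilities, named A, C, G, T.
#' @return the average odds score, or NA if the sequence is too short.
#' @export
average_odds_score <- function(motif, sequence,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25)) {
  stopifnot(all(background > 0))
  w <- motif$length
  n <- nchar(sequence)
  if (n < w) return(NA_real_)
  ratio <- motif$frequencies / background[c("A", "C", "G", "T")]
  ratio <- rbind(ratio, N = 1) # 5th row: N contributes factor 1
  odds_one_strand <- function(s) {
    v <- seq_to_int(s)
    n_off <- length(v) - w + 1L
    odds <- rep(1, n_off)
    for (j in seq_len(w)) {
      odds <- odds * ratio[cbind(v[j:(j + n_off - 1L)], j)]
    }
    odds
  }
  mean(c(odds_one_strand(sequence), odds_one_strand(revcomp(sequence))))
}

# score a set of sequences; NA for sequences shorter than the motif
score_sequences <- function(motif, sequences, background) {
  vapply(sequences, function(s) average_odds_score(motif, s, background),
         numeric(1), USE.NAMES = FALSE)
}

# precompute integer codes of both strands of a sequence set
encode_set <- function(sequences) {
  lapply(sequences, function(s) {
    v <- seq_to_int(s)
    rc <- 5L - rev(v)
    rc[rc == 0L] <- 5L
    list(v, rc)
  })
}

# average-odds scores of one motif over an encoded set
score_encoded <- function(motif, encoded, background) {
  w <- motif$length
  ratio <- motif$frequencies / background[c("A", "C", "G", "T")]
  ratio <- rbind(ratio, N = 1)
  one <- function(v) {
    n_off <- length(v) - w + 1L
    odds <- rep(1, n_off)
    for (j in seq_len(w)) {
      odds <- odds * ratio[cbind(v[j:(j + n_off - 1L)], j)]
    }
    odds
  }
  vapply(encoded, function(e) {
    if (length(e[[1]]) < w) return(NA_real_)
    mean(c(one(e[[1]]), one(e[[2]])))
  }, numeric(1))
}

#' One-sided rank-sum enrichment p-value
#'
#' Wilcoxon rank-sum (Mann-Whitney) test of the foreground scores being
#' stochastically greater than the background scores: exact enumeration when
#' both sets have at most 20 values and there are no ties, normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param fg_scores,bg_scores numeric vectors (non-empty; NAs dropped).
#' @return the one-sided p-value.
#' @export
ranksum_enrichment <- function(fg_scores, bg_scores) {
  fg <- fg_scores[!is.na(fg_scores)]
  bg <- bg_scores[!is.na(bg_scores)]
  stopifnot(length(fg) > 0, length(bg) > 0)
  exact <- length(fg) <= 20L && length(bg) <= 20L &&
    !anyDuplicated(c(fg, bg))
  suppressWarnings(
    stats::wilcox.test(fg, bg, alternative = "greater", exact = exact,
                       correct = TRUE)$p.value)
}

#' Fit a 0th- or 1st-order Markov model to sequences
#'
#' Order 0 is the maximum-likelihood base composition; order 1 adds
#' transition frequencies estimated from within-sequence dinucleotide counts,
#' with unseen contexts smoothed to the uniform distribution. N bases are
#' ignored.
#'
#' @param sequences character vector of DNA sequences.
#' @param order 0 or 1.
#' @return list of class `markov_model`: `order`, `initial` (base
#'   probabilities), `transitions` (4 x 4 row-stochastic matrix, order 1
#'   only).
#' @export
fit_markov_model <- function(sequences, order = 0L) {
  stopifnot(order %in% c(0L, 1L))
  bases <- c("A", "C", "G", "T")
  counts <- stats::setNames(numeric(4), bases)
  trans <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (s in sequences) {
    v <- seq_to_int(s)
    v <- v[v <= 4L]
    counts <- counts + tabulate(v, 4L)
    if (order == 1L && length(v) >= 2L) {
      from <- v[-length(v)]
      to <- v[-1L]
      for (b in 1:4) {
        if (any(from == b)) trans[b, ] <- trans[b, ] + tabulate(to[from == b], 4L)
      }
    }
  }
  if (sum(counts) == 0) stopf("no informative bases to fit a Markov model")
  model <- list(order = order, initial = counts / sum(counts))
  if (order == 1L) {
    rs <- rowSums(trans)
    for (b in 1:4) {
      trans[b, ] <- if (rs[b] > 0) trans[b, ] / rs[b] else rep(0.25, 4)
    }
    model$transitions <- trans
  }
  structure(model, class = "markov_model")
}

#' Sample random sequences from a Markov model
#'
#' @param model a `markov_model`.
#' @param n_sequences number of sequences.
#' @param lengths sequence length(s); recycled to `n_sequences` (default 50,
#'   pass the original sequences' lengths to match them).
#' @param seed integer PRNG seed; `NULL` leaves the PRNG state alone.
#' @return character vector of sequences.
#' @export
generate_background <- function(model, n_sequences = 500L, lengths = 50L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lengths <- rep_len(as.integer(lengths), n_sequences)
  maxlen <- max(lengths)
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0L, nrow = n_sequences, ncol = maxlen)
  mat[, 1L] <- sample.int(4L, n_sequences, replace = TRUE, prob = model$initial)
  if (model$order == 0L) {
    if (maxlen > 1L) {
      mat[, -1L] <- sample.int(4L, n_sequences * (maxlen - 1L), replace = TRUE,
                               prob = model$initial)
    }
  } else {
    for (j in 2L:maxlen) {
      for (b in 1:4) {
        at <- which(mat[, j - 1L] == b)
        if (length(at) > 0L) {
          mat[at, j] <- sample.int(4L, length(at), replace = TRUE,
                                   prob = model$transitions[b, ])
        }
      }
    }
  }
  vapply(seq_len(n_sequences), function(i) {
    paste(bases[mat[i, seq_len(lengths[i])]], collapse = "")
  }, character(1))
}

# decision rule for the shuffle control: a primary-significant motif is a
# composition artifact when significant in MORE than artifact_threshold of
# the shuffled iterations (exactly at the threshold it survives); a motif is
# shared when enriched against its own shuffles in AT LEAST shared_threshold
# of iterations for both sets.
motif_verdicts <- function(primary_sig, artifact_fraction, shared_fg,
                           shared_bg, params) {
  verdict <- rep("ns", length(primary_sig))
  is_artifact <- artifact_fraction > params$artifact_threshold
  verdict[primary_sig] <- "differential"
  verdict[primary_sig & is_artifact] <- "composition-bias-artifact"
  is_shared <- shared_fg >= params$shared_threshold &
    shared_bg >= params$shared_threshold
  verdict[!primary_sig & is_shared] <- "shared"
  verdict
}

# one enrichment pass: scores, rank-sum p per motif, BH across motifs
enrichment_pass <- function(fg, bg, motifs, background) {
  enc_fg <- if (is.list(fg) && !is.character(fg)) fg else encode_set(fg)
  enc_bg <- if (is.list(bg) && !is.character(bg)) bg else encode_set(bg)
  p <- vapply(motifs, function(m) {
    ranksum_enrichment(score_encoded(m, enc_fg, background),
                       score_encoded(m, enc_bg, background))
  }, numeric(1))
  data.frame(motif_id = vapply(motifs, `[[`, "", "motif_id"),
             p_value = p, adjusted_p = adjust_fdr(p))
}

#' Differential motif enrichment with Markov-shuffle control
#'
#' Three stages: (a) the primary run scores every motif on the foreground
#' against the background set (average odds, one-sided rank-sum, BH across
#' motifs) and keeps motifs with adjusted p below `alpha`; (b) for every
#' iteration and Markov order in {0, 1}, models are fitted to each set,
#' matched random sets are generated, and the test is re-run
#' shuffled-vs-shuffled — motifs significant in more than
#' `artifact_threshold` of all pooled iterations are removed from (a) as
#' composition-bias artifacts; (c) each original set is tested against its
#' own shuffles — motifs significant in at least `shared_threshold` of
#' iterations for both sets are reported as enriched in both directions
#' (verdict `shared`), with the least significant p across iterations.
#'
#' Odds-scoring background probabilities are the order-0 composition of the
#' union of both input sets.
#'
#' @param fg,bg character vectors of foreground/background sequences.
#' @param motifs list of [motif_matrix()] objects.
#' @param params a [shuffle_params()] object.
#' @param alpha significance cutoff on BH-adjusted p-values (default 0.05).
#' @return data.frame with one row per motif: `motif_id`, `p_value`,
#'   `adjusted_p` (primary run), `artifact_fraction`, `shared_fraction_fg`,
#'   `shared_fraction_bg`, `shared_p`, `verdict` (`differential`,
#'   `composition-bias-artifact`, `shared`, or `ns`).
#' @export
differential_motif_analysis <- function(fg, bg, motifs,
                                        params = shuffle_params(),
                                        alpha = 0.05) {
  if (length(motifs) == 0L) stopf("motif library is empty")
  stopifnot(length(fg) > 0, length(bg) > 0)
  set.seed(params$seed)
  background <- fit_markov_model(c(fg, bg), order = 0L)$initial
  background <- pmax(background, 1e-6)

  primary <- enrichment_pass(fg, bg, motifs, background)
  n_motifs <- nrow(primary)

  cap <- params$n_sequences
  fg_use <- utils::head(fg, cap)
  bg_use <- utils::head(bg, cap)
  enc_fg_use <- encode_set(fg_use)
  enc_bg_use <- encode_set(bg_use)
  n_it <- params$n_iterations
  sig_shuffle <- matrix(FALSE, n_motifs, 2L * n_it)
  sig_fg <- matrix(FALSE, n_motifs, 2L * n_it)
  sig_bg <- matrix(FALSE, n_motifs, 2L * n_it)
  p_fg <- matrix(NA_real_, n_motifs, 2L * n_it)
  p_bg <- matrix(NA_real_, n_motifs, 2L * n_it)
  col <- 0L
  for (it in seq_len(n_it)) {
    for (ord in c(0L, 1L)) {
      col <- col + 1L
      m_fg <- fit_markov_model(fg_use, order = ord)
      m_bg <- fit_markov_model(bg_use, order = ord)
      sh_fg <- generate_background(m_fg, length(fg_use), nchar(fg_use))
      sh_bg <- generate_background(m_bg, length(bg_use), nchar(bg_use))
      enc_sh_fg <- encode_set(sh_fg)
      enc_sh_bg <- encode_set(sh_bg)
      res_sh <- enrichment_pass(enc_sh_fg, enc_sh_bg, motifs, background)
      sig_shuffle[, col] <- res_sh$adjusted_p < alpha
      res_f <- enrichment_pass(enc_fg_use, enc_sh_fg, motifs, background)
      sig_fg[, col] <- res_f$adjusted_p < alpha
      p_fg[, col] <- res_f$p_value
      res_b <- enrichment_pass(enc_bg_use, enc_sh_bg, motifs, background)
      sig_bg[, col] <- res_b$adjusted_p < alpha
      p_bg[, col] <- res_b$p_value
    }
  }
  artifact_fraction <- rowMeans(sig_shuffle)
  shared_fg <- rowMeans(sig_fg)
  shared_bg <- rowMeans(sig_bg)

  verdict <- motif_verdicts(primary$adjusted_p < alpha, artifact_fraction,
                            shared_fg, shared_bg, params)
  is_shared <- shared_fg >= params$shared_threshold &
    shared_bg >= params$shared_threshold

  # for each motif enriched against its shuffles, report the least
  # significant (largest) p across iterations
  shared_p <- pmax(apply(p_fg, 1L, max), apply(p_bg, 1L, max))
  shared_p[!is_shared] <- NA_real_

  out <- data.frame(
    motif_id = primary$motif_id,
    p_value = primary$p_value,
    adjusted_p = primary$adjusted_p,
    artifact_fraction = artifact_fraction,
    shared_fraction_fg = shared_fg,
    shared_fraction_bg = shared_bg,
    shared_p = shared_p,
    verdict = verdict)
  rownames(out) <- NULL
  out
}
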