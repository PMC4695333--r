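# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive and separate from the implementation paths they check.

# step-up FDR adjustment, written directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (j in m:1) {
    running <- min(running, m * p[o[j]] / j)
    adj[o[j]] <- min(running, 1)
  }
  adj
}

# textbook two-sample pooled-variance t-test
oracle_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  t <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

# restriction digest by naive substring scanning (no regex)
oracle_digest_lengths <- function(sequence, site = "CCGG", cut_offset = 1) {
  n <- nchar(sequence)
  w <- nchar(site)
  cuts <- integer(0)
  for (i in seq_len(max(n - w + 1, 0))) {
    if (substr(sequence, i, i + w - 1) == site) {
      cuts <- c(cuts, i - 1 + cut_offset)
    }
  }
  cuts <- cuts[cuts > 0 & cuts < n]
  diff(c(0, cuts, n))
}

# expected deduced-fragment consensus computed directly from the reads of one
# library fragment: per-strand base-majority with the 5% C-retention rule,
# then the strand-merge restoration. Returns the forward-strand consensus.
oracle_fragment_consensus <- function(fwd_reads, rev_reads,
                                      c_call_threshold = 0.05) {
  consensus_one <- function(reads) {
    L <- max(nchar(reads))
    mat <- matrix(NA_character_, length(reads), L)
    for (i in seq_along(reads)) {
      v <- strsplit(reads[i], "")[[1]]
      mat[i, seq_along(v)] <- v
    }
    vapply(seq_len(L), function(j) {
      col <- mat[, j]
      col <- col[!is.na(col)]
      tab <- sort(table(col), decreasing = TRUE)
      base <- names(tab)[1]
      if (mean(col == "C") >= c_call_threshold) base <- "C"
      base
    }, character(1))
  }
  fwd <- consensus_one(fwd_reads)
  rev_cons <- consensus_one(rev_reads)
  # literal reverse complement of the reverse-strand consensus
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rcp <- rev(unname(comp[rev_cons]))
  stopifnot(length(fwd) == length(rcp))
  fwd[fwd == "T" & rcp == "C"] <- "C"
  paste(fwd, collapse = "")
}

# exhaustive worst-of-three ranking of a small fragment table
oracle_rank_fragments <- function(p, lfc, diff) {
  comp_rank <- function(x) {
    vapply(x, function(v) sum(x < v) + 1L, integer(1))
  }
  rp <- comp_rank(p)
  rl <- comp_rank(-abs(lfc))
  rd <- comp_rank(-abs(diff))
  pmax(rp, rl, rd)
}

# sharply peaked motif around a consensus word
sharp_motif <- function(id, consensus, peak = 0.88) {
  w <- nchar(consensus)
  f <- matrix((1 - peak) / 3, 4, w,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  v <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  f[cbind(v, seq_len(w))] <- peak
  motif_matrix(id, f)
}

# reads data.frame builder
make_reads <- function(sequences, sample_id = "s1", quality = NULL) {
  data.frame(
    read_id = sprintf("%s_r%04d", sample_id, seq_along(sequences)),
    sample_id = sample_id,
    sequence = sequences,
    quality = quality %||% strrep("I", nchar(sequences)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared small error-free simulation, built once per test run
.sim_cache <- new.env(parent = emptyenv())

# shared realistic-scale (50 bp read) pipeline input, built once per run
pipeline_fixture <- function() {
  if (is.null(.sim_cache$pipeline)) {
    sheet <- data.frame(sample_id = paste0("s", 1:4),
                        group_label = rep(c("g1", "g2"), each = 2L))
    g <- simulate_genome(30000, seed = 17)
    truth <- simulate_methylation_truth(g, c("g1", "g2"), seed = 18)
    sim <- simulate_rrbs_reads(g, truth, sheet, depth = 30, read_length = 50,
                               seed = 19)
    .sim_cache$pipeline <- list(sheet = sheet, sim = sim)
  }
  .sim_cache$pipeline
}
errorfree_sim <- function(genome_length = 60000L, seed = 7L) {
  key <- paste0("g", genome_length, "_", seed)
  if (is.null(.sim_cache[[key]])) {
    sheet <- data.frame(sample_id = paste0("s", 1:4),
                        group_label = rep(c("g1", "g2"), each = 2L))
    g <- simulate_genome(genome_length, seed = seed)
    truth <- simulate_methylation_truth(g, c("g1", "g2"), seed = seed + 1L)
    sim <- simulate_rrbs_reads(g, truth, sheet, depth = 30, read_length = 222,
                               size_range = c(40, 220), error_rate = 0,
                               conversion_rate = 1, overconversion_rate = 0,
                               seed = seed + 2L)
    .sim_cache[[key]] <- list(genome = g, truth = truth, sheet = sheet,
                              sim = sim)
  }
  .sim_cache[[key]]
}
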