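# RRBS simulator: synthetic genomes, in-silico restriction digestion,
# methylation truth, bisulfite read generation and spike-in controls.
# Every downstream stage of the pipeline is testable against the ground
# truth this module records.

#' In-silico restriction digest
#'
#' Cuts the sequence at every occurrence of the recognition pattern
#' (overlapping occurrences included), `cut_offset` bases into the pattern.
#' MspI (`C^CGG`) is the default; TaqI is `T^CGA` with the same offset.
#' Fragments exactly tile `[0, nchar(sequence))`.
#'
#' @param sequence genome string.
#' @param site recognition sequence (default `"CCGG"`).
#' @param cut_offset cut position within the site (default 1, i.e. `C^CGG`).
#' @return data.frame with 0-based half-open `start`, `end` and `length`;
#'   empty for an empty sequence.
#' @export
in_silico_digest <- function(sequence, site = "CCGG", cut_offset = 1L) {
  n <- nchar(sequence)
  if (n == 0L) {
    return(data.frame(start = integer(0), end = integer(0), length = integer(0)))
  }
  hits <- gregexpr(paste0("(?=", site, ")"), sequence, perl = TRUE)[[1]]
  cuts <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L + cut_offset
  cuts <- cuts[cuts > 0L & cuts < n]
  bounds <- c(0L, sort(unique(cuts)), n)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1],
             length = diff(bounds))
}

#' Library fragment-length histogram
#'
#' Counts digest fragments by library-molecule length, adding
#' `adapter_length` twice (one adapter per end) to model the sequenced
#' molecule. Deterministic; mirrors the electrophoresis prediction used to
#' assess RRBS libraries before sequencing.
#'
#' @param fragments data.frame from [in_silico_digest()].
#' @param adapter_length bases added per end (default 0).
#' @return named integer vector: counts indexed by length.
#' @export
fragment_length_histogram <- function(fragments, adapter_length = 0L) {
  stopifnot(adapter_length >= 0)
  lens <- fragments$length + 2L * as.integer(adapter_length)
  tab <- table(lens)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Simulate a CpG-enriched genome
#'
#' Samples a genome from a first-order chain with the stationary base
#' composition implied by `gc_fraction`, inflating the C-to-G transition by
#' `cpg_enrichment` to mimic the CpG-island-like context around MspI sites.
#'
#' @param length genome length in bases (>= 1).
#' @param gc_fraction target GC content in `[0, 1]` (default 0.45).
#' @param cpg_enrichment multiplier on the CpG dinucleotide frequency over
#'   the base-composition expectation (default 3).
#' @param seed integer PRNG seed; the result is reproducible for a fixed seed.
#' @return object of class `sim_genome`: list with `sequence`,
#'   `cpg_positions` (0-based positions of the C of every CpG) and `seed`.
#' @export
simulate_genome <- function(length, gc_fraction = 0.45, cpg_enrichment = 3,
                            seed = 1L) {
  stopifnot(length >= 1, gc_fraction >= 0, gc_fraction <= 1,
            cpg_enrichment >= 0)
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  trans <- rbind(p, p, p, p)
  rownames(trans) <- names(p)
  if (p[["G"]] > 0 && p[["C"]] > 0 && p[["A"]] + p[["T"]] > 0) {
    # boost P(G | C) to cpg_enrichment times the base expectation and absorb
    # the excess in the A/T rows, so the stationary composition stays p while
    # C runs (and hence CCGG sites) keep their density
    qg <- min(cpg_enrichment * p[["G"]], 0.95,
              p[["G"]] * (1 - p[["G"]]) / p[["C"]])
    row_c <- p * (1 - qg) / (1 - p[["G"]])
    row_c[["G"]] <- qg
    row_at <- (p * (1 - p[["G"]]) - p[["C"]] * row_c) /
      (p[["A"]] + p[["T"]])
    if (all(row_at >= 0)) {
      trans["A", ] <- row_at
      trans["C", ] <- row_c
      trans["T", ] <- row_at
    }
  }
  bases <- c("A", "C", "G", "T")
  out <- integer(length)
  out[1] <- sample.int(4L, 1L, prob = p)
  if (length > 1L) {
    # column of uniform draws, walked through the chain
    u <- stats::runif(length - 1L)
    cum <- t(apply(trans, 1L, cumsum))
    for (i in 2L:length) {
      out[i] <- findInterval(u[i - 1L], cum[out[i - 1L], ], left.open = TRUE) + 1L
    }
  }
  sequence <- paste(bases[out], collapse = "")
  structure(list(sequence = sequence,
                 cpg_positions = find_cpg_sites(sequence) - 1L,
                 seed = seed),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d bp, %d CpGs, seed %d\n",
              nchar(x$sequence), length(x$cpg_positions), x$seed))
  invisible(x)
}

#' Draw per-group CpG methylation truth
#'
#' @param genome a `sim_genome`.
#' @param groups character vector of group labels.
#' @param level `"uniform"` draws every group/CpG level from Uniform(0,1);
#'   a single number fixes all levels to that value.
#' @param seed integer PRNG seed.
#' @return object of class `methylation_truth`: matrix of methylation
#'   probabilities, rows = groups, columns = 0-based CpG positions.
#' @export
simulate_methylation_truth <- function(genome, groups, level = "uniform",
                                       seed = 1L) {
  set.seed(seed)
  ncpg <- length(genome$cpg_positions)
  m <- if (identical(level, "uniform")) {
    matrix(stats::runif(length(groups) * ncpg), nrow = length(groups))
  } else {
    stopifnot(is.numeric(level), all(level >= 0), all(level <= 1))
    matrix(rep_len(level, length(groups) * ncpg), nrow = length(groups))
  }
  rownames(m) <- groups
  colnames(m) <- as.character(genome$cpg_positions)
  class(m) <- c("methylation_truth", class(m))
  m
}

# internal: library fragments = internal digest fragments (both ends are cut
# sites; adapter ligation needs the CG overhang) passing size selection on
# the digest fragment length. The sequenced molecule spans [start, end + 2):
# MspI leaves 5'-CG overhangs and end fill-in extends each strand by the two
# overhang bases, so both strand reads start [CT]GG and end [CT][CT]G.
library_fragments <- function(genome, size_range, site = "CCGG",
                              cut_offset = 1L) {
  digest <- in_silico_digest(genome$sequence, site = site,
                             cut_offset = cut_offset)
  if (nrow(digest) < 3L) {
    return(digest[0, , drop = FALSE])
  }
  internal <- digest[-c(1L, nrow(digest)), , drop = FALSE]
  keep <- internal$length >= size_range[1] & internal$length <= size_range[2]
  out <- internal[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# bisulfite-convert one molecule (integer codes, forward genomic frame).
# cpg_state: logical per CpG-C position in `idx_cpg` (TRUE = methylated).
convert_strand <- function(mol, idx_cpg, cpg_state, conversion_rate,
                           overconversion_rate) {
  out <- mol
  idx_c <- which(mol == 2L)
  idx_non <- setdiff(idx_c, idx_cpg)
  if (length(idx_non) > 0L) {
    conv <- stats::runif(length(idx_non)) < conversion_rate
    out[idx_non[conv]] <- 4L
  }
  if (length(idx_cpg) > 0L) {
    u <- stats::runif(length(idx_cpg))
    to_t <- ifelse(cpg_state, u < overconversion_rate, u < conversion_rate)
    out[idx_cpg[to_t]] <- 4L
  }
  out
}

apply_sequencing_errors <- function(v, error_rate) {
  if (error_rate <= 0) return(v)
  hit <- which(stats::runif(length(v)) < error_rate)
  if (length(hit) > 0L) {
    v[hit] <- ((v[hit] - 1L + sample(1:3, length(hit), replace = TRUE)) %% 4L) + 1L
  }
  v
}

#' Simulate bisulfite RRBS reads with ground truth
#'
#' Performs an in-silico MspI digest, size-selects internal fragments, and
#' emits single-end bisulfite reads for every sample in the sheet. Reads are
#' MspI-anchored: each read starts at a library-molecule end, on the forward
#' or reverse strand with equal probability, truncated to `read_length`.
#' Methylation is drawn once per CpG per DNA molecule (both strands of a
#' molecule agree), then bisulfite chemistry is applied: a methylated CpG C
#' survives as C unless over-converted, an unmethylated C converts to T with
#' probability `conversion_rate` (so P(C) = m (1 - over) + (1 - m)(1 - conv)),
#' and non-CpG Cs convert at `conversion_rate`. Reverse-strand reads apply
#' the same logic to the complementary strand. Uniform sequencing errors are
#' added after conversion.
#'
#' @param genome a `sim_genome`.
#' @param truth a `methylation_truth` matrix (groups x CpGs).
#' @param samples sample sheet data.frame (`sample_id`, `group_label`).
#' @param depth mean reads per library fragment per sample (Poisson).
#' @param read_length read length in bases (default 50).
#' @param size_range digest-fragment size-selection window (default 40-220).
#' @param error_rate per-base uniform sequencing error rate (default 0.001).
#' @param conversion_rate probability that an unmethylated C reads as T
#'   (default 0.995).
#' @param overconversion_rate probability that a methylated CpG C reads as T
#'   (default 0.005).
#' @param seed integer PRNG seed; the full output is byte-identical across
#'   runs for a fixed seed.
#' @return list with
#'   `reads`: named list (per sample) of read data.frames;
#'   `truth`: per-sample per-CpG table (`sample_id`, `cpg_position`,
#'     `true_level`, `n_molecules`, `n_methylated`, `realized_level`);
#'   `fragments`: the library fragments (with `fragment_index`);
#'   `provenance`: per-read origin (`read_id`, `sample_id`, `fragment_index`,
#'     `strand`);
#'   `params`: the simulation parameters.
#' @export
simulate_rrbs_reads <- function(genome, truth, samples, depth = 30,
                                read_length = 50, size_range = c(40, 220),
                                error_rate = 0.001, conversion_rate = 0.995,
                                overconversion_rate = 0.005, seed = 1L) {
  validate_sample_sheet(samples)
  frags <- library_fragments(genome, size_range)
  if (nrow(frags) == 0L) stopf("no fragments pass size selection")
  frags$fragment_index <- seq_len(nrow(frags))
  glen <- nchar(genome$sequence)
  set.seed(seed)

  # precompute molecule templates and their CpG layout
  mol_int <- vector("list", nrow(frags))
  mol_cpg_pos <- vector("list", nrow(frags)) # 1-based within molecule
  mol_cpg_gpos <- vector("list", nrow(frags)) # 0-based genomic C position
  cpg_set <- genome$cpg_positions
  for (f in seq_len(nrow(frags))) {
    s <- frags$start[f]
    e <- min(frags$end[f] + 2L, glen)
    mol <- substr(genome$sequence, s + 1L, e)
    mol_int[[f]] <- seq_to_int(mol)
    local_cpg <- find_cpg_sites(mol) # 1-based
    mol_cpg_pos[[f]] <- local_cpg
    mol_cpg_gpos[[f]] <- s + local_cpg - 1L
  }

  reads <- stats::setNames(vector("list", nrow(samples)), samples$sample_id)
  prov <- vector("list", nrow(samples))
  truth_rows <- vector("list", nrow(samples))

  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    grp <- samples$group_label[si]
    if (!grp %in% rownames(truth)) stopf("group '%s' missing from truth", grp)
    seqs <- character(0); rids <- character(0)
    p_frag <- integer(0); p_strand <- character(0)
    t_mol <- t_meth <- stats::setNames(
      numeric(length(cpg_set)), as.character(cpg_set))
    serial <- 0L
    for (f in seq_len(nrow(frags))) {
      n_mol <- stats::rpois(1L, depth)
      if (n_mol == 0L) next
      mol <- mol_int[[f]]
      lpos <- mol_cpg_pos[[f]]
      gpos <- as.character(mol_cpg_gpos[[f]])
      m <- truth[grp, gpos]
      L <- length(mol)
      rev_lpos <- L - lpos # rev-strand C opposite the CpG G (1-based)
      fwd <- stats::runif(n_mol) < 0.5
      for (k in seq_len(n_mol)) {
        state <- stats::runif(length(lpos)) < m
        t_mol[gpos] <- t_mol[gpos] + 1
        t_meth[gpos] <- t_meth[gpos] + state
        if (fwd[k]) {
          v <- convert_strand(mol, lpos, state, conversion_rate,
                              overconversion_rate)
        } else {
          rc <- 5L - rev(mol) # revcomp on codes 1..4
          v <- convert_strand(rc, rev_lpos, state, conversion_rate,
                              overconversion_rate)
        }
        v <- apply_sequencing_errors(v, error_rate)
        v <- v[seq_len(min(read_length, L))]
        serial <- serial + 1L
        rids <- c(rids, sprintf("%s_r%06d", sid, serial))
        seqs <- c(seqs, int_to_seq(v))
        p_frag <- c(p_frag, f)
        p_strand <- c(p_strand, if (fwd[k]) "+" else "-")
      }
    }
    reads[[si]] <- data.frame(
      read_id = rids, sample_id = sid, sequence = seqs,
      quality = strrep("I", nchar(seqs)))
    prov[[si]] <- data.frame(read_id = rids, sample_id = sid,
                             fragment_index = p_frag, strand = p_strand)
    covered <- t_mol > 0
    truth_rows[[si]] <- data.frame(
      sample_id = sid,
      cpg_position = cpg_set[covered],
      true_level = unname(truth[grp, as.character(cpg_set[covered])]),
      n_molecules = unname(t_mol[covered]),
      n_methylated = unname(t_meth[covered]),
      realized_level = unname(t_meth[covered] / t_mol[covered]))
  }

  list(reads = reads,
       truth = do.call(rbind, truth_rows),
       fragments = frags,
       provenance = do.call(rbind, prov),
       params = list(depth = depth, read_length = read_length,
                     size_range = size_range, error_rate = error_rate,
                     conversion_rate = conversion_rate,
                     overconversion_rate = overconversion_rate, seed = seed))
}

#' Default bisulfite conversion spike-in controls
#'
#' Two synthetic 60-mer oligonucleotides: a CpG-methylated control and a
#' fully unmethylated control, used to measure over- and under-conversion.
#' Sequences are synthetic and deliberately dissimilar from MspI fragments
#' (no CCGG).
#'
#' @return data.frame with columns `name`, `sequence`, `methylated`.
#' @export
default_spikein_controls <- function() {
  data.frame(
    name = c("meth_control", "unmeth_control"),
    sequence = c(
      "ATTCGATGGTAACGTTAGCATCGTTAGGATCGATTAGGTACGATTAGCATTCGATAGGTA",
      "ATTCATGCTAACTTGACCATGATTACCATGATTACCTAGATTGACCATGCTTACATGGTA"),
    methylated = c(TRUE, FALSE))
}

#' Simulate spike-in control reads
#'
#' Unmethylated controls convert every C at `conversion_rate`; methylated
#' controls convert CpG Cs erroneously at `overconversion_rate` and non-CpG
#' Cs at `conversion_rate`. Reads cover the full oligo, from either strand
#' with equal probability. The default spike-in mass fraction in a library is
#' 0.1% of the sample reads (see [spikein_default_fraction]).
#'
#' @param controls data.frame as [default_spikein_controls()].
#' @param conversion_rate,overconversion_rate conversion parameters.
#' @param n_reads total number of control reads.
#' @param seed integer PRNG seed.
#' @return read data.frame (`read_id`, `sample_id`, `sequence`, `quality`).
#' @export
simulate_spike_ins <- function(controls = default_spikein_controls(),
                               conversion_rate = 0.995,
                               overconversion_rate = 0.005,
                               n_reads = 1000L, seed = 1L) {
  set.seed(seed)
  stopifnot(nrow(controls) >= 1L)
  pick <- sample.int(nrow(controls), n_reads, replace = TRUE)
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    ctl <- controls[pick[i], ]
    v <- seq_to_int(ctl$sequence)
    lpos <- if (ctl$methylated) find_cpg_sites(ctl$sequence) else integer(0)
    state <- rep(ctl$methylated, length(lpos))
    if (stats::runif(1) < 0.5) {
      seqs[i] <- int_to_seq(
        convert_strand(v, lpos, state, conversion_rate, overconversion_rate))
    } else {
      L <- length(v)
      rc <- 5L - rev(v)
      seqs[i] <- int_to_seq(
        convert_strand(rc, L - lpos, state, conversion_rate,
                       overconversion_rate))
    }
  }
  data.frame(read_id = sprintf("spike_r%06d", seq_len(n_reads)),
             sample_id = "spikein", sequence = seqs,
             quality = strrep("I", nchar(seqs)))
}

#' Default spike-in mass fraction of a library (0.1%)
#' @export
spikein_default_fraction <- 0.001

#' Simulate a fragment-structured methylation level matrix
#'
#' Generates per-site methylation levels for a two-group design directly at
#' the matrix level (binomial read sampling at the given coverage), with an
#' optional set of planted differentially methylated fragments. Baseline
#' fragment methylation is drawn from Uniform(0.2, 0.8) — the intermediate
#' range typical of the regulatory regions where cell-type differences
#' arise — and planted fragments shift one randomly chosen group by
#' `effect_size` from a Uniform(0.2, 0.6) baseline so levels stay inside
#' [0, 1]. Sites within a fragment share the fragment's mean with a small
#' jitter.
#'
#' @param n_fragments number of fragments.
#' @param n_planted number of fragments carrying a true group difference.
#' @param effect_size absolute methylation difference of planted fragments
#'   (default 0.4).
#' @param sites_per_fragment range of CpG sites per fragment (default 1-4).
#' @param n_per_group samples per group (default 4).
#' @param coverage reads per site per sample (default 30).
#' @param baseline_null range of the Uniform baseline for unchanged
#'   fragments (default c(0.2, 0.8); use c(0.5, 0.5) for a fixed-level null).
#' @param baseline_planted range of the Uniform baseline of planted
#'   fragments before the shift (default c(0.2, 0.6)).
#' @param seed integer PRNG seed.
#' @return list with `levels` (sites x samples matrix, rownames
#'   `"frag_XXXXXX <position>"`), `coverage` (same shape), `groups` (column
#'   group labels) and `planted` (character vector of planted fragment ids).
#' @export
simulate_differential_levels <- function(n_fragments = 1000L, n_planted = 0L,
                                         effect_size = 0.4,
                                         sites_per_fragment = c(1L, 4L),
                                         n_per_group = 4L, coverage = 30L,
                                         baseline_null = c(0.2, 0.8),
                                         baseline_planted = c(0.2, 0.6),
                                         seed = 1L) {
  set.seed(seed)
  stopifnot(n_planted <= n_fragments, effect_size >= 0, effect_size <= 1)
  frag_ids <- sprintf("frag_%06d", seq_len(n_fragments))
  planted <- sort(sample(frag_ids, n_planted))
  nsites <- sample(sites_per_fragment[1]:sites_per_fragment[2], n_fragments,
                   replace = TRUE)
  groups <- rep(c("g1", "g2"), each = n_per_group)
  cols <- paste0(groups, "_", rep(seq_len(n_per_group), 2L))
  total_sites <- sum(nsites)
  levels <- matrix(NA_real_, total_sites, length(cols),
                   dimnames = list(NULL, cols))
  rown <- character(total_sites)
  r <- 0L
  for (f in seq_len(n_fragments)) {
    is_planted <- frag_ids[f] %in% planted
    if (is_planted) {
      base <- stats::runif(1, baseline_planted[1], baseline_planted[2])
      m_g1 <- base
      m_g2 <- base + effect_size
      if (stats::runif(1) < 0.5) { tmp <- m_g1; m_g1 <- m_g2; m_g2 <- tmp }
    } else {
      m_g1 <- m_g2 <- stats::runif(1, baseline_null[1], baseline_null[2])
    }
    for (s in seq_len(nsites[f])) {
      r <- r + 1L
      rown[r] <- paste(frag_ids[f], (s - 1L) * 10L)
      m_site <- pmin(pmax(c(rep(m_g1, n_per_group), rep(m_g2, n_per_group)) +
                            stats::rnorm(1, 0, 0.02), 0), 1)
      levels[r, ] <- stats::rbinom(length(cols), coverage, m_site) / coverage
    }
  }
  rownames(levels) <- rown
  coverage_mat <- matrix(as.numeric(coverage), total_sites, length(cols),
                         dimnames = dimnames(levels))
  list(levels = levels, coverage = coverage_mat, groups = groups,
       planted = planted)
}
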