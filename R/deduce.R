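# Deduced-genome construction: six steps from trimmed bisulfite reads to a
# spacer-separated ad hoc genome. Reads sharing a fully C>T-converted form
# are collapsed into pre-consensus sequences, clustered by similarity,
# refined, strand-merged, and concatenated.

#' Parameters of the deduced-genome builder
#'
#' Houses the tunable constants of the six-step procedure. All thresholds are
#' honored exactly at their boundary: a C is retained when at least 5% of the
#' reads show a C (`>=`), pre-consensus sequences merge when the mismatch
#' ratio is below 8% (`<`), and group members are split off when they exceed
#' 5% mismatch against the consensus (`>`).
#'
#' @param min_multiplicity minimum number of per-sample representative reads
#'   (across all samples) sharing a converted key (default 2).
#' @param c_call_threshold minimum read fraction showing C for the consensus
#'   to retain a C (default 0.05).
#' @param merge_threshold maximum (exclusive) mismatch ratio for merging
#'   pre-consensus sequences into a group (default 0.08).
#' @param refine_threshold mismatch ratio above which (exclusive) a member is
#'   split from its group during refinement (default 0.05).
#' @param spacer_length number of Ns between concatenated fragments
#'   (default 50, matching the read length).
#' @param restriction_start,restriction_end regular expressions for the
#'   bisulfite-space restriction-site ends required of strand-merge
#'   candidates (defaults `[CT]GG` and `[CT][CT]G` for MspI).
#' @param max_refine_iter iteration cap for consensus refinement.
#' @return a list of class `builder_params`.
#' @export
builder_params <- function(min_multiplicity = 2L, c_call_threshold = 0.05,
                           merge_threshold = 0.08, refine_threshold = 0.05,
                           spacer_length = 50L,
                           restriction_start = "^[CT]GG",
                           restriction_end = "[CT][CT]G$",
                           max_refine_iter = 100L) {
  stopifnot(refine_threshold > 0, refine_threshold <= merge_threshold,
            merge_threshold < 1, min_multiplicity >= 1,
            c_call_threshold >= 0, c_call_threshold <= 1, spacer_length >= 0)
  structure(list(min_multiplicity = as.integer(min_multiplicity),
                 c_call_threshold = c_call_threshold,
                 merge_threshold = merge_threshold,
                 refine_threshold = refine_threshold,
                 spacer_length = as.integer(spacer_length),
                 restriction_start = restriction_start,
                 restriction_end = restriction_end,
                 max_refine_iter = as.integer(max_refine_iter)),
            class = "builder_params")
}

#' Step 1: pre-filter reads for genome construction
#'
#' Collapses exact duplicate sequences within each sample to one
#' representative (keeping the copy count), excludes reads containing N from
#' genome building, and discards converted keys (fully C>T-converted forms)
#' supported by fewer than `min_multiplicity` representatives across all
#' samples.
#'
#' @param reads_by_sample named list of read data.frames (one per sample).
#' @param params a [builder_params()] object.
#' @return data.frame with one row per surviving distinct raw sequence:
#'   `converted_key`, `sequence`, `copies` (pre-collapse copy count summed
#'   over samples), `representatives` (number of sample-sequence pairs).
#' @export
prefilter_reads <- function(reads_by_sample, params = builder_params()) {
  if (is.data.frame(reads_by_sample)) {
    reads_by_sample <- split(reads_by_sample, reads_by_sample$sample_id)
  }
  per_sample <- lapply(reads_by_sample, function(df) {
    seqs <- df$sequence[!grepl("N", df$sequence, fixed = TRUE)]
    if (length(seqs) == 0L) return(NULL)
    tab <- table(seqs)
    data.frame(sequence = names(tab), copies = as.integer(tab))
  })
  all <- do.call(rbind, per_sample)
  if (is.null(all) || nrow(all) == 0L) {
    stopf("no reads for genome construction")
  }
  all$converted_key <- convert_ct(all$sequence)
  reps_per_key <- table(all$converted_key)
  keep_keys <- names(reps_per_key)[reps_per_key >= params$min_multiplicity]
  all <- all[all$converted_key %in% keep_keys, , drop = FALSE]
  if (nrow(all) == 0L) stopf("no reads for genome construction")
  # aggregate identical raw sequences across samples
  all$representatives <- 1L
  out <- stats::aggregate(cbind(copies, representatives) ~ converted_key + sequence,
                          data = all, FUN = sum)
  out <- out[order(out$converted_key, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# consensus over member sequences: per-position majority base among covering
# members (weighted), then C assigned wherever the weighted C fraction of
# covering members reaches c_call_threshold.
consensus_sequence <- function(sequences, weights, c_call_threshold) {
  if (length(sequences) == 1L) return(sequences)
  ints <- lapply(sequences, seq_to_int)
  maxlen <- max(lengths(ints))
  counts <- matrix(0, nrow = 5L, ncol = maxlen)
  for (i in seq_along(ints)) {
    v <- ints[[i]]
    counts[cbind(v, seq_along(v))] <- counts[cbind(v, seq_along(v))] + weights[i]
  }
  cover <- colSums(counts)
  maj <- apply(counts[1:4, , drop = FALSE], 2L, which.max)
  cfrac <- counts[2L, ] / cover
  maj[cfrac >= c_call_threshold] <- 2L
  int_to_seq(maj)
}

#' Step 2: preliminary read grouping by exact converted-sequence matching
#'
#' Reads sharing the same fully converted form are combined into one
#' pre-consensus sequence: a position is called C when at least
#' `c_call_threshold` of the member reads (weighted by their pre-collapse
#' copy counts) carry a C there, and keeps the converted base otherwise.
#'
#' @param filtered output of [prefilter_reads()].
#' @param params a [builder_params()] object.
#' @return data.frame of pre-consensus records: `converted_key`, `sequence`,
#'   `member_count` (total read copies), `n_members` (distinct raw
#'   sequences).
#' @export
preliminary_grouping <- function(filtered, params = builder_params()) {
  idx <- split(seq_len(nrow(filtered)), filtered$converted_key)
  keys <- names(idx)
  seqs <- character(length(idx))
  counts <- integer(length(idx))
  nmem <- integer(length(idx))
  for (k in seq_along(idx)) {
    rows <- idx[[k]]
    seqs[k] <- consensus_sequence(filtered$sequence[rows],
                                  filtered$copies[rows],
                                  params$c_call_threshold)
    counts[k] <- sum(filtered$copies[rows])
    nmem[k] <- length(rows)
  }
  out <- data.frame(converted_key = keys, sequence = seqs,
                    member_count = counts, n_members = nmem)
  rownames(out) <- NULL
  out
}

# anchored mismatch ratio between integer vectors over the shorter length
ratio_int <- function(a, b) {
  n <- min(length(a), length(b))
  sum(a[seq_len(n)] != b[seq_len(n)]) / n
}

#' Step 3: cluster pre-consensus sequences by similarity
#'
#' All-against-all ungapped comparison of the converted keys, anchored at the
#' restriction-site-defined 5' end, mismatch ratio over the shorter length.
#' Pre-consensus sequences are processed in descending member-count order
#' (ties broken lexicographically by converted key); each joins the largest
#' already-formed group whose seed key is within `merge_threshold`
#' (strictly below), otherwise it seeds a new group. The group consensus is
#' the per-position majority base with the C-restoration rule applied.
#'
#' @param pre data.frame from [preliminary_grouping()].
#' @param params a [builder_params()] object.
#' @return list of class `fragment_groups`; each element has `members`
#'   (row indices into `pre`), `consensus` and `size`.
#' @export
cluster_fragments <- function(pre, params = builder_params()) {
  ord <- order(-pre$member_count, pre$converted_key)
  key_int <- lapply(pre$converted_key, seq_to_int)
  seeds <- list()
  seed_keys <- character(0)
  members <- list()
  sizes <- numeric(0)
  for (i in ord) {
    ki <- key_int[[i]]
    hit <- 0L
    if (length(seeds) > 0L) {
      ratios <- vapply(seeds, function(s) ratio_int(ki, s), numeric(1))
      cand <- which(ratios < params$merge_threshold)
      if (length(cand) > 0L) {
        best <- cand[order(-sizes[cand], seed_keys[cand])]
        hit <- best[1L]
      }
    }
    if (hit > 0L) {
      members[[hit]] <- c(members[[hit]], i)
      sizes[hit] <- sizes[hit] + pre$member_count[i]
    } else {
      seeds[[length(seeds) + 1L]] <- ki
      seed_keys <- c(seed_keys, pre$converted_key[i])
      members[[length(members) + 1L]] <- i
      sizes <- c(sizes, pre$member_count[i])
    }
  }
  groups <- lapply(seq_along(members), function(g) {
    rows <- members[[g]]
    list(members = rows,
         consensus = consensus_sequence(pre$sequence[rows],
                                        pre$member_count[rows],
                                        params$c_call_threshold),
         size = sizes[g])
  })
  structure(list(groups = groups, pre = pre), class = "fragment_groups")
}

#' Step 4: refine group consensus sequences
#'
#' Iteratively removes members whose converted key exceeds
#' `refine_threshold` mismatch ratio (strictly above) against the converted
#' group consensus, re-clusters the removed members among themselves, and
#' recomputes consensus sequences, until every member is within the
#' threshold.
#'
#' @param grouping a `fragment_groups` object from [cluster_fragments()].
#' @param params a [builder_params()] object.
#' @return a refined `fragment_groups` object.
#' @export
refine_consensus <- function(grouping, params = builder_params()) {
  pre <- grouping$pre
  groups <- grouping$groups
  key_int <- lapply(pre$converted_key, seq_to_int)
  for (iter in seq_len(params$max_refine_iter)) {
    changed <- FALSE
    next_groups <- list()
    for (g in groups) {
      if (length(g$members) == 1L) {
        next_groups[[length(next_groups) + 1L]] <- g
        next
      }
      cons_int <- seq_to_int(convert_ct(g$consensus))
      ratios <- vapply(g$members, function(i) ratio_int(key_int[[i]], cons_int),
                       numeric(1))
      bad <- ratios > params$refine_threshold
      if (!any(bad)) {
        next_groups[[length(next_groups) + 1L]] <- g
        next
      }
      changed <- TRUE
      keep <- g$members[!bad]
      if (length(keep) > 0L) {
        next_groups[[length(next_groups) + 1L]] <- list(
          members = keep,
          consensus = consensus_sequence(pre$sequence[keep],
                                         pre$member_count[keep],
                                         params$c_call_threshold),
          size = sum(pre$member_count[keep]))
      }
      sub <- cluster_fragments(pre[g$members[bad], , drop = FALSE], params)
      for (sg in sub$groups) {
        next_groups[[length(next_groups) + 1L]] <- list(
          members = g$members[bad][sg$members],
          consensus = sg$consensus,
          size = sg$size)
      }
    }
    groups <- next_groups
    if (!changed) {
      return(structure(list(groups = groups, pre = pre),
                       class = "fragment_groups"))
    }
  }
  stopf("consensus refinement did not converge within %d iterations (%d groups)",
        params$max_refine_iter, length(groups))
}

#' Step 5: merge reverse-complement strand partners
#'
#' Candidates are consensus sequences that start and end with the
#' bisulfite-space restriction-site patterns (MspI: 5' `[CT]GG` ...
#' `[CT][CT]G` 3'). Two equal-length candidates pair when they become perfect
#' reverse complements of each other after replacing all Cs by Ts and all Gs
#' by As. The merged consensus takes the forward partner and sets a C at
#' every T position where the literal reverse complement of the partner shows
#' a C (an opposite-strand G is genomic evidence of a C, untouched by
#' bisulfite). Pairing is greedy: fragments are processed by descending read
#' support (ties lexicographic) and merge at most once; unpaired fragments
#' pass through unchanged.
#'
#' @param consensi data.frame with columns `sequence` and `n_reads` (for a
#'   `fragment_groups` object use [fragment_groups_table()]).
#' @param params a [builder_params()] object.
#' @return data.frame of deduced fragments: `sequence`, `n_reads`,
#'   `strand_merged`.
#' @export
merge_reverse_complements <- function(consensi, params = builder_params()) {
  if (inherits(consensi, "fragment_groups")) {
    consensi <- fragment_groups_table(consensi)
  }
  n <- nrow(consensi)
  seqs <- consensi$sequence
  nreads <- consensi$n_reads
  gate <- grepl(params$restriction_start, seqs) &
    grepl(params$restriction_end, seqs)
  tkey <- bisulfite_collapse(seqs)
  # partner must have collapsed form equal to revcomp of ours (A<->T reversal)
  want <- vapply(tkey, function(s) intToUtf8(rev(utf8ToInt(chartr("AT", "TA", s)))),
                 character(1), USE.NAMES = FALSE)
  ord <- order(-nreads, seqs)
  merged_with <- rep(NA_integer_, n)
  is_forward <- rep(FALSE, n)
  for (i in ord) {
    if (!gate[i] || !is.na(merged_with[i])) next
    cand <- which(gate & is.na(merged_with) & tkey == want[i] &
                    seq_len(n) != i)
    if (length(cand) == 0L) next
    j <- cand[order(-nreads[cand], seqs[cand])][1L]
    merged_with[i] <- j
    merged_with[j] <- i
    is_forward[i] <- TRUE
  }
  out_seq <- character(0); out_reads <- numeric(0); out_merged <- logical(0)
  for (i in seq_len(n)) {
    if (is.na(merged_with[i])) {
      out_seq <- c(out_seq, seqs[i])
      out_reads <- c(out_reads, nreads[i])
      out_merged <- c(out_merged, FALSE)
    } else if (is_forward[i]) {
      j <- merged_with[i]
      fwd <- seq_to_int(seqs[i])
      rcp <- seq_to_int(revcomp(seqs[j]))
      fwd[fwd == 4L & rcp == 2L] <- 2L
      out_seq <- c(out_seq, int_to_seq(fwd))
      out_reads <- c(out_reads, nreads[i] + nreads[j])
      out_merged <- c(out_merged, TRUE)
    }
  }
  data.frame(sequence = out_seq, n_reads = out_reads,
             strand_merged = out_merged)
}

#' Tabulate fragment groups
#'
#' @param grouping a `fragment_groups` object.
#' @return data.frame with `sequence` (consensus) and `n_reads` (size).
#' @export
fragment_groups_table <- function(grouping) {
  data.frame(
    sequence = vapply(grouping$groups, `[[`, "", "consensus"),
    n_reads = vapply(grouping$groups, `[[`, 0, "size"))
}

#' Step 6: concatenate fragments into a deduced genome
#'
#' Fragments are ordered deterministically (descending read support, ties
#' lexicographic by sequence), assigned stable identifiers and concatenated
#' with runs of exactly `spacer_length` Ns between consecutive fragments.
#'
#' @param fragments data.frame from [merge_reverse_complements()] (columns
#'   `sequence`, `n_reads`, `strand_merged`).
#' @param params a [builder_params()] object.
#' @return object of class `deduced_genome`: list with `fragments`
#'   (data.frame `fragment_id`, `sequence`, `length`, `n_reads`,
#'   `strand_merged`, `start`, `end` — 0-based half-open coordinates in the
#'   concatenated sequence) and `spacer_length`.
#' @export
concatenate_genome <- function(fragments, params = builder_params()) {
  if (nrow(fragments) == 0L) stopf("no fragments to concatenate")
  ord <- order(-fragments$n_reads, fragments$sequence)
  fragments <- fragments[ord, , drop = FALSE]
  lens <- nchar(fragments$sequence)
  starts <- cumsum(c(0L, utils::head(lens + params$spacer_length, -1L)))
  df <- data.frame(
    fragment_id = sprintf("frag_%06d", seq_len(nrow(fragments))),
    sequence = fragments$sequence,
    length = lens,
    n_reads = fragments$n_reads,
    strand_merged = fragments$strand_merged %||% FALSE,
    start = starts,
    end = starts + lens)
  rownames(df) <- NULL
  structure(list(fragments = df,
                 spacer_length = as.integer(params$spacer_length)),
            class = "deduced_genome")
}

#' Build a deduced genome from trimmed reads
#'
#' Runs the six-step procedure: pre-filtering, preliminary grouping by exact
#' converted-sequence matching, similarity clustering, consensus refinement,
#' reverse-complement merging and concatenation.
#'
#' @param reads_by_sample named list of (trimmed) read data.frames.
#' @param params a [builder_params()] object.
#' @return a `deduced_genome` object.
#' @export
deduce_genome <- function(reads_by_sample, params = builder_params()) {
  filtered <- prefilter_reads(reads_by_sample, params)
  pre <- preliminary_grouping(filtered, params)
  grouping <- cluster_fragments(pre, params)
  grouping <- refine_consensus(grouping, params)
  fragments <- merge_reverse_complements(grouping, params)
  concatenate_genome(fragments, params)
}

#' @export
print.deduced_genome <- function(x, ...) {
  f <- x$fragments
  cat(sprintf(
    "<deduced_genome> %d fragments, %d bp total (+%d-N spacers), %d strand-merged\n",
    nrow(f), sum(f$length), x$spacer_length, sum(f$strand_merged)))
  invisible(x)
}

#' Concatenated sequence of a deduced genome
#'
#' @param genome a `deduced_genome`.
#' @return single string: fragments joined by `spacer_length` Ns.
#' @export
genome_sequence <- function(genome) {
  paste(genome$fragments$sequence,
        collapse = strrep("N", genome$spacer_length))
}

#' Export a deduced genome
#'
#' `write_deduced_genome()` writes the FASTA (one concatenated record, or one
#' record per fragment); `write_fragment_table()` writes the TSV fragment
#' table (id, length, n_reads, strand_merged).
#'
#' @param genome a `deduced_genome`.
#' @param path output file.
#' @param per_fragment write one FASTA record per fragment instead of the
#'   concatenated genome.
#' @return `path`, invisibly.
#' @export
write_deduced_genome <- function(genome, path, per_fragment = FALSE) {
  if (per_fragment) {
    seqs <- stats::setNames(genome$fragments$sequence,
                            genome$fragments$fragment_id)
  } else {
    seqs <- c(deduced_genome = genome_sequence(genome))
  }
  write_fasta(seqs, path)
}

#' @rdname write_deduced_genome
#' @export
write_fragment_table <- function(genome, path) {
  f <- genome$fragments
  utils::write.table(
    f[, c("fragment_id", "length", "n_reads", "strand_merged", "start", "end")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
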