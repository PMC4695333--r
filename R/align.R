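# Bisulfite-aware read alignment against the deduced genome: exact k-mer
# seeds on the converted frames, ungapped full-length verification with the
# asymmetric C/T (forward) and G/A (reverse-complement) matching rules.

#' Aligner parameters
#'
#' @param max_mismatch_rate maximum allowed mismatch fraction (inclusive) of
#'   the aligned read length (default 0.08).
#' @param multimap_policy how to resolve equally good hits: `"random-best"`
#'   assigns one at random (seeded PRNG, mirroring a random single-hit
#'   aligner), `"best-unique"` reports such reads as unaligned.
#' @param seed integer PRNG seed for the random-best policy.
#' @param seed_length exact-seed k-mer length on the converted frames
#'   (default 16).
#' @param report_unaligned include unaligned read ids in the result.
#' @return a list of class `aligner_params`.
#' @export
aligner_params <- function(max_mismatch_rate = 0.08,
                           multimap_policy = c("random-best", "best-unique"),
                           seed = 1L, seed_length = 16L,
                           report_unaligned = FALSE) {
  stopifnot(max_mismatch_rate > 0, max_mismatch_rate < 1, seed_length >= 4L)
  structure(list(max_mismatch_rate = max_mismatch_rate,
                 multimap_policy = match.arg(multimap_policy),
                 seed = as.integer(seed),
                 seed_length = as.integer(seed_length),
                 report_unaligned = isTRUE(report_unaligned)),
            class = "aligner_params")
}

#' Build a bisulfite alignment index
#'
#' Indexes every `seed_length`-mer of the C-to-T-converted forward frame and
#' of the G-to-A-converted frame (for reverse-complement hits) of each
#' fragment. Spacer regions are never indexed and can never be matched:
#' alignment is per fragment.
#'
#' @param genome a `deduced_genome`, or a named character vector of
#'   sequences (e.g. spike-in controls).
#' @param seed_length exact-seed k-mer length (default 16).
#' @return an index object (class `bs_index`).
#' @export
build_index <- function(genome, seed_length = 16L) {
  if (inherits(genome, "deduced_genome")) {
    ids <- genome$fragments$fragment_id
    seqs <- genome$fragments$sequence
  } else {
    ids <- names(genome)
    seqs <- as.character(genome)
    if (is.null(ids)) ids <- sprintf("seq_%04d", seq_along(seqs))
  }
  k <- as.integer(seed_length)
  env_ct <- new.env(hash = TRUE, parent = emptyenv())
  env_ga <- new.env(hash = TRUE, parent = emptyenv())
  add_frame <- function(env, converted, frag_idx) {
    n <- nchar(converted)
    if (n < k) return(invisible())
    kmers <- substring(converted, 1:(n - k + 1L), k:n)
    for (off in seq_along(kmers)) {
      km <- kmers[off]
      env[[km]] <- rbind(env[[km]], c(frag_idx, off))
    }
  }
  for (i in seq_along(seqs)) {
    add_frame(env_ct, convert_ct(seqs[i]), i)
    add_frame(env_ga, convert_ga(seqs[i]), i)
  }
  structure(list(k = k, env_ct = env_ct, env_ga = env_ga,
                 fragment_ids = ids,
                 fragment_seq = seqs,
                 fragment_int = lapply(seqs, seq_to_int),
                 fragment_len = nchar(seqs)),
            class = "bs_index")
}

# count bisulfite-aware mismatches; genome C read as T is a match on the
# forward frame, genome G read as A is a match on the reverse-complement
# frame (one-directional asymmetry).
bs_mismatches <- function(read_int, frag_int, offset, frame) {
  g <- frag_int[offset:(offset + length(read_int) - 1L)]
  if (frame == "CT") {
    sum(read_int != g & !(g == 2L & read_int == 4L))
  } else {
    sum(read_int != g & !(g == 3L & read_int == 1L))
  }
}

# candidate generation + verification for one read; returns a list or NULL
align_one <- function(seq, index, params) {
  len <- nchar(seq)
  k <- index$k
  if (len < k) return(NULL)
  max_mm <- floor(params$max_mismatch_rate * len + 1e-9)
  starts <- unique(c(seq(1L, len - k + 1L, by = k), len - k + 1L))
  cand <- list()
  seen <- character(0)
  collect <- function(query_full, query_int, env, frame) {
    for (s in starts) {
      hits <- env[[substr(query_full, s, s + k - 1L)]]
      if (is.null(hits)) next
      for (h in seq_len(nrow(hits))) {
        fi <- hits[h, 1L]
        off <- hits[h, 2L] - s + 1L
        if (off < 1L || off + len - 1L > index$fragment_len[fi]) next
        key <- paste(frame, fi, off)
        if (key %in% seen) next
        seen <<- c(seen, key)
        mm <- bs_mismatches(query_int, index$fragment_int[[fi]], off, frame)
        if (mm <= max_mm) {
          cand[[length(cand) + 1L]] <<- list(
            fragment = fi, offset = off, frame = frame, mismatches = mm)
        }
      }
    }
  }
  collect(convert_ct(seq), seq_to_int(seq), index$env_ct, "CT")
  rc <- revcomp(seq)
  collect(convert_ga(rc), seq_to_int(rc), index$env_ga, "GA")
  if (length(cand) == 0L) return(NULL)
  mms <- vapply(cand, `[[`, 0L, "mismatches")
  best <- which(mms == min(mms))
  mapq_proxy <- if (length(mms) > 1L) {
    sort(mms)[2L] - min(mms)
  } else Inf
  if (length(best) > 1L) {
    if (params$multimap_policy == "best-unique") return(NULL)
    best <- best[floor(stats::runif(1) * length(best)) + 1L]
  }
  c(cand[[best]], list(mapq_proxy = mapq_proxy, length = len))
}

#' Align one sample's reads to the deduced genome
#'
#' Ungapped, full-read-length bisulfite-aware alignment. A forward-frame
#' position matches when the bases are equal or the genome has C where the
#' read has T; on the reverse-complement frame the genome's G may be read as
#' A. The candidate with the fewest mismatches wins; ties are resolved by
#' `multimap_policy`; candidates exceeding `max_mismatch_rate` are unaligned.
#'
#' @param reads read data.frame for one sample.
#' @param index a `bs_index` from [build_index()].
#' @param params an [aligner_params()] object.
#' @return list with `alignments` (data.frame `read_id`, `sample_id`,
#'   `fragment_id`, `offset` (0-based within the fragment), `orientation`
#'   (`"+"` forward / `"-"` reverse-complement), `mismatches`, `mapq_proxy`,
#'   `length`) and `mapping_efficiency` (aligned / total).
#' @export
align_sample <- function(reads, index, params = aligner_params()) {
  set.seed(params$seed)
  n <- nrow(reads)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- align_one(reads$sequence[i], index, params)
  }
  ok <- !vapply(res, is.null, TRUE)
  alignments <- data.frame(
    read_id = reads$read_id[ok],
    sample_id = if ("sample_id" %in% names(reads)) reads$sample_id[ok] else NA,
    fragment_id = index$fragment_ids[vapply(res[ok], `[[`, 0L, "fragment")],
    offset = vapply(res[ok], `[[`, 0L, "offset") - 1L,
    orientation = ifelse(vapply(res[ok], `[[`, "", "frame") == "CT", "+", "-"),
    mismatches = vapply(res[ok], `[[`, 0L, "mismatches"),
    mapq_proxy = vapply(res[ok], `[[`, 0, "mapq_proxy"),
    length = vapply(res[ok], `[[`, 0L, "length"))
  out <- list(alignments = alignments,
              mapping_efficiency = if (n == 0L) NA_real_ else sum(ok) / n)
  if (params$report_unaligned) out$unaligned <- reads$read_id[!ok]
  out
}

#' Align every sample against the deduced genome
#'
#' Per-sample seeds are derived deterministically from `params$seed`, so the
#' result does not depend on how samples are partitioned over workers.
#'
#' @param reads_by_sample named list of read data.frames.
#' @param index a `bs_index`.
#' @param params an [aligner_params()] object.
#' @param threads number of worker processes (1 = serial); output is
#'   identical for any value.
#' @return list with `alignments` (row-bound data.frame) and `summary`
#'   (per-sample reads in, aligned, mapping efficiency).
#' @export
align_samples <- function(reads_by_sample, index, params = aligner_params(),
                          threads = 1L) {
  run <- function(si) {
    p <- params
    p$seed <- derive_seed(params$seed, si)
    align_sample(reads_by_sample[[si]], index, p)
  }
  res <- if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(reads_by_sample), run, mc.cores = threads)
  } else {
    lapply(seq_along(reads_by_sample), run)
  }
  summary <- data.frame(
    sample_id = names(reads_by_sample),
    reads_in = vapply(reads_by_sample, nrow, 0L),
    aligned = vapply(res, function(r) nrow(r$alignments), 0L),
    mapping_efficiency = vapply(res, `[[`, 0, "mapping_efficiency"))
  rownames(summary) <- NULL
  list(alignments = do.call(rbind, lapply(res, `[[`, "alignments")),
       summary = summary)
}

#' Compute spike-in bisulfite conversion metrics
#'
#' Aligns reads to the control sequences with the same bisulfite-aware rules
#' and tallies C/T evidence at control cytosines. The underconversion rate is
#' the fraction of unmethylated-control Cs still read as C; the
#' overconversion rate is the fraction of methylated-control CpG Cs read as
#' T. Reverse-complement alignments contribute through the complementary
#' G/A evidence.
#'
#' @param reads read data.frame (typically the spike-in subset of a sample).
#' @param controls control data.frame (see [default_spikein_controls()]).
#' @param params an [aligner_params()] object.
#' @return list of class `conversion_metrics`: `underconversion_rate`,
#'   `overconversion_rate`, `n_control_reads`.
#' @export
compute_conversion_metrics <- function(reads,
                                       controls = default_spikein_controls(),
                                       params = aligner_params()) {
  idx <- build_index(stats::setNames(controls$sequence, controls$name),
                     seed_length = params$seed_length)
  aln <- align_sample(reads, idx, params)$alignments
  n_reads <- nrow(aln)
  if (n_reads == 0L) {
    warnf("no reads aligned to the spike-in controls; conversion rates undefined")
    return(structure(list(underconversion_rate = NA_real_,
                          overconversion_rate = NA_real_,
                          n_control_reads = 0L),
                     class = "conversion_metrics"))
  }
  tally <- function(meth) {
    ctl <- controls[controls$methylated == meth, , drop = FALSE]
    c_kept <- 0L; c_conv <- 0L
    for (ci in seq_len(nrow(ctl))) {
      seq <- ctl$sequence[ci]
      v <- seq_to_int(seq)
      cpg <- find_cpg_sites(seq)
      cpos <- if (meth) cpg else which(v == 2L) # methylated controls: CpG Cs
      gpos <- if (meth) cpg + 1L else which(v == 3L) # opposite-strand Cs
      sub <- aln[aln$fragment_id == ctl$name[ci], , drop = FALSE]
      rd <- reads[match(sub$read_id, reads$read_id), "sequence"]
      for (ai in seq_len(nrow(sub))) {
        off <- sub$offset[ai]
        rv <- seq_to_int(rd[ai])
        if (sub$orientation[ai] == "-") rv <- 5L - rev(rv)
        span <- off + seq_along(rv) # 1-based control positions covered
        if (sub$orientation[ai] == "+") {
          at <- cpos[cpos %in% span]
          b <- rv[at - off]
          c_kept <- c_kept + sum(b == 2L)
          c_conv <- c_conv + sum(b == 4L)
        } else {
          at <- gpos[gpos %in% span]
          b <- rv[at - off]
          c_kept <- c_kept + sum(b == 3L) # G = opposite-strand C retained
          c_conv <- c_conv + sum(b == 1L) # A = converted
        }
      }
    }
    if (c_kept + c_conv == 0L) NA_real_ else c(c_kept, c_conv)
  }
  un <- tally(FALSE)
  ov <- tally(TRUE)
  structure(list(
    underconversion_rate = if (all(is.na(un))) NA_real_ else un[1] / sum(un),
    overconversion_rate = if (all(is.na(ov))) NA_real_ else ov[2] / sum(ov),
    n_control_reads = n_reads),
    class = "conversion_metrics")
}

#' @export
print.conversion_metrics <- function(x, ...) {
  cat(sprintf(
    "<conversion_metrics> underconversion %.4f, overconversion %.4f (%d control reads)\n",
    x$underconversion_rate, x$overconversion_rate, x$n_control_reads))
  invisible(x)
}
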