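# End-to-end orchestration: trim -> deduce genome -> align -> call ->
# filter -> differential -> top-fragment export -> motif enrichment, with a
# JSON run manifest, checkpoint/resume and a simulation-backed selftest.

#' Assemble a pipeline configuration
#'
#' @param sample_sheet sample sheet data.frame (see [read_sample_sheet()]) or
#'   path to one.
#' @param output_dir output directory (created if missing).
#' @param reads optional named list of in-memory read data.frames (overrides
#'   `fastq_path`; used by the simulator and selftest).
#' @param comparison two group labels to contrast (default: the first two in
#'   the sheet).
#' @param motif_file optional motif database (MEME minimal or JASPAR pfm);
#'   the motif stage is skipped when absent.
#' @param contexts methylation contexts to call (default CpG).
#' @param builder a [builder_params()] object.
#' @param aligner an [aligner_params()] object.
#' @param shuffle a [shuffle_params()] object.
#' @param quality_cutoff,adapter,min_length trimming settings (see
#'   [trim_reads()]).
#' @param min_coverage,max_coverage site coverage filter (defaults 8, 200).
#' @param top_n,min_mean_coverage,max_adjusted_p top-fragment gates (see
#'   [select_top_fragments()]).
#' @param seed master seed; all stage seeds derive from it.
#' @param threads worker processes for per-sample stages; the output is
#'   identical for any value.
#' @param resume skip stages whose inputs are unchanged since the last run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_sheet, output_dir, reads = NULL,
                            comparison = NULL, motif_file = NULL,
                            contexts = "CpG",
                            builder = builder_params(),
                            aligner = aligner_params(),
                            shuffle = shuffle_params(),
                            quality_cutoff = 20, adapter = TRUSEQ_ADAPTER,
                            min_length = 16,
                            min_coverage = 8L, max_coverage = 200L,
                            top_n = 500L, min_mean_coverage = 2,
                            max_adjusted_p = 0.05,
                            seed = 1L, threads = 1L, resume = FALSE) {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  sample_sheet <- validate_sample_sheet(sample_sheet)
  if (is.null(reads)) {
    missing <- sample_sheet$fastq_path[!file.exists(sample_sheet$fastq_path)]
    if (length(missing) > 0L) stopf("FASTQ file not found: %s", missing[1])
  }
  if (!is.null(motif_file) && !file.exists(motif_file)) {
    stopf("motif file not found: %s", motif_file)
  }
  structure(list(sample_sheet = sample_sheet, output_dir = output_dir,
                 reads = reads, comparison = comparison,
                 motif_file = motif_file, contexts = contexts,
                 builder = builder, aligner = aligner, shuffle = shuffle,
                 quality_cutoff = quality_cutoff, adapter = adapter,
                 min_length = min_length,
                 min_coverage = min_coverage, max_coverage = max_coverage,
                 top_n = top_n, min_mean_coverage = min_mean_coverage,
                 max_adjusted_p = max_adjusted_p,
                 seed = as.integer(seed), threads = as.integer(threads),
                 resume = isTRUE(resume)),
            class = "pipeline_config")
}

# stable fingerprint of an R object (md5 of its serialization)
fingerprint <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(obj, tf, version = 2L, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Run the full reference-free differential methylation pipeline
#'
#' Executes all stages in order, writes every stage's outputs under
#' `output_dir` in documented text formats, and records a JSON manifest with
#' the configuration, per-stage fingerprints and wall times. With
#' `resume = TRUE`, stages whose input fingerprints match the previous run
#' and whose outputs exist are loaded from disk instead of recomputed. Given
#' a fixed seed the entire output tree is byte-identical across runs and
#' independent of `threads`.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the in-memory stage results (`genome`,
#'   `alignments`, `calls`, `site_results`, `fragment_results`, `top`,
#'   `motif_results`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  old_manifest <- if (config$resume && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else NULL
  manifest <- list(seed = config$seed,
                   comparison = config$comparison,
                   stages = list())

  run_stage <- function(name, fp_obj, outputs, run_fn, load_fn) {
    fp <- fingerprint(fp_obj)
    old_fp <- old_manifest$stages[[name]]$fingerprint
    paths <- file.path(out_dir, outputs)
    if (!is.null(old_fp) && identical(old_fp, unname(fp)) &&
        all(file.exists(paths))) {
      res <- load_fn(paths)
      manifest$stages[[name]] <<- list(fingerprint = fp, status = "skipped",
                                       wall_time = 0)
      message(sprintf("[%s] skipped (inputs unchanged)", name))
      return(res)
    }
    t0 <- proc.time()[["elapsed"]]
    res <- run_fn(paths)
    manifest$stages[[name]] <<- list(
      fingerprint = fp, status = "done",
      wall_time = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  sheet <- config$sample_sheet
  samples <- sheet$sample_id

  # -- stage 1: trim ---------------------------------------------------------
  raw_fp <- if (is.null(config$reads)) {
    list(files = unname(tools::md5sum(sheet$fastq_path)))
  } else {
    config$reads
  }
  trim_fp <- list(raw = raw_fp, q = config$quality_cutoff,
                  a = config$adapter, l = config$min_length)
  dir.create(file.path(out_dir, "trimmed"), showWarnings = FALSE)
  trimmed <- run_stage(
    "trim", trim_fp, file.path("trimmed", paste0(samples, ".fastq")),
    run_fn = function(paths) {
      out <- stats::setNames(vector("list", length(samples)), samples)
      for (i in seq_along(samples)) {
        rd <- if (is.null(config$reads)) {
          read_fastq(sheet$fastq_path[i], sample_id = samples[i])
        } else config$reads[[samples[i]]]
        tr <- trim_reads(rd, quality_cutoff = config$quality_cutoff,
                         adapter = config$adapter,
                         min_length = config$min_length)
        write_fastq(tr, paths[i])
        message(sprintf("[trim] %s: %d reads in, %d kept", samples[i],
                        nrow(rd), nrow(tr)))
        out[[i]] <- tr
      }
      out
    },
    load_fn = function(paths) {
      stats::setNames(lapply(seq_along(samples), function(i)
        read_fastq(paths[i], sample_id = samples[i])), samples)
    })

  # -- stage 2: deduce genome ------------------------------------------------
  genome <- run_stage(
    "genome", list(trim_fp, config$builder),
    c("deduced_genome.fa", "deduced_fragments.fa", "fragments.tsv"),
    run_fn = function(paths) {
      g <- deduce_genome(trimmed, config$builder)
      write_deduced_genome(g, paths[1], per_fragment = FALSE)
      write_deduced_genome(g, paths[2], per_fragment = TRUE)
      write_fragment_table(g, paths[3])
      message(sprintf("[genome] %d fragments, %d bp, %d strand-merged",
                      nrow(g$fragments), sum(g$fragments$length),
                      sum(g$fragments$strand_merged)))
      g
    },
    load_fn = function(paths) {
      seqs <- read_fasta(paths[2])
      tab <- utils::read.delim(paths[3], stringsAsFactors = FALSE)
      structure(list(
        fragments = data.frame(fragment_id = tab$fragment_id,
                               sequence = unname(seqs[tab$fragment_id]),
                               length = tab$length, n_reads = tab$n_reads,
                               strand_merged = tab$strand_merged,
                               start = tab$start, end = tab$end),
        spacer_length = config$builder$spacer_length),
        class = "deduced_genome")
    })

  # -- stage 3: align --------------------------------------------------------
  align_fp <- list(genome = genome$fragments$sequence, aligner = config$aligner,
                   trim = trim_fp, seed = config$seed)
  aligned <- run_stage(
    "align", align_fp, c("alignments.tsv", "alignment_summary.tsv"),
    run_fn = function(paths) {
      index <- build_index(genome, seed_length = config$aligner$seed_length)
      p <- config$aligner
      p$seed <- config$seed
      res <- align_samples(trimmed, index, p, threads = config$threads)
      utils::write.table(res$alignments, paths[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(res$summary, paths[2], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      for (i in seq_len(nrow(res$summary))) {
        message(sprintf("[align] %s: %d/%d aligned (%.1f%%)",
                        res$summary$sample_id[i], res$summary$aligned[i],
                        res$summary$reads_in[i],
                        100 * res$summary$mapping_efficiency[i]))
      }
      res
    },
    load_fn = function(paths) {
      list(alignments = utils::read.delim(paths[1], stringsAsFactors = FALSE),
           summary = utils::read.delim(paths[2], stringsAsFactors = FALSE))
    })

  # -- stage 4: call + filter ------------------------------------------------
  call_fp <- list(align = align_fp, contexts = config$contexts,
                  cov = c(config$min_coverage, config$max_coverage))
  dir.create(file.path(out_dir, "calls"), showWarnings = FALSE)
  calls <- run_stage(
    "call", call_fp,
    c(file.path("calls", paste0(samples, ".tsv")), "calls_filtered.tsv"),
    run_fn = function(paths) {
      all_calls <- call_methylation(aligned$alignments, trimmed, genome,
                                    contexts = config$contexts)
      for (i in seq_along(samples)) {
        write_methylation_table(
          all_calls[all_calls$sample_id == samples[i], , drop = FALSE],
          paths[i])
      }
      filtered <- filter_sites(all_calls, config$min_coverage,
                               config$max_coverage)
      utils::write.table(filtered, paths[length(paths)], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      message(sprintf("[call] %d site calls, %d pass coverage [%d, %d]",
                      nrow(all_calls), nrow(filtered), config$min_coverage,
                      config$max_coverage))
      filtered
    },
    load_fn = function(paths) {
      utils::read.delim(paths[length(paths)], stringsAsFactors = FALSE)
    })

  # -- stage 5: differential -------------------------------------------------
  comparison <- config$comparison %||% unique(sheet$group_label)[1:2]
  validate_sample_sheet(sheet[sheet$group_label %in% comparison, ],
                        require_groups = TRUE)
  diff_fp <- list(call = call_fp, comparison = comparison,
                  gates = c(config$top_n, config$min_mean_coverage,
                            config$max_adjusted_p))
  diffres <- run_stage(
    "differential", diff_fp,
    c("site_results.tsv", "fragment_results.tsv",
      "top_fragments_hyper_group1.fa", "top_fragments_hyper_group2.fa"),
    run_fn = function(paths) {
      use <- sheet$sample_id[sheet$group_label %in% comparison]
      grp <- factor(sheet$group_label[match(use, sheet$sample_id)],
                    levels = comparison)
      mat <- build_methylation_matrix(calls[calls$sample_id %in% use, ],
                                      sample_ids = use)
      site_results <- moderated_t_test(mat$levels, grp)
      cov_w <- rowMeans(mat$coverage, na.rm = TRUE)[
        match(site_results$site, rownames(mat$levels))]
      fragment_results <- rank_fragments(site_results, site_coverage = cov_w)
      top <- select_top_fragments(fragment_results, genome, n = config$top_n,
                                  min_mean_coverage = config$min_mean_coverage,
                                  max_adjusted_p = config$max_adjusted_p)
      utils::write.table(site_results, paths[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(fragment_results, paths[2], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_fasta(stats::setNames(top$hyper_group1$sequence,
                                  top$hyper_group1$fragment_id), paths[3])
      write_fasta(stats::setNames(top$hyper_group2$sequence,
                                  top$hyper_group2$fragment_id), paths[4])
      message(sprintf(
        "[differential] %d sites tested, %d fragments ranked, top %d/%d exported",
        nrow(site_results), nrow(fragment_results), nrow(top$hyper_group1),
        nrow(top$hyper_group2)))
      list(site_results = site_results, fragment_results = fragment_results,
           top = top)
    },
    load_fn = function(paths) {
      top1 <- read_fasta(paths[3]); top2 <- read_fasta(paths[4])
      list(site_results = utils::read.delim(paths[1], stringsAsFactors = FALSE),
           fragment_results = utils::read.delim(paths[2],
                                                stringsAsFactors = FALSE),
           top = list(hyper_group1 = data.frame(fragment_id = names(top1),
                                                sequence = unname(top1)),
                      hyper_group2 = data.frame(fragment_id = names(top2),
                                                sequence = unname(top2))))
    })

  # -- stage 6: motif enrichment ---------------------------------------------
  motif_results <- NULL
  if (!is.null(config$motif_file)) {
    motif_fp <- list(diff = diff_fp, motifs = unname(tools::md5sum(config$motif_file)),
                     shuffle = config$shuffle)
    motif_results <- run_stage(
      "motifs", motif_fp, "motif_results.tsv",
      run_fn = function(paths) {
        fg <- diffres$top$hyper_group1$sequence
        bg <- diffres$top$hyper_group2$sequence
        if (length(fg) == 0L || length(bg) == 0L) {
          warnf("empty top-fragment set; motif stage skipped")
          return(NULL)
        }
        motifs <- read_motifs(config$motif_file, pseudocount = 0.1)
        sp <- config$shuffle
        sp$seed <- derive_seed(config$seed, 999L)
        res <- differential_motif_analysis(fg, bg, motifs, sp)
        utils::write.table(res, paths[1], sep = "\t", quote = FALSE,
                           row.names = FALSE)
        message(sprintf("[motifs] %d motifs tested, %d differential, %d artifacts, %d shared",
                        nrow(res), sum(res$verdict == "differential"),
                        sum(res$verdict == "composition-bias-artifact"),
                        sum(res$verdict == "shared")))
        res
      },
      load_fn = function(paths) {
        utils::read.delim(paths[1], stringsAsFactors = FALSE)
      })
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(genome = genome, alignments = aligned, calls = calls,
                 site_results = diffres$site_results,
                 fragment_results = diffres$fragment_results,
                 top = diffres$top, motif_results = motif_results,
                 manifest = manifest))
}

#' Simulation-backed pipeline selftest
#'
#' Simulates an RRBS experiment with known truth, runs the pipeline stages in
#' memory, and asserts the core invariants: (1) error-free fully covered
#' simulation reconstructs exactly one deduced fragment per library fragment,
#' each string-equal to the genomic molecule (in either orientation);
#' (2) called CpG levels at coverage >= 8 correlate with the realized truth
#' at Pearson r >= 0.95; (3) planted differentially methylated fragments are
#' recovered in the top combined ranks; (4) a planted motif is detected and
#' survives the composition filter; (5) spike-in conversion metrics recover
#' the simulated rates.
#'
#' @param seed integer seed for the whole run.
#' @param genome_length simulated genome length (default 60000 bases, enough
#'   for a three-digit fragment count while keeping the test fast).
#' @param verbose print a per-check summary.
#' @return invisible named logical vector of check results; fails with
#'   diagnostics if any check fails.
#' @export
selftest <- function(seed = 1L, genome_length = 60000L, verbose = TRUE) {
  checks <- c()
  note <- function(name, ok) {
    checks[[name]] <<- ok
    if (verbose) message(sprintf("[selftest] %-28s %s", name,
                                 if (ok) "PASS" else "FAIL"))
  }
  sheet <- data.frame(
    sample_id = paste0("s", 1:4),
    group_label = rep(c("g1", "g2"), each = 2L))
  g <- simulate_genome(genome_length, seed = derive_seed(seed, 1L))
  truth <- simulate_methylation_truth(g, c("g1", "g2"),
                                      seed = derive_seed(seed, 2L))
  sim <- simulate_rrbs_reads(g, truth, sheet, depth = 30, read_length = 222,
                             size_range = c(40, 220), error_rate = 0,
                             conversion_rate = 1, overconversion_rate = 0,
                             seed = derive_seed(seed, 3L))
  genome <- deduce_genome(sim$reads)
  expected <- substring(g$sequence, sim$fragments$start + 1L,
                        pmin(sim$fragments$end + 2L, nchar(g$sequence)))
  got <- genome$fragments$sequence
  recon <- length(got) == length(expected) &&
    all(got %in% c(expected, revcomp(expected))) &&
    all(expected %in% c(got, revcomp(got)))
  note("genome_reconstruction", recon)

  index <- build_index(genome)
  aln <- align_samples(sim$reads, index, aligner_params(seed = seed))
  note("mapping_efficiency", all(aln$summary$mapping_efficiency > 0.99))
  calls <- filter_sites(call_methylation(aln$alignments, sim$reads, genome))
  r <- methylation_recovery(calls, genome, g, sim$truth)
  note("methylation_recovery_r>=0.95", isTRUE(r >= 0.95))

  spikes <- simulate_spike_ins(conversion_rate = 0.99,
                               overconversion_rate = 0.01, n_reads = 2000L,
                               seed = derive_seed(seed, 4L))
  cm <- compute_conversion_metrics(spikes)
  note("conversion_metrics", abs(cm$underconversion_rate - 0.01) < 0.01 &&
         abs(cm$overconversion_rate - 0.01) < 0.01)
  if (cm$underconversion_rate > 0.05 || cm$overconversion_rate > 0.05) {
    warnf("conversion control alert: underconversion %.3f, overconversion %.3f",
          cm$underconversion_rate, cm$overconversion_rate)
  }

  dml <- simulate_differential_levels(n_fragments = 1000L, n_planted = 50L,
                                      seed = derive_seed(seed, 5L))
  st <- moderated_t_test(dml$levels, dml$groups)
  cov_w <- dml$coverage[match(st$site, rownames(dml$levels)), 1L]
  fr <- rank_fragments(st, site_coverage = cov_w)
  hits <- mean(dml$planted %in% fr$fragment_id[fr$combined_rank <= 100])
  note("planted_dmr_recovery>=0.9", hits >= 0.9)

  pm <- planted_motif_library()
  set.seed(derive_seed(seed, 6L))
  fg <- generate_background(fit_markov_model("ACGT", 0L), 60L, 50L)
  bg <- generate_background(fit_markov_model("ACGT", 0L), 60L, 50L)
  fg[1:30] <- vapply(fg[1:30], function(s) {
    paste0(substr(s, 1, 20), "TGACGTCATT", substr(s, 31, 50))
  }, "")
  mres <- differential_motif_analysis(fg, bg, pm,
                                      shuffle_params(seed = derive_seed(seed, 7L)))
  note("planted_motif_detected",
       mres$verdict[mres$motif_id == "planted_CREB_like"] == "differential")

  if (!all(unlist(checks))) {
    stopf("selftest failed: %s",
          paste(names(checks)[!unlist(checks)], collapse = ", "))
  }
  invisible(unlist(checks))
}

#' Correlation between called and simulated methylation levels
#'
#' Maps each deduced fragment back to its source library molecule by sequence
#' identity (either orientation), links every called CpG to its genomic
#' position, and returns the Pearson correlation between the called levels
#' and the realized per-sample molecule-level methylation from the simulator
#' truth table.
#'
#' @param calls filtered site calls.
#' @param genome the `deduced_genome` built from the simulated reads.
#' @param sim_genome the `sim_genome` the reads were simulated from.
#' @param truth the simulator truth table (`sim$truth`).
#' @return Pearson correlation coefficient (NA if nothing could be matched).
#' @export
methylation_recovery <- function(calls, genome, sim_genome, truth) {
  frag <- genome$fragments
  gseq <- sim_genome$sequence
  # locate each deduced fragment in the simulated genome, either orientation
  loc <- lapply(frag$sequence, function(s) {
    i <- regexpr(s, gseq, fixed = TRUE)[1]
    if (i > 0L) return(list(start = i - 1L, rev = FALSE, len = nchar(s)))
    i <- regexpr(revcomp(s), gseq, fixed = TRUE)[1]
    if (i > 0L) return(list(start = i - 1L, rev = TRUE, len = nchar(s)))
    NULL
  })
  names(loc) <- frag$fragment_id
  pairs <- merge(calls, data.frame(
    fragment_id = frag$fragment_id,
    mapped = !vapply(loc, is.null, TRUE)), by = "fragment_id")
  pairs <- pairs[pairs$mapped, , drop = FALSE]
  if (nrow(pairs) == 0L) return(NA_real_)
  gpos <- vapply(seq_len(nrow(pairs)), function(i) {
    l <- loc[[pairs$fragment_id[i]]]
    if (!l$rev) l$start + pairs$position[i]
    else l$start + l$len - 2L - pairs$position[i] # C of CpG on the other strand
  }, 0L)
  key <- paste(pairs$sample_id, gpos)
  tkey <- paste(truth$sample_id, truth$cpg_position)
  m <- match(key, tkey)
  ok <- !is.na(m)
  if (sum(ok) < 3L) return(NA_real_)
  stats::cor(pairs$level[ok], truth$realized_level[m[ok]])
}

# small built-in motif library for selftests: one sharp CREB-like planted
# motif plus unrelated decoys
planted_motif_library <- function() {
  sharp <- function(id, consensus) {
    w <- nchar(consensus)
    f <- matrix(0.04, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
    v <- seq_to_int(consensus)
    f[cbind(v, seq_len(w))] <- 0.88
    motif_matrix(id, f)
  }
  list(sharp("planted_CREB_like", "TGACGTCATT"),
       sharp("decoy_GATA", "AGATAAGA"),
       sharp("decoy_ETS", "ACCGGAAGTG"),
       sharp("decoy_HOX", "TTAATTAA"),
       sharp("decoy_NFKB", "GGGACTTTCC"))
}
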