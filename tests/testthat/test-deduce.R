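# The six-step deduced-genome builder.

test_that("pre-filtering collapses duplicates and applies the multiplicity rule", {
  # seen once in one sample: discarded at min_multiplicity 2
  expect_error(prefilter_reads(list(s1 = make_reads("ACGTACGT"))),
               "no reads")
  # identical sequence in two samples (1x each): retained, multiplicity 2
  out <- prefilter_reads(list(s1 = make_reads("ACGTACGT", "s1"),
                              s2 = make_reads("ACGTACGT", "s2")))
  expect_equal(nrow(out), 1L)
  expect_equal(out$copies, 2L)
  expect_equal(out$representatives, 2L)
  # sequences differing only at a C share a converted key and count together
  out2 <- prefilter_reads(list(s1 = make_reads("TCGGA", "s1"),
                               s2 = make_reads("TTGGA", "s2")))
  expect_equal(unique(out2$converted_key), "TTGGA")
  expect_equal(sum(out2$representatives), 2L)
  # duplicates within one sample collapse to one representative
  out3 <- prefilter_reads(list(
    s1 = make_reads(c("ACGTACGT", "ACGTACGT", "ACGTACGT"), "s1"),
    s2 = make_reads("ACGTACGT", "s2")))
  expect_equal(out3$representatives, 2L)
  expect_equal(out3$copies, 4L)
  # reads containing N are excluded from genome building
  expect_error(prefilter_reads(list(s1 = make_reads(c("ACGTN", "ACGTN")))),
               "no reads")
})

test_that("preliminary grouping restores Cs at the 5% read fraction", {
  filtered <- data.frame(
    converted_key = "TTGGATTGA",
    sequence = c("TCGGATTGA", "TTGGATTGA"),
    copies = c(1L, 1L), representatives = c(1L, 1L))
  pre <- preliminary_grouping(filtered)
  expect_equal(pre$sequence, "TCGGATTGA") # C fraction 0.5 >= 0.05
  expect_equal(pre$member_count, 2L)
  # 4 of 100 copies with a C (0.04 < 0.05): position stays T
  filtered$copies <- c(4L, 96L)
  expect_equal(preliminary_grouping(filtered)$sequence, "TTGGATTGA")
  # exactly 5%: retained
  filtered$copies <- c(5L, 95L)
  expect_equal(preliminary_grouping(filtered)$sequence, "TCGGATTGA")
  # a single member keeps its unconverted sequence
  single <- data.frame(converted_key = "TTGA", sequence = "TCGA",
                       copies = 3L, representatives = 2L)
  expect_equal(preliminary_grouping(single)$sequence, "TCGA")
})

test_that("clustering merges below 8% mismatch over the shorter length", {
  mk_pre <- function(keys, counts) {
    data.frame(converted_key = keys, sequence = keys,
               member_count = counts, n_members = 1L)
  }
  # 1/9 = 11.1% > 8%: separate groups
  g1 <- cluster_fragments(mk_pre(c("TTGGATTGA", "TTGGATTTA"), c(2L, 1L)))
  expect_length(g1$groups, 2L)
  # 1/13 = 7.7% < 8%: merged
  a <- "TTGGATTGATTGA"
  b <- paste0(substr(a, 1, 12), "G")
  g2 <- cluster_fragments(mk_pre(c(a, b), c(2L, 1L)))
  expect_length(g2$groups, 1L)
  expect_equal(g2$groups[[1]]$size, 3)
  # identical keys: single group with Cs restored by the member sequences
  pre3 <- data.frame(converted_key = "TTGGATTGA",
                     sequence = c("TCGGATTGA", "TTGGATTGA"),
                     member_count = c(1L, 1L), n_members = 1L)
  g3 <- cluster_fragments(pre3)
  expect_length(g3$groups, 1L)
  expect_equal(g3$groups[[1]]$consensus, "TCGGATTGA")
  # a shorter read that is a prefix of a longer key joins its group
  g4 <- cluster_fragments(mk_pre(c("TTGGATTGATTGA", "TTGGATTGATT"), c(3L, 1L)))
  expect_length(g4$groups, 1L)
})

test_that("refinement splits members above 5% mismatch until convergence", {
  mk_pre <- function(keys, counts) {
    data.frame(converted_key = keys, sequence = keys,
               member_count = counts, n_members = 1L)
  }
  # within 5% of consensus: fixed point
  a20 <- strrep("TTGGA", 4)
  b20 <- paste0(substr(a20, 1, 19), "T") # 1/20 = 5%: not above
  pre <- mk_pre(c(a20, b20), c(2L, 1L))
  grouping <- cluster_fragments(pre, builder_params(merge_threshold = 0.2))
  expect_length(grouping$groups, 1L)
  refined <- refine_consensus(grouping, builder_params(merge_threshold = 0.2))
  expect_length(refined$groups, 1L)
  # two members differing by 10%: forced into one group, refinement splits
  c20 <- paste0(substr(a20, 1, 18), "TT")
  pre2 <- mk_pre(c(a20, c20), c(2L, 1L))
  forced <- cluster_fragments(pre2, builder_params(merge_threshold = 0.2))
  expect_length(forced$groups, 1L)
  split <- refine_consensus(forced) # default refine threshold 5%
  expect_length(split$groups, 2L)
  # singletons are always fixed points
  single <- cluster_fragments(mk_pre("TTGGATTGA", 1L))
  expect_length(refine_consensus(single)$groups, 1L)
})

test_that("reverse-complement merging follows the degenerate-transform rule", {
  # worked example: duplex CGGTACACCG / CGGTGTACCG with methylated CpGs
  cons <- data.frame(sequence = c("CGGTATATCG", "CGGTGTATCG"),
                     n_reads = c(2, 1))
  merged <- merge_reverse_complements(cons)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$sequence, "CGGTACACCG")
  expect_true(merged$strand_merged)
  expect_equal(merged$n_reads, 3)
  # a fragment not starting with [CT]GG is never a candidate
  cons2 <- data.frame(sequence = c("AGGTATATCG", "CGGTGTATCG"),
                      n_reads = c(2, 1))
  merged2 <- merge_reverse_complements(cons2)
  expect_equal(nrow(merged2), 2L)
  expect_false(any(merged2$strand_merged))
  # two copies of a palindromic fragment with no new C evidence merge
  # without change (every T faces a non-G on the partner)
  cons3 <- data.frame(sequence = c("CGGTTAACCG", "CGGTTAACCG"),
                      n_reads = c(1, 1))
  merged3 <- merge_reverse_complements(cons3)
  expect_equal(nrow(merged3), 1L)
  expect_equal(merged3$sequence, "CGGTTAACCG")
})

test_that("concatenation orders fragments and spaces them with 50 Ns", {
  frags <- data.frame(sequence = c(strrep("A", 10), strrep("G", 20)),
                      n_reads = c(5, 9), strand_merged = FALSE)
  g <- concatenate_genome(frags)
  expect_equal(g$fragments$start, c(0L, 70L))
  expect_equal(g$fragments$end, c(20L, 80L))
  expect_equal(g$fragments$sequence[1], strrep("G", 20)) # larger n_reads first
  seqs <- genome_sequence(g)
  expect_equal(nchar(seqs), 80L)
  expect_equal(substr(seqs, 21, 70), strrep("N", 50))
  # single fragment: no spacer
  g1 <- concatenate_genome(frags[1, ])
  expect_equal(nchar(genome_sequence(g1)), 10L)
  # spacer override 0: fragments abut
  g0 <- concatenate_genome(frags, builder_params(spacer_length = 0))
  expect_equal(g0$fragments$start, c(0L, 20L))
  expect_error(concatenate_genome(frags[0, ]), "no fragments")
})

test_that("the builder reconstructs every library fragment exactly (oracle)", {
  fx <- errorfree_sim(20000L)
  dg <- deduce_genome(fx$sim$reads)
  mols <- substring(fx$genome$sequence, fx$sim$fragments$start + 1,
                    pmin(fx$sim$fragments$end + 2, nchar(fx$genome$sequence)))
  expect_equal(nrow(dg$fragments), length(mols))
  # brute-force oracle: consensus from the raw reads of each fragment
  all_reads <- do.call(rbind, fx$sim$reads)
  prov <- fx$sim$provenance
  seq_by_id <- stats::setNames(all_reads$sequence, all_reads$read_id)
  for (f in seq_along(mols)) {
    pf <- prov[prov$fragment_index == f, ]
    expected <- oracle_fragment_consensus(
      unname(seq_by_id[pf$read_id[pf$strand == "+"]]),
      unname(seq_by_id[pf$read_id[pf$strand == "-"]]))
    expect_true(expected %in% c(dg$fragments$sequence,
                                revcomp(dg$fragments$sequence)),
                label = sprintf("fragment %d consensus recovered", f))
    # under full double-strand coverage the consensus is the genomic molecule
    expect_identical(expected, mols[f])
  }
})

test_that("the builder is idempotent on reads from its own output", {
  fx <- errorfree_sim(20000L)
  dg <- deduce_genome(fx$sim$reads)
  # regenerate fully methylated, error-free reads from the deduced fragments
  regen <- lapply(c(s1 = "s1", s2 = "s2"), function(sid) {
    fwd <- vapply(dg$fragments$sequence, function(s) {
      v <- strsplit(s, "")[[1]]
      cpg <- gregexpr("(?=CG)", s, perl = TRUE)[[1]]
      v[v == "C" & !(seq_along(v) %in% cpg)] <- "T"
      paste(v, collapse = "")
    }, "", USE.NAMES = FALSE)
    rev <- vapply(revcomp(dg$fragments$sequence), function(s) {
      v <- strsplit(s, "")[[1]]
      cpg <- gregexpr("(?=CG)", s, perl = TRUE)[[1]]
      v[v == "C" & !(seq_along(v) %in% cpg)] <- "T"
      paste(v, collapse = "")
    }, "", USE.NAMES = FALSE)
    make_reads(c(fwd, rev), sid)
  })
  dg2 <- deduce_genome(regen)
  canon <- function(x) sort(pmin(x, revcomp(x)))
  expect_equal(canon(dg2$fragments$sequence), canon(dg$fragments$sequence))
})

test_that("raising min_multiplicity never increases the fragment count", {
  fx <- errorfree_sim(20000L)
  counts <- vapply(1:4, function(mm) {
    nrow(deduce_genome(fx$sim$reads,
                       builder_params(min_multiplicity = mm))$fragments)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})
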