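# Methylation calling, coverage filtering, fragment aggregation, matrices.

# fragment TTCGGATCGTT: CpGs at 0-based positions 2 and 7
call_fixture <- function() {
  g <- concatenate_genome(data.frame(sequence = "TTCGGATCGTT", n_reads = 1,
                                     strand_merged = FALSE))
  list(genome = g, fid = g$fragments$fragment_id)
}

mk_aln <- function(read_ids, fid, orientation = "+", offset = 0L,
                   sample_id = "s1") {
  data.frame(read_id = read_ids, sample_id = sample_id, fragment_id = fid,
             offset = offset, orientation = orientation, mismatches = 0L,
             mapq_proxy = Inf, length = 11L)
}

test_that("forward reads tally C as methylated and T as unmethylated", {
  fx <- call_fixture()
  reads <- make_reads(c("TTCGGATCGTT", "TTCGGATTGTT", "TTCGGATTGTT",
                        "TTTGGATTGTT"))
  aln <- mk_aln(reads$read_id, fx$fid)
  calls <- call_methylation(aln, reads, fx$genome)
  s2 <- calls[calls$position == 2L, ]
  expect_equal(s2$count_methylated, 3L)
  expect_equal(s2$count_unmethylated, 1L)
  expect_equal(s2$level, 0.75)
  s7 <- calls[calls$position == 7L, ]
  expect_equal(s7$count_methylated, 1L)
  expect_equal(s7$count_unmethylated, 3L)
})

test_that("reverse-complement reads contribute via the paired G", {
  fx <- call_fixture()
  # aligned reverse-complement equals the fragment: G at both CpG Gs
  reads <- make_reads(revcomp("TTCGGATCGTT"))
  aln <- mk_aln(reads$read_id, fx$fid, orientation = "-")
  calls <- call_methylation(aln, reads, fx$genome)
  expect_equal(calls$count_methylated, c(1L, 1L))
  expect_equal(calls$count_unmethylated, c(0L, 0L))
  # converted reverse strand: A at the paired G reads unmethylated
  reads2 <- make_reads(revcomp("TTCAGATCGTT"))
  aln2 <- mk_aln(reads2$read_id, fx$fid, orientation = "-")
  calls2 <- call_methylation(aln2, reads2, fx$genome)
  expect_equal(calls2$count_methylated, c(0L, 1L))
  expect_equal(calls2$count_unmethylated[calls2$position == 2L], 1L)
  # unknown fragment: hard error
  expect_error(call_methylation(mk_aln("r", "nope"), reads, fx$genome),
               "unknown fragment")
  # mismatching bases count for neither side
  reads3 <- make_reads("TTAGGATGGTT")
  calls3 <- call_methylation(mk_aln(reads3$read_id, fx$fid), reads3, fx$genome)
  expect_equal(nrow(calls3), 0L)
})

test_that("coverage filtering keeps [8, 200] inclusively", {
  calls <- data.frame(fragment_id = "f", position = 1:4, context = "CpG",
                      sample_id = "s1",
                      count_methylated = c(3L, 4L, 100L, 101L),
                      count_unmethylated = c(4L, 4L, 100L, 100L),
                      level = 0.5)
  kept <- filter_sites(calls)
  expect_equal(kept$count_methylated + kept$count_unmethylated, c(8L, 200L))
  expect_equal(nrow(filter_sites(calls[0, ])), 0L)
})

test_that("fragment aggregation pools reads, not site levels", {
  calls <- data.frame(fragment_id = "f", position = c(2L, 7L), context = "CpG",
                      sample_id = "s1",
                      count_methylated = c(4L, 8L),
                      count_unmethylated = c(4L, 0L),
                      level = c(0.5, 1))
  agg <- aggregate_fragments(calls)
  expect_equal(agg$level, 12 / 16)
  expect_equal(agg$n_sites, 2L)
  expect_equal(agg$mean_coverage, 8)
  # a single site: fragment level equals the site level
  one <- aggregate_fragments(calls[1, ])
  expect_equal(one$level, 0.5)
  # all sites unmethylated
  zero <- transform(calls, count_methylated = 0L)
  expect_equal(aggregate_fragments(zero)$level, 0)
})

test_that("the level matrix has explicit missing values and sheet column order", {
  calls <- data.frame(
    fragment_id = c("f1", "f1", "f1", "f2", "f2"),
    position = c(2L, 2L, 7L, 1L, 1L), context = "CpG",
    sample_id = c("a", "b", "a", "a", "c"),
    count_methylated = c(1L, 2L, 3L, 4L, 5L),
    count_unmethylated = c(1L, 2L, 1L, 0L, 5L),
    level = c(0.5, 0.5, 0.75, 1, 0.5))
  m <- build_methylation_matrix(calls, sample_ids = c("c", "b", "a"))
  expect_equal(colnames(m$levels), c("c", "b", "a"))
  expect_equal(rownames(m$levels), c("f1 2", "f1 7", "f2 1"))
  expect_true(is.na(m$levels["f1 7", "b"]))
  expect_equal(m$levels["f2 1", "c"], 0.5)
  expect_equal(m$coverage["f1 2", "a"], 2)
  fm <- build_methylation_matrix(aggregate_fragments(calls), unit = "fragment")
  expect_equal(rownames(fm$levels), c("f1", "f2"))
})

test_that("a symmetric simulation calls levels around 0.5 and conserves counts", {
  sheet <- data.frame(sample_id = c("s1", "s2"), group_label = "g1")
  g <- simulate_genome(20000, seed = 21)
  th <- simulate_methylation_truth(g, "g1", level = 0.5)
  sim <- simulate_rrbs_reads(g, th, sheet, depth = 30, read_length = 222,
                             error_rate = 0, conversion_rate = 1,
                             overconversion_rate = 0, seed = 22)
  dg <- deduce_genome(sim$reads)
  idx <- build_index(dg)
  aln <- align_samples(sim$reads, idx)
  calls <- call_methylation(aln$alignments, sim$reads, dg)
  total <- sum(calls$count_methylated + calls$count_unmethylated)
  expect_lt(abs(mean(calls$level[calls$count_methylated +
                                   calls$count_unmethylated >= 8]) - 0.5),
            3 * sqrt(0.25 / total) + 0.02)
  # conservation: every counted base comes from an aligned read overlapping
  # the fragment, bounded by reads x CpGs per read
  max_cpg <- max(vapply(dg$fragments$sequence, function(s)
    length(gregexpr("(?=CG)", s, perl = TRUE)[[1]]), 0L))
  expect_lte(total, nrow(aln$alignments) * max_cpg)
})

test_that("non-CpG contexts report residual unconverted cytosines only", {
  sheet <- data.frame(sample_id = "s1", group_label = "g1")
  g <- simulate_genome(20000, seed = 31)
  th <- simulate_methylation_truth(g, "g1", level = 0.7)
  sim <- simulate_rrbs_reads(g, th, sheet, depth = 60, read_length = 222,
                             error_rate = 0, conversion_rate = 0.98,
                             overconversion_rate = 0, seed = 32)
  dg <- deduce_genome(sim$reads)
  idx <- build_index(dg)
  aln <- align_samples(sim$reads, idx)
  calls <- call_methylation(aln$alignments, sim$reads, dg,
                            contexts = c("CpG", "CHG", "CHH"))
  non <- calls[calls$context != "CpG", ]
  m <- sum(non$count_methylated)
  n <- sum(non$count_methylated + non$count_unmethylated)
  expect_gt(n, 1000)
  expect_lt(abs(m / n - 0.02), 3 * sqrt(0.02 * 0.98 / n) + 0.005)
})
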