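# Per-cytosine methylation calling from alignments, coverage filtering,
# fragment-level aggregation and the sites x samples level matrix.

# 1-based positions of cytosines in the requested contexts
context_positions <- function(sequence, contexts) {
  out <- list()
  if ("CpG" %in% contexts) {
    p <- gregexpr("(?=CG)", sequence, perl = TRUE)[[1]]
    if (p[1] != -1L) out$CpG <- as.integer(p)
  }
  if ("CHG" %in% contexts) {
    p <- gregexpr("(?=C[ACT]G)", sequence, perl = TRUE)[[1]]
    if (p[1] != -1L) out$CHG <- as.integer(p)
  }
  if ("CHH" %in% contexts) {
    p <- gregexpr("(?=C[ACT][ACT])", sequence, perl = TRUE)[[1]]
    if (p[1] != -1L) out$CHH <- as.integer(p)
  }
  out
}

#' Call per-cytosine methylation from alignments
#'
#' For every genomic C in a requested context, forward-orientation reads
#' contribute C (methylated) or T (unmethylated) at the site, and
#' reverse-complement-orientation reads contribute through the complementary
#' base at the paired G — G methylated, A unmethylated; for the CpG context
#' the paired G is the position after the C, so both strands of a CpG are
#' merged into one site. Read bases other than the two expected letters
#' (mismatches, N) are ignored. Non-CpG contexts are called from
#' forward-orientation reads only (the opposite-strand cytosine of a CHG/CHH
#' is a different site). Duplicate reads are not removed: RRBS fragments
#' legitimately share start positions.
#'
#' @param alignments alignment data.frame (see [align_sample()]), any number
#'   of samples.
#' @param reads read data.frame(s) the alignments refer to (data.frame or
#'   named list per sample).
#' @param genome the `deduced_genome` aligned against.
#' @param contexts subset of `c("CpG", "CHG", "CHH")` (default CpG).
#' @return data.frame of `SiteMethylation` rows: `fragment_id`, `position`
#'   (0-based C position within the fragment), `context`, `sample_id`,
#'   `count_methylated`, `count_unmethylated`, `level`. Sites with zero
#'   informative reads are absent.
#' @export
call_methylation <- function(alignments, reads, genome, contexts = "CpG") {
  stopifnot(all(contexts %in% c("CpG", "CHG", "CHH")))
  if (is.list(reads) && !is.data.frame(reads)) {
    reads <- do.call(rbind, reads)
  }
  frag <- genome$fragments
  unknown <- setdiff(unique(alignments$fragment_id), frag$fragment_id)
  if (length(unknown) > 0L) {
    stopf("alignment references unknown fragment '%s'", unknown[1])
  }
  samples <- unique(alignments$sample_id)
  # site catalogue: one row per (fragment, position, context)
  sites <- list()
  site_key <- character(0)
  for (fi in seq_len(nrow(frag))) {
    ctx <- context_positions(frag$sequence[fi], contexts)
    for (cx in names(ctx)) {
      sites[[length(sites) + 1L]] <- data.frame(
        fragment_id = frag$fragment_id[fi], position = ctx[[cx]] - 1L,
        context = cx)
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(fragment_id = character(0), position = integer(0),
               context = character(0))
  if (nrow(sites) == 0L || nrow(alignments) == 0L) {
    return(data.frame(fragment_id = character(0), position = integer(0),
                      context = character(0), sample_id = character(0),
                      count_methylated = integer(0),
                      count_unmethylated = integer(0), level = numeric(0)))
  }
  site_key <- paste(sites$fragment_id, sites$position, sites$context)
  meth <- matrix(0L, nrow = nrow(sites), ncol = length(samples),
                 dimnames = list(site_key, samples))
  unmeth <- meth
  # per-fragment site lookup (1-based C position -> site row)
  by_frag <- split(seq_len(nrow(sites)), sites$fragment_id)
  read_seq <- stats::setNames(reads$sequence, reads$read_id)
  a_frag <- alignments$fragment_id
  a_read <- alignments$read_id
  a_off <- alignments$offset
  a_orient <- alignments$orientation
  a_scol <- match(alignments$sample_id, samples)
  site_pos <- sites$position
  site_ctx <- sites$context
  for (ai in seq_len(nrow(alignments))) {
    rows <- by_frag[[a_frag[ai]]]
    if (is.null(rows)) next
    rv <- seq_to_int(read_seq[[a_read[ai]]])
    len <- length(rv)
    off <- a_off[ai]
    scol <- a_scol[ai]
    if (a_orient[ai] == "+") {
      pos1 <- site_pos[rows] + 1L # 1-based C position
      cover <- rows[pos1 > off & pos1 <= off + len]
      if (length(cover) == 0L) next
      b <- rv[site_pos[cover] + 1L - off]
      m <- b == 2L
      u <- b == 4L
    } else {
      # reverse-complement evidence at the paired G (CpG only)
      cover <- rows[site_ctx[rows] == "CpG"]
      gpos1 <- site_pos[cover] + 2L # 1-based paired G
      cover <- cover[gpos1 > off & gpos1 <= off + len]
      if (length(cover) == 0L) next
      rcv <- 5L - rev(rv) # aligned reverse-complement of the read
      rcv[rcv == 0L] <- 5L # N stays N
      b <- rcv[site_pos[cover] + 2L - off]
      m <- b == 3L
      u <- b == 1L
    }
    if (any(m)) meth[cbind(cover[m], scol)] <- meth[cbind(cover[m], scol)] + 1L
    if (any(u)) unmeth[cbind(cover[u], scol)] <- unmeth[cbind(cover[u], scol)] + 1L
  }
  total <- meth + unmeth
  hit <- which(total > 0L, arr.ind = TRUE)
  out <- data.frame(
    fragment_id = sites$fragment_id[hit[, 1L]],
    position = sites$position[hit[, 1L]],
    context = sites$context[hit[, 1L]],
    sample_id = samples[hit[, 2L]],
    count_methylated = meth[hit],
    count_unmethylated = unmeth[hit])
  out$level <- out$count_methylated /
    (out$count_methylated + out$count_unmethylated)
  out <- out[order(out$fragment_id, out$position, out$sample_id), ]
  rownames(out) <- NULL
  out
}

#' Coverage-filter methylation calls
#'
#' Keeps sites whose total read count per sample lies within
#' `[min_coverage, max_coverage]` (both inclusive; defaults 8 and 200, the
#' standard filtering window).
#'
#' @param calls data.frame from [call_methylation()].
#' @param min_coverage minimum total reads (default 8).
#' @param max_coverage maximum total reads (default 200).
#' @return filtered calls.
#' @export
filter_sites <- function(calls, min_coverage = 8L, max_coverage = 200L) {
  stopifnot(min_coverage > 0, min_coverage <= max_coverage)
  total <- calls$count_methylated + calls$count_unmethylated
  out <- calls[total >= min_coverage & total <= max_coverage, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate site calls to fragment methylation levels
#'
#' The fragment level is coverage-weighted: summed methylated counts over
#' summed total counts across the fragment's passing CpGs (read-level
#' pooling), per sample. Fragments with no passing sites are omitted.
#'
#' @param calls (filtered) calls data.frame.
#' @return data.frame: `fragment_id`, `sample_id`, `level`, `n_sites`,
#'   `mean_coverage`.
#' @export
aggregate_fragments <- function(calls) {
  if (nrow(calls) == 0L) {
    return(data.frame(fragment_id = character(0), sample_id = character(0),
                      level = numeric(0), n_sites = integer(0),
                      mean_coverage = numeric(0)))
  }
  key <- paste(calls$fragment_id, calls$sample_id, sep = "\r")
  m <- tapply(calls$count_methylated, key, sum)
  u <- tapply(calls$count_unmethylated, key, sum)
  n <- tapply(calls$count_methylated, key, length)
  parts <- do.call(rbind, strsplit(names(m), "\r", fixed = TRUE))
  out <- data.frame(fragment_id = parts[, 1L], sample_id = parts[, 2L],
                    level = as.numeric(m / (m + u)),
                    n_sites = as.integer(n),
                    mean_coverage = as.numeric((m + u) / n))
  out <- out[order(out$fragment_id, out$sample_id), ]
  rownames(out) <- NULL
  out
}

#' Build the sites-or-fragments x samples methylation matrix
#'
#' @param calls site calls (`unit = "site"`) or fragment levels from
#'   [aggregate_fragments()] (`unit = "fragment"`).
#' @param sample_ids column order (defaults to order of appearance; pass the
#'   sample sheet's `sample_id` to fix it).
#' @param unit `"site"` or `"fragment"`.
#' @return list with `levels` and `coverage` matrices (coverage only for
#'   sites) and `rows` (row annotation data.frame). Missing values are
#'   explicit NAs; row order is fragment, then position.
#' @export
build_methylation_matrix <- function(calls, sample_ids = NULL,
                                     unit = c("site", "fragment")) {
  unit <- match.arg(unit)
  if (is.null(sample_ids)) sample_ids <- unique(calls$sample_id)
  if (unit == "site") {
    rows <- unique(calls[, c("fragment_id", "position")])
    rows <- rows[order(rows$fragment_id, rows$position), , drop = FALSE]
    key <- paste(rows$fragment_id, rows$position)
    ckey <- paste(calls$fragment_id, calls$position)
  } else {
    rows <- unique(calls[, "fragment_id", drop = FALSE])
    rows <- rows[order(rows$fragment_id), , drop = FALSE]
    key <- rows$fragment_id
    ckey <- calls$fragment_id
  }
  rownames(rows) <- NULL
  levels <- matrix(NA_real_, nrow = length(key), ncol = length(sample_ids),
                   dimnames = list(key, sample_ids))
  ri <- match(ckey, key)
  ci <- match(calls$sample_id, sample_ids)
  ok <- !is.na(ci)
  levels[cbind(ri[ok], ci[ok])] <- calls$level[ok]
  out <- list(levels = levels, rows = rows)
  if (unit == "site") {
    coverage <- matrix(NA_real_, nrow = length(key), ncol = length(sample_ids),
                       dimnames = dimnames(levels))
    coverage[cbind(ri[ok], ci[ok])] <-
      calls$count_methylated[ok] + calls$count_unmethylated[ok]
    out$coverage <- coverage
  } else {
    coverage <- matrix(NA_real_, nrow = length(key), ncol = length(sample_ids),
                       dimnames = dimnames(levels))
    if (!is.null(calls$mean_coverage)) {
      coverage[cbind(ri[ok], ci[ok])] <- calls$mean_coverage[ok]
    }
    out$coverage <- coverage
  }
  out
}
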