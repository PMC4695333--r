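# Position-weight-matrix input: MEME minimal and JASPAR pfm formats.

#' Construct a motif matrix
#'
#' @param motif_id motif identifier.
#' @param frequencies 4 x w numeric matrix (rows A, C, G, T); every column
#'   must sum to 1 within 1e-9.
#' @return an object of class `motif_matrix` with fields `motif_id`,
#'   `frequencies` and `length`.
#' @export
motif_matrix <- function(motif_id, frequencies) {
  frequencies <- as.matrix(frequencies)
  if (nrow(frequencies) != 4L) stopf("motif %s: frequency matrix must have 4 rows", motif_id)
  if (ncol(frequencies) < 1L) stopf("motif %s: length must be >= 1", motif_id)
  rownames(frequencies) <- c("A", "C", "G", "T")
  sums <- colSums(frequencies)
  bad <- which(abs(sums - 1) > 1e-9)
  if (length(bad) > 0L) {
    stopf("motif %s: position %d frequencies sum to %g, not 1",
          motif_id, bad[1], sums[bad[1]])
  }
  structure(list(motif_id = motif_id, frequencies = frequencies,
                 length = ncol(frequencies)),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("<motif_matrix> %s (%d positions)\n", x$motif_id, x$length))
  print(round(x$frequencies, 3))
  invisible(x)
}

normalize_counts <- function(counts, motif_id, pseudocount) {
  counts <- counts + pseudocount
  sums <- colSums(counts)
  bad <- which(sums <= 0)
  if (length(bad) > 0L) {
    stopf("motif %s: position %d does not sum to a positive total",
          motif_id, bad[1])
  }
  sweep(counts, 2L, sums, "/")
}

#' Read motif matrices from MEME minimal or JASPAR pfm files
#'
#' The format is detected from the file content: MEME minimal files contain
#' `letter-probability matrix` blocks introduced by `MOTIF` lines; JASPAR
#' files consist of `>`-header records followed by four count rows (with or
#' without the `A [ ... ]` decoration). Counts (or probabilities) are
#' normalized per position to frequencies, with `pseudocount` added to every
#' cell before normalization.
#'
#' @param path motif database file.
#' @param pseudocount probability/count mass added to every cell before
#'   per-position normalization (default 0).
#' @return list of [motif_matrix()] objects in file order.
#' @export
read_motifs <- function(path, pseudocount = 0) {
  if (!file.exists(path)) stopf("motif file not found: %s", path)
  lines <- readLines(path)
  if (any(grepl("^MOTIF\\b", lines))) {
    parse_meme_motifs(lines, pseudocount)
  } else if (any(startsWith(lines, ">"))) {
    parse_jaspar_motifs(lines, pseudocount)
  } else {
    stopf("unrecognized motif format in %s (expected MEME minimal or JASPAR pfm)",
          path)
  }
}

parse_meme_motifs <- function(lines, pseudocount) {
  motif_starts <- grep("^MOTIF\\b", lines)
  out <- vector("list", length(motif_starts))
  for (k in seq_along(motif_starts)) {
    i <- motif_starts[k]
    id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    j <- i + 1L
    while (j <= length(lines) && !grepl("letter-probability matrix", lines[j])) {
      j <- j + 1L
    }
    if (j > length(lines)) stopf("motif %s: no letter-probability matrix", id)
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[j]))
    rows <- lines[(j + 1L):(j + w)]
    vals <- lapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
    if (any(vapply(vals, length, 0L) != 4L)) {
      stopf("motif %s: matrix rows must have 4 values", id)
    }
    counts <- t(do.call(rbind, vals)) # 4 x w, rows A C G T
    out[[k]] <- motif_matrix(id, normalize_counts(counts, id, pseudocount))
  }
  out
}

parse_jaspar_motifs <- function(lines, pseudocount) {
  lines <- lines[nzchar(trimws(lines))]
  headers <- which(startsWith(lines, ">"))
  out <- vector("list", length(headers))
  for (k in seq_along(headers)) {
    i <- headers[k]
    id <- strsplit(sub("^>", "", trimws(lines[i])), "\\s+")[[1]][1]
    end <- if (k < length(headers)) headers[k + 1L] - 1L else length(lines)
    rows <- lines[(i + 1L):end]
    if (length(rows) != 4L) {
      stopf("motif %s: expected 4 count rows, found %d", id, length(rows))
    }
    vals <- lapply(rows, function(r) {
      r <- gsub("^[ACGT]\\s*\\[|\\]\\s*$", "", trimws(r))
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    if (length(unique(vapply(vals, length, 0L))) != 1L) {
      stopf("motif %s: count rows have unequal lengths", id)
    }
    counts <- do.call(rbind, vals) # rows already A C G T
    out[[k]] <- motif_matrix(id, normalize_counts(counts, id, pseudocount))
  }
  out
}
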