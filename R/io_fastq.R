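# FASTQ reading/writing and read trimming.
#
# Reads are represented as plain data.frames with columns read_id, sample_id,
# sequence and quality (Phred+33 encoded string, possibly NA). This keeps the
# whole pipeline inspectable with ordinary data-frame tools.

#' Read a FASTQ file
#'
#' Reads a (optionally gzip-compressed) 4-line-per-record FASTQ file into a
#' data.frame. N bases are preserved verbatim. Compression is detected
#' transparently from the file content.
#'
#' @param path path to a FASTQ file (plain or gzipped).
#' @param sample_id sample identifier attached to every read (caller context;
#'   defaults to the file name without extension).
#' @return data.frame with columns `read_id`, `sample_id`, `sequence`,
#'   `quality`.
#' @export
read_fastq <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stopf("FASTQ file not found: %s", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  }
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stopf("malformed FASTQ %s: %d lines is not a multiple of 4",
          path, length(lines))
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(read_id = character(0), sample_id = character(0),
                      sequence = character(0), quality = character(0)))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad_hdr <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad_hdr) > 0L) {
    stopf("malformed FASTQ record %d in %s: missing @/+ markers",
          bad_hdr[1], path)
  }
  bad_len <- which(nchar(seqs) != nchar(qual))
  if (length(bad_len) > 0L) {
    stopf(
      "malformed FASTQ record %d in %s: sequence length %d != quality length %d",
      bad_len[1], path, nchar(seqs[bad_len[1]]), nchar(qual[bad_len[1]]))
  }
  ids <- sub("^@", "", hdr)
  ids <- sub("\\s.*$", "", ids)
  data.frame(read_id = ids, sample_id = sample_id,
             sequence = toupper(seqs), quality = qual)
}

#' Write reads to a FASTQ file
#'
#' Inverse of [read_fastq()] on valid data. Reads without quality strings are
#' written with constant quality `I` (Phred 40).
#'
#' @param reads data.frame with columns `read_id`, `sequence` and optionally
#'   `quality`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("quality" %in% names(reads)) reads$quality else NA_character_
  qual <- ifelse(is.na(qual), strrep("I", nchar(reads$sequence)), qual)
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Default Illumina TruSeq adapter used for trimming
#' @export
TRUSEQ_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"

# BWA-style running-sum 3' quality trimming: keep [1, stop) where stop
# maximises the running sum of (cutoff - q) taken from the 3' end.
quality_trim_length <- function(qualities, cutoff) {
  n <- length(qualities)
  if (n == 0L) return(0L)
  s <- 0
  best <- 0
  stop_at <- n
  for (i in n:1) {
    s <- s + (cutoff - qualities[i])
    if (s < 0) break
    if (s > best) {
      best <- s
      stop_at <- i - 1L
    }
  }
  stop_at
}

# Leftmost 3' adapter occurrence: longest read suffix matching an adapter
# prefix with at most floor(error_rate * overlap) mismatches.
adapter_trim_length <- function(sequence, adapter, error_rate, min_overlap) {
  n <- nchar(sequence)
  alen <- nchar(adapter)
  if (n == 0L || alen == 0L) return(n)
  sv <- utf8ToInt(sequence)
  av <- utf8ToInt(adapter)
  for (p in seq_len(n)) {
    ov <- min(n - p + 1L, alen)
    if (ov < min_overlap) break
    mism <- sum(sv[p:(p + ov - 1L)] != av[seq_len(ov)])
    if (mism <= floor(error_rate * ov)) return(p - 1L)
  }
  n
}

#' Quality- and adapter-trim RRBS reads
#'
#' Applies 3' quality trimming (BWA-style running-sum algorithm at the given
#' Phred cutoff, +33 encoding), followed by 3' adapter removal (longest read
#' suffix matching a prefix of the adapter with at most 10% mismatches,
#' minimum overlap 1 by default). Reads shorter than `min_length` after
#' trimming are discarded. Trimming is idempotent. N bases are passed through
#' untouched; downstream filters deal with them.
#'
#' @param reads data.frame as returned by [read_fastq()].
#' @param quality_cutoff Phred cutoff for 3' quality trimming (default 20).
#' @param adapter adapter sequence (default the Illumina TruSeq adapter).
#' @param min_length minimum read length kept after trimming (default 16).
#' @param error_rate maximum mismatch fraction for adapter matching
#'   (default 0.1).
#' @param min_overlap minimum read/adapter overlap considered (default 1).
#' @return data.frame of surviving reads, with an attribute `n_discarded`.
#' @export
trim_reads <- function(reads, quality_cutoff = 20, adapter = TRUSEQ_ADAPTER,
                       min_length = 16, error_rate = 0.1, min_overlap = 1) {
  n <- nrow(reads)
  if (n == 0L) {
    attr(reads, "n_discarded") <- 0L
    return(reads)
  }
  has_qual <- "quality" %in% names(reads)
  out_seq <- character(n)
  out_qual <- character(n)
  for (i in seq_len(n)) {
    s <- reads$sequence[i]
    q <- if (has_qual && !is.na(reads$quality[i])) reads$quality[i] else NA
    # iterate to a fixed point: a cut can expose a new trimmable 3' end
    # (e.g. a single trailing base matching the adapter start at overlap 1)
    repeat {
      len0 <- nchar(s)
      if (!is.na(q)) {
        keep <- quality_trim_length(utf8ToInt(q) - 33L, quality_cutoff)
        s <- substr(s, 1L, keep)
        q <- substr(q, 1L, keep)
      }
      keep <- adapter_trim_length(s, adapter, error_rate, min_overlap)
      s <- substr(s, 1L, keep)
      if (!is.na(q)) q <- substr(q, 1L, keep)
      if (nchar(s) == len0 || nchar(s) == 0L) break
    }
    out_seq[i] <- s
    out_qual[i] <- if (is.na(q)) NA_character_ else q
  }
  survive <- nchar(out_seq) >= min_length
  out <- reads[survive, , drop = FALSE]
  out$sequence <- out_seq[survive]
  if (has_qual) out$quality <- out_qual[survive]
  rownames(out) <- NULL
  attr(out, "n_discarded") <- sum(!survive)
  out
}
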