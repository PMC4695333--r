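# Low-level sequence helpers shared by all modules. Sequences are plain
# uppercase character strings over {A,C,G,T,N}; positions reported to users
# are 0-based half-open (BED convention), internal indexing is 1-based R.

BASE_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Bisulfite frame conversions
#'
#' `convert_ct()` replaces every C by T (the fully converted forward frame);
#' `convert_ga()` replaces every G by A (the frame in which reverse-complement
#' hits are sought); `bisulfite_collapse()` applies both, the degenerate
#' transform used to detect strand partners.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of transformed sequences.
#' @export
convert_ct <- function(x) chartr("C", "T", x)

#' @rdname convert_ct
#' @export
convert_ga <- function(x) chartr("G", "A", x)

#' @rdname convert_ct
#' @export
bisulfite_collapse <- function(x) chartr("CG", "TA", x)

# integer codes 1..5 for A,C,G,T,N (anything else maps to N)
seq_to_int <- function(s) {
  v <- utf8ToInt(s)
  out <- rep(5L, length(v))
  out[v == 65L] <- 1L # A
  out[v == 67L] <- 2L # C
  out[v == 71L] <- 3L # G
  out[v == 84L] <- 4L # T
  out
}

int_to_seq <- function(v) {
  paste(c("A", "C", "G", "T", "N")[v], collapse = "")
}

# mismatches between two equal-anchored sequences over the shorter length
anchored_mismatch <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  va <- utf8ToInt(substr(a, 1L, n))
  vb <- utf8ToInt(substr(b, 1L, n))
  list(mismatches = sum(va != vb), length = n, ratio = sum(va != vb) / n)
}

# find all 1-based start positions of dinucleotide/k-mer contexts
find_cpg_sites <- function(sequence) {
  hits <- gregexpr("(?=CG)", sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)

# deterministic per-unit seed derivation (kept well below 2^31)
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1103L + i * 12289L) %% 2147483399)
}
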