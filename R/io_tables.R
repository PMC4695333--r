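# Sample sheets, per-site methylation call tables, FASTA helpers.

#' Read a sample sheet
#'
#' Accepts a tab-separated file with a header (`sample_id`, `group_label`,
#' `fastq_path`) or a YAML file containing a list of records with the same
#' fields. `fastq_path` may be omitted for simulated in-memory data.
#'
#' @param path sample sheet file.
#' @param require_groups if TRUE, enforce the design needed for differential
#'   analysis: at least two groups with at least two samples each.
#' @return data.frame with columns `sample_id`, `group_label`, `fastq_path`.
#' @export
read_sample_sheet <- function(path, require_groups = FALSE) {
  if (!file.exists(path)) stopf("sample sheet not found: %s", path)
  if (grepl("\\.ya?ml$", path)) {
    recs <- yaml::read_yaml(path)
    sheet <- data.frame(
      sample_id = vapply(recs, function(r) as.character(r$sample_id), ""),
      group_label = vapply(recs, function(r) as.character(r$group_label), ""),
      fastq_path = vapply(recs, function(r)
        as.character(r$fastq_path %||% NA_character_), "")
    )
  } else {
    sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"fastq_path" %in% names(sheet)) sheet$fastq_path <- NA_character_
  }
  validate_sample_sheet(sheet, require_groups = require_groups)
}

#' Construct and validate a sample sheet in memory
#'
#' @param sheet data.frame with columns `sample_id`, `group_label` and
#'   optionally `fastq_path`.
#' @inheritParams read_sample_sheet
#' @return the validated sheet.
#' @export
validate_sample_sheet <- function(sheet, require_groups = FALSE) {
  need <- c("sample_id", "group_label")
  if (!all(need %in% names(sheet))) {
    stopf("sample sheet must have columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) {
    stopf("duplicate sample_id in sample sheet: %s",
          sheet$sample_id[duplicated(sheet$sample_id)][1])
  }
  if (require_groups) {
    sizes <- table(sheet$group_label)
    if (length(sizes) < 2L) {
      stopf("differential analysis needs >= 2 groups, found %d", length(sizes))
    }
    if (any(sizes < 2L)) {
      stopf("differential analysis needs >= 2 samples per group (group '%s' has %d)",
            names(sizes)[sizes < 2][1], min(sizes))
    }
  }
  if (!"fastq_path" %in% names(sheet)) sheet$fastq_path <- NA_character_
  rownames(sheet) <- NULL
  sheet
}

#' Write a per-sample methylation call table
#'
#' Tab-separated, BED-like: `fragment_id`, `start`, `end`, `strand`,
#' `count_methylated`, `count_unmethylated`, `level`, with 0-based half-open
#' coordinates on the deduced genome (strand `+` is the deduced fragment
#' orientation). One row per site; one file per sample.
#'
#' @param calls methylation calls for a single sample (see
#'   [call_methylation()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_methylation_table <- function(calls, path) {
  if ("sample_id" %in% names(calls) &&
      length(unique(calls$sample_id)) > 1L) {
    stopf("write_methylation_table() writes one sample per file; got %d samples",
          length(unique(calls$sample_id)))
  }
  out <- data.frame(
    fragment_id = calls$fragment_id %||% character(0),
    start = calls$position,
    end = calls$position + 1L,
    strand = rep("+", length(calls$position)),
    count_methylated = calls$count_methylated,
    count_unmethylated = calls$count_unmethylated,
    level = calls$count_methylated /
      (calls$count_methylated + calls$count_unmethylated)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a methylation call table written by [write_methylation_table()]
#'
#' The level column is recomputed from the counts so that a write/read
#' round trip is exact.
#'
#' @param path call table file.
#' @param sample_id optional sample id to attach.
#' @return data.frame with columns `fragment_id`, `position`,
#'   `count_methylated`, `count_unmethylated`, `level` (and `sample_id`).
#' @export
read_methylation_table <- function(path, sample_id = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(
    fragment_id = as.character(tab$fragment_id),
    position = as.integer(tab$start),
    count_methylated = as.integer(tab$count_methylated),
    count_unmethylated = as.integer(tab$count_unmethylated)
  )
  out$level <- out$count_methylated /
    (out$count_methylated + out$count_unmethylated)
  if (!is.null(sample_id)) out$sample_id <- sample_id
  out
}

#' FASTA input/output
#'
#' Thin wrappers around Biostrings for named DNA sequence sets.
#'
#' @param sequences named character vector of DNA sequences.
#' @param path FASTA file path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
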