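#' Read / write FASTQ (Phred+33)
#'
#' Thin tidy wrappers around Biostrings' quality-aware FASTQ I/O. Reads come
#' back as a tibble with one row per record; qualities stay as Phred+33
#' strings (decode with [phred_scores()]).
#'
#' @param path FASTQ file path.
#' @return [read_fastq()]: tibble with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("No such FASTQ file: ", path))
  # structural pre-check: Biostrings does not reliably reject a truncated
  # final record, so validate the 4-line layout first
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0) {
    abort(sprintf("Malformed FASTQ: truncated record %d.",
                  length(lines) %/% 4 + 1))
  }
  n_rec <- length(lines) %/% 4
  if (n_rec > 0) {
    ids <- lines[seq(1, length(lines), by = 4)]
    seps <- lines[seq(3, length(lines), by = 4)]
    bad_hdr <- which(!startsWith(ids, "@") | !startsWith(seps, "+"))
    if (length(bad_hdr) > 0) {
      abort(sprintf("Malformed FASTQ: invalid record %d.", bad_hdr[1]))
    }
    seq_len_b <- nchar(lines[seq(2, length(lines), by = 4)], type = "bytes")
    qual_len_b <- nchar(lines[seq(4, length(lines), by = 4)], type = "bytes")
    bad <- which(seq_len_b != qual_len_b)
    if (length(bad) > 0) {
      abort(sprintf("Sequence/quality length mismatch at record %d.", bad[1]))
    }
  }
  tryCatch({
    reads <- Biostrings::readQualityScaledDNAStringSet(path)
    tibble(
      id = names(reads) %||% character(0),
      sequence = as.character(reads),
      quality = as.character(Biostrings::quality(reads))
    )
  }, error = function(e) {
    abort(paste0("Malformed FASTQ (truncated or invalid record): ",
                 conditionMessage(e)))
  })
}

#' @rdname read_fastq
#' @param reads tibble with `id`, `sequence`, `quality`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    abort("Sequence/quality length mismatch.")
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(reads$quality)
  )
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param quality character vector of Phred+33-encoded quality strings.
#' @return list of integer vectors, one per input string.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) {
    if (nchar(q) == 0) return(integer(0))
    utf8ToInt(q) - 33L
  })
}
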