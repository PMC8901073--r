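#' Longest run of consecutive low-quality base calls
#'
#' A call is low-quality when its Phred score is `<= threshold` (the QIIME
#' convention for a stated threshold of 19: Q19 counts as low, Q20 as high).
#'
#' @param quality integer vector of Phred scores.
#' @param threshold Phred score at or below which a call is low-quality.
#' @return integer, the length of the longest low-quality run (0 if none).
#' @export
max_consecutive_low_quality <- function(quality, threshold = 19L) {
  if (length(quality) == 0) abort("Empty quality vector.")
  r <- rle(quality <= threshold)
  runs <- r$lengths[r$values]
  if (length(runs) == 0) 0L else as.integer(max(runs))
}

# Retained read length under the truncation rule: the read is cut immediately
# before the start of the first run of more than `max_bad_run` consecutive
# low-quality calls (whole read retained if no such run).
truncation_length <- function(quality, threshold, max_bad_run) {
  r <- rle(quality <= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- which(r$values & r$lengths > max_bad_run)
  if (length(bad) == 0) length(quality) else starts[bad[1]] - 1L
}

#' Truncate a read at its first disqualifying low-quality run
#'
#' Implements the retained-fraction rule: the read is truncated immediately
#' before the first run of more than `max_bad_run` consecutive low-quality
#' calls (Phred `<= threshold`), and the fraction is the truncated length
#' over the original length.
#'
#' @param read one-row tibble (or list) with `id`, `sequence`, `quality`
#'   (Phred+33 string).
#' @inheritParams max_consecutive_low_quality
#' @param max_bad_run longest tolerated run of low-quality calls.
#' @return list with `read` (truncated) and `fraction`.
#' @export
truncate_and_fraction <- function(read, threshold = 19L, max_bad_run = 3L) {
  q <- phred_scores(read$quality)[[1]]
  n <- length(q)
  if (n == 0) abort("Empty read.")
  keep <- truncation_length(q, threshold, max_bad_run)
  list(
    read = tibble(
      id = read$id,
      sequence = substr(read$sequence, 1L, keep),
      quality = substr(read$quality, 1L, keep)
    ),
    fraction = keep / n
  )
}

#' Quality-filter a set of reads
#'
#' Applies the three filter rules of the study protocol: (i) truncate each
#' read at the first run of more than `max_bad_run` consecutive low-quality
#' calls (Phred `<= threshold`); (ii) require the retained fraction to be at
#' least `min_fraction` of the original length; (iii) allow no uncalled `N`
#' base in the retained portion. Reads failing any rule are dropped;
#' failures are counted once, under the first failing rule in the order
#' fraction, then N.
#'
#' `mode = "longest_run"` provides the alternative non-truncating
#' interpretation: reads whose longest low-quality run exceeds `max_bad_run`
#' are discarded outright (counted under `long_low_run`), the fraction rule
#' is then tested on the longest consecutive high-quality stretch, and reads
#' are never shortened.
#'
#' @param reads tibble from [read_fastq()] or [generate_reads()].
#' @inheritParams truncate_and_fraction
#' @param min_fraction minimum retained (or high-quality-stretch) fraction.
#' @param mode `"truncate"` (default) or `"longest_run"`.
#' @return list with `kept` (tibble of retained, possibly truncated reads)
#'   and `stats` (a one-row `QcStats` tibble: `n_input`, `n_kept`,
#'   `n_long_low_run`, `n_low_fraction`, `n_contains_n`, `retention_rate`).
#' @export
filter_reads <- function(reads, threshold = 19L, max_bad_run = 3L,
                         min_fraction = 0.75,
                         mode = c("truncate", "longest_run")) {
  mode <- match.arg(mode)
  qs <- phred_scores(reads$quality)
  n_input <- nrow(reads)
  fail <- character(n_input)
  out_seq <- reads$sequence
  out_qual <- reads$quality
  for (i in seq_len(n_input)) {
    q <- qs[[i]]
    n <- length(q)
    if (mode == "truncate") {
      keep <- truncation_length(q, threshold, max_bad_run)
      if (keep / n < min_fraction) {
        fail[i] <- "low_fraction"
        next
      }
      seq_i <- substr(reads$sequence[i], 1L, keep)
      if (grepl("N", seq_i, fixed = TRUE)) {
        fail[i] <- "contains_n"
        next
      }
      out_seq[i] <- seq_i
      out_qual[i] <- substr(reads$quality[i], 1L, keep)
    } else {
      if (max_consecutive_low_quality(q, threshold) > max_bad_run) {
        fail[i] <- "long_low_run"
        next
      }
      r <- rle(q > threshold)
      best <- if (any(r$values)) max(r$lengths[r$values]) else 0L
      if (best / n < min_fraction) {
        fail[i] <- "low_fraction"
        next
      }
      if (grepl("N", reads$sequence[i], fixed = TRUE)) {
        fail[i] <- "contains_n"
        next
      }
    }
  }
  kept <- reads
  kept$sequence <- out_seq
  kept$quality <- out_qual
  kept <- kept[fail == "", , drop = FALSE]
  stats <- tibble(
    n_input = n_input,
    n_kept = nrow(kept),
    n_long_low_run = sum(fail == "long_low_run"),
    n_low_fraction = sum(fail == "low_fraction"),
    n_contains_n = sum(fail == "contains_n"),
    retention_rate = if (n_input == 0) NA_real_ else nrow(kept) / n_input
  )
  list(kept = kept, stats = stats)
}
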