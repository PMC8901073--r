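#' Filter rare OTUs
#'
#' Retains exactly the taxa with total count `>= min_total` and a nonzero
#' count in at least `min_samples` samples; the sample set is unchanged.
#' This is the standard reading of the protocol's "fewer than 10 counts in 2
#' samples or less" filter, and it is idempotent.
#'
#' @param table a raw `otu_tbl`.
#' @param min_total minimum total count across samples.
#' @param min_samples minimum number of samples with a nonzero count.
#' @return the filtered `otu_tbl`.
#' @export
filter_otus <- function(table, min_total = 10L, min_samples = 2L) {
  stopifnot(is_otu_table(table))
  m <- otu_counts(table)
  keep <- rowSums(m) >= min_total & rowSums(m > 0) >= min_samples
  if (!any(keep)) {
    abort("All taxa removed by the OTU filter; review min_total/min_samples.")
  }
  replace_counts(table, m[keep, , drop = FALSE])
}

#' Cumulative sum scaling (CSS) normalization
#'
#' Per sample j, the scaling factor s_j is the sum of the counts at or below
#' q_j, the `quantile`-th (type-1, lower empirical) quantile of the sample's
#' positive counts; values are `x / s_j * scale_constant`. Ties at the
#' quantile are included in the cumulative sum. The fixed median quantile
#' keeps the operation deterministic; within-sample rank order of taxa is
#' unchanged by construction.
#'
#' @param table a raw `otu_tbl` (every sample needs at least one positive
#'   count).
#' @param quantile proportion in (0, 1].
#' @param scale_constant positive multiplier applied after division.
#' @return a normalized `otu_tbl` carrying `scaling_factors` and
#'   `scale_constant` attributes.
#' @export
css_normalize <- function(table, quantile = 0.5, scale_constant = 1000) {
  stopifnot(is_otu_table(table))
  m <- otu_counts(table)
  s <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    pos <- x[x > 0]
    if (length(pos) == 0) return(0)
    q <- stats::quantile(pos, quantile, type = 1, names = FALSE)
    sum(x[x <= q])
  }, 0)
  if (any(s == 0)) {
    abort(paste0("CSS scaling factor is zero for sample: ",
                 colnames(m)[which(s == 0)[1]]))
  }
  norm <- sweep(m, 2, s, "/") * scale_constant
  replace_counts(table, norm, normalized = TRUE,
                 scaling_factors = setNames(s, colnames(m)),
                 scale_constant = scale_constant)
}

#' Aggregate an OTU table at a taxonomic rank
#'
#' Sums values over taxa sharing the lineage prefix up to `rank`; explicit
#' `"uncultured"`/`"unclassified"` labels are real levels and aggregate by
#' their full prefix, never get dropped.
#'
#' @param table an `otu_tbl` (raw or normalized).
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return an `otu_tbl` whose rows are the distinct lineage prefixes;
#'   `taxon_id` becomes the `;`-joined prefix.
#' @export
aggregate_taxonomy <- function(table, rank) {
  stopifnot(is_otu_table(table))
  rank <- match.arg(rank, setdiff(wb_ranks(), "domain"))
  ranks_use <- wb_ranks()[seq_len(match(rank, wb_ranks()))]
  lin <- otu_lineages(table)
  if (!all(ranks_use %in% names(lin))) {
    abort("Table lacks the lineage columns needed for this rank.")
  }
  key <- do.call(paste, c(lin[ranks_use], sep = ";"))
  m <- otu_counts(table)
  agg <- rowsum(m, group = key)
  lin_out <- lin[!duplicated(key), ranks_use, drop = FALSE]
  lin_out <- lin_out[match(rownames(agg), key[!duplicated(key)]), , drop = FALSE]
  lin_out$taxon_id <- rownames(agg)
  otu_table(agg, lin_out[, c("taxon_id", ranks_use)], sample_meta(table),
            normalized = is_normalized(table),
            scaling_factors = attr(table, "scaling_factors"),
            scale_constant = attr(table, "scale_constant"),
            rank = rank)
}

#' Mean relative abundance per treatment x timepoint cell
#'
#' Per cell, the mean over samples of each taxon's within-sample proportion;
#' taxa whose cell mean falls at or below `min_rel` are pooled into an
#' `"other"` row, so cell proportions (including `"other"`) sum to 1.
#'
#' @param table an `otu_tbl`.
#' @param rank rank to aggregate to first (`NULL` keeps the current rows).
#' @param min_rel pooling threshold on the cell-mean proportion (0 disables
#'   pooling).
#' @return tibble with `treatment`, `timepoint`, `taxon`, `proportion`.
#' @export
relative_abundance <- function(table, rank = NULL, min_rel = 0.001) {
  stopifnot(is_otu_table(table))
  if (!is.null(rank)) table <- aggregate_taxonomy(table, rank)
  m <- otu_counts(table)
  props <- sweep(m, 2, colSums(m), "/")
  md <- sample_meta(table)
  long <- as_tibble(props, rownames = "taxon") |>
    tidyr::pivot_longer(-"taxon", names_to = "sample", values_to = "p") |>
    left_join(md[, c("sample", "treatment", "timepoint")], by = "sample") |>
    group_by(.data$treatment, .data$timepoint, .data$taxon) |>
    summarise(proportion = mean(.data$p), .groups = "drop")
  long |>
    mutate(taxon = ifelse(min_rel == 0 | .data$proportion > min_rel,
                          .data$taxon, "other")) |>
    group_by(.data$treatment, .data$timepoint, .data$taxon) |>
    summarise(proportion = sum(.data$proportion), .groups = "drop")
}

#' Rarefaction curves
#'
#' Sequence mode: for each sample and depth, the mean (and SD) number of
#' distinct taxa observed over `reps` random subsamples of reads drawn
#' without replacement. Sample mode: the mean cumulative number of distinct
#' taxa over `reps` random orderings of the samples.
#'
#' @param table a raw `otu_tbl`.
#' @param depths integer depths (reads for sequence mode, number of samples
#'   for sample mode).
#' @param reps number of random subsamples/orderings.
#' @param mode `"sequence"` or `"sample"`.
#' @param seed integer seed.
#' @return tibble with `mode`, `unit` (sample id or `"pooled"`), `depth`,
#'   `mean`, `sd`.
#' @export
rarefaction_curves <- function(table, depths, reps = 10L,
                               mode = c("sequence", "sample"), seed = 1L) {
  stopifnot(is_otu_table(table))
  mode <- match.arg(mode)
  m <- otu_counts(table)
  withr::with_seed(seed, {
    if (mode == "sequence") {
      if (any(depths > max(colSums(m)))) {
        abort("Depth exceeds the largest library size.")
      }
      out <- purrr::map_dfr(colnames(m), function(smp) {
        x <- m[, smp]
        pool <- rep.int(seq_along(x), x)
        n <- length(pool)
        purrr::map_dfr(depths[depths <= n], function(d) {
          rich <- vapply(seq_len(reps), function(r) {
            length(unique(pool[sample.int(n, d)]))
          }, 0L)
          tibble(mode = "sequence", unit = smp, depth = d,
                 mean = mean(rich), sd = sd(rich))
        })
      })
    } else {
      if (any(depths > ncol(m))) abort("Depth exceeds the number of samples.")
      pres <- m > 0
      out <- purrr::map_dfr(depths, function(d) {
        rich <- vapply(seq_len(reps), function(r) {
          ord <- sample.int(ncol(m), d)
          sum(rowSums(pres[, ord, drop = FALSE]) > 0)
        }, 0L)
        tibble(mode = "sample", unit = "pooled", depth = d,
               mean = mean(rich), sd = sd(rich))
      })
    }
  })
  out
}
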