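#' Prevalence-based core taxa
#'
#' Taxa (at `rank`, genus by default) with a nonzero count in at least
#' `prevalence_threshold` of the chosen samples. The threshold is applied as
#' `presence >= threshold * n` with a tiny guard against floating-point
#' error in the product, so a taxon present in 9 of 10 samples passes a 0.9
#' threshold. The pre-weaning core pools all T0+T1 samples; the post core
#' all T2+T3 samples.
#'
#' @param table an `otu_tbl` (the filtered raw table by default in the
#'   pipeline; prevalence uses presence/absence so raw vs normalized only
#'   affects `avg_count`).
#' @param period `"pre"`, `"post"` or `"all"`; alternatively give `samples`.
#' @param samples optional character vector of sample ids overriding
#'   `period`.
#' @param prevalence_threshold proportion of samples a core taxon must occur
#'   in.
#' @param rank rank at which membership is evaluated.
#' @return a `core_set` tibble: lineage columns, `prevalence`, `avg_count`
#'   (mean count over the chosen samples), with attributes `period`,
#'   `threshold`, `rank`, `n_samples`.
#' @export
core_taxa <- function(table, period = c("all", "pre", "post"), samples = NULL,
                      prevalence_threshold = 0.9, rank = "genus") {
  stopifnot(is_otu_table(table))
  md <- sample_meta(table)
  if (is.null(samples)) {
    period <- match.arg(period)
    samples <- if (period == "all") md$sample else md$sample[md$period == period]
  } else {
    period <- "custom"
    missing <- setdiff(samples, md$sample)
    if (length(missing) > 0) {
      abort(paste0("Unknown sample(s): ", paste(missing, collapse = ", ")))
    }
  }
  if (length(samples) == 0) abort("Empty sample subset.")
  agg <- aggregate_taxonomy(table, rank)
  m <- otu_counts(agg)[, samples, drop = FALSE]
  presence <- rowSums(m > 0)
  n <- length(samples)
  keep <- presence + 1e-9 >= prevalence_threshold * n
  lin <- otu_lineages(agg)[keep, , drop = FALSE]
  out <- bind_cols(lin, tibble(
    prevalence = unname(presence[keep]) / n,
    avg_count = unname(rowMeans(m[keep, , drop = FALSE]))
  )) |> arrange(across(any_of(wb_ranks())))
  structure(out, class = c("core_set", class(tibble())),
            period = period, threshold = prevalence_threshold,
            rank = rank, n_samples = n)
}

#' Compare two core sets
#'
#' Overlap of pre- vs post-weaning cores, matching on the full lineage (all
#' rank columns both sets share), as in a two-period core comparison.
#'
#' @param pre,post `core_set` tibbles (or plain tibbles of lineages) at the
#'   same rank.
#' @return list with `n_pre`, `n_post`, `n_shared`, and tibbles `shared`,
#'   `pre_only`, `post_only`.
#' @export
compare_cores <- function(pre, post) {
  ranks <- intersect(intersect(wb_ranks(), names(pre)), names(post))
  if (length(ranks) == 0) abort("Core sets share no lineage columns.")
  key_pre <- do.call(paste, c(pre[ranks], sep = ";"))
  key_post <- do.call(paste, c(post[ranks], sep = ";"))
  if (anyDuplicated(key_pre) || anyDuplicated(key_post)) {
    abort("Core sets must have unique lineages.")
  }
  shared <- intersect(key_pre, key_post)
  list(
    n_pre = length(key_pre),
    n_post = length(key_post),
    n_shared = length(shared),
    shared = as_tibble(pre[key_pre %in% shared, ranks, drop = FALSE]),
    pre_only = as_tibble(pre[!key_pre %in% shared, ranks, drop = FALSE]),
    post_only = as_tibble(post[!key_post %in% shared, ranks, drop = FALSE])
  )
}
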