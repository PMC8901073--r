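#' Per-sample alpha-diversity indices
#'
#' Computes observed richness, Chao1 (bias-corrected,
#' `S + F1(F1-1)/(2(F2+1))`), ACE (rare-taxon cutoff 10) and Fisher's alpha
#' on integer counts, and Shannon (bits, log base 2), Simpson (`1 - sum
#' p^2`), Pielou equitability (`H / log2(S)`) and Simpson evenness
#' (`(1/sum p^2)/S`) on proportions. The richness estimators' formulas need
#' integer frequencies-of-frequencies, so `table` must hold raw counts;
#' pass the CSS-normalized table as `normalized` to compute the
#' proportion-based indices from normalized values, as the pipeline does.
#'
#' @param table a raw (integer) `otu_tbl`.
#' @param normalized optional normalized `otu_tbl` with the same samples,
#'   used for the proportion-based indices.
#' @return tibble with one row per sample and columns `sample`,
#'   `observed_otus`, `chao1`, `ACE`, `fisher_alpha`, `shannon`, `simpson`,
#'   `equitability`, `simpson_e`.
#' @export
alpha_diversity <- function(table, normalized = NULL) {
  stopifnot(is_otu_table(table))
  if (is_normalized(table)) {
    abort("Richness estimators need integer counts: pass the raw table (use `normalized =` for the CSS table).")
  }
  m <- otu_counts(table)
  if (any(abs(m - round(m)) > 1e-8)) {
    abort("Richness estimators need integer counts: pass the raw table.")
  }
  pm <- if (is.null(normalized)) m else {
    stopifnot(is_otu_table(normalized))
    otu_counts(normalized)[, colnames(m), drop = FALSE]
  }
  # estimateR warns (NaN) where ACE is undefined; that case is handled below
  est <- suppressWarnings(vegan::estimateR(t(round(m))))
  # ACE is undefined (0/0) when a sample has no rare taxa (abundance <= 10):
  # there is nothing to extrapolate from, so fall back to observed richness
  ace <- as.numeric(est["S.ACE", ])
  ace[!is.finite(ace)] <- as.numeric(est["S.obs", ])[!is.finite(ace)]
  fisher <- suppressWarnings(vegan::fisher.alpha(t(round(m))))
  prop_idx <- apply(pm, 2, function(x) {
    p <- x[x > 0] / sum(x)
    s <- length(p)
    h <- -sum(p * log2(p))
    simp <- 1 - sum(p^2)
    c(shannon = h,
      simpson = simp,
      equitability = if (s > 1) h / log2(s) else NA_real_,
      simpson_e = (1 / sum(p^2)) / s)
  })
  tibble(
    sample = colnames(m),
    observed_otus = as.numeric(est["S.obs", ]),
    chao1 = as.numeric(est["S.chao1", ]),
    ACE = ace,
    fisher_alpha = as.numeric(fisher),
    shannon = unname(prop_idx["shannon", ]),
    simpson = unname(prop_idx["simpson", ]),
    equitability = unname(prop_idx["equitability", ]),
    simpson_e = unname(prop_idx["simpson_e", ])
  )
}

#' Summarise alpha diversity per period and treatment cell
#'
#' Cell means in the layout of a published alpha-diversity table: the
#' `overall` pre/post columns (all samples of a period) and the per-diet
#' cells. `observed_species` is emitted as a duplicate of `observed_otus`
#' for compatibility with that layout.
#'
#' @param alpha per-sample tibble from [alpha_diversity()].
#' @param metadata a [sample_metadata()] tibble.
#' @return tibble with `index`, `period`, `group`, `value`.
#' @export
alpha_summary <- function(alpha, metadata) {
  long <- alpha |>
    tidyr::pivot_longer(-"sample", names_to = "index", values_to = "value") |>
    left_join(metadata[, c("sample", "treatment", "period")], by = "sample")
  per_cell <- long |>
    group_by(.data$index, .data$period, group = as.character(.data$treatment)) |>
    summarise(value = mean(.data$value), .groups = "drop")
  overall <- long |>
    group_by(.data$index, .data$period) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    mutate(group = "overall")
  out <- bind_rows(overall, per_cell)
  dup <- out[out$index == "observed_otus", ]
  if (nrow(dup) > 0) {
    dup$index <- "observed_species"
    out <- bind_rows(out, dup)
  }
  arrange(out[, c("index", "period", "group", "value")],
          .data$index, .data$period, .data$group)
}

#' Baseline-adjust per-sample alpha indices
#'
#' For each treatment group and index, subtracts the group's mean value at
#' the baseline timepoint from all of that group's values, so group means at
#' baseline are exactly zero and between-timepoint differences are
#' unchanged. This removes confounding from individual variability at the
#' first sampling day.
#'
#' @param alpha per-sample tibble from [alpha_diversity()].
#' @param metadata a [sample_metadata()] tibble.
#' @param baseline baseline timepoint label.
#' @return long tibble `sample`, `pig`, `treatment`, `timepoint`, `period`,
#'   `index`, `value`, `adjusted`.
#' @export
baseline_adjust <- function(alpha, metadata, baseline = "T0") {
  if (!baseline %in% as.character(metadata$timepoint)) {
    abort(paste0("No samples at baseline timepoint ", baseline))
  }
  long <- alpha |>
    tidyr::pivot_longer(-"sample", names_to = "index", values_to = "value") |>
    left_join(metadata, by = "sample")
  miss <- long |>
    group_by(.data$treatment) |>
    summarise(has = any(.data$timepoint == baseline), .groups = "drop")
  if (!all(miss$has)) {
    abort("Every treatment group needs at least one baseline sample.")
  }
  long |>
    group_by(.data$treatment, .data$index) |>
    mutate(adjusted = .data$value -
             mean(.data$value[.data$timepoint == baseline])) |>
    ungroup() |>
    select("sample", "pig", "treatment", "timepoint", "period",
           "index", "value", "adjusted")
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` between sample columns,
#' computed on the (normalized) table values.
#'
#' @param table an `otu_tbl`.
#' @return a `stats::dist` object labelled with sample ids.
#' @export
bray_curtis <- function(table) {
  stopifnot(is_otu_table(table))
  m <- otu_counts(table)
  if (ncol(m) < 2) abort("Need at least 2 samples.")
  vegan::vegdist(t(m), method = "bray")
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 minimization (vegan's engine) from a metric-scaling
#' start with random restarts; deterministic for a fixed `seed`.
#'
#' @param dist a `dist` object (e.g. from [bray_curtis()]).
#' @param k embedding dimension.
#' @param seed integer seed.
#' @param trymax random restarts.
#' @return a `wb_nmds` list: `points` (tibble `sample`, `NMDS1`..), `stress`
#'   (Kruskal stress-1, proportion), `converged`.
#' @export
nmds <- function(dist, k = 2L, seed = 1L, trymax = 20L) {
  n <- attr(dist, "Size")
  if (k >= n) abort("k must be smaller than the number of samples.")
  fit <- withr::with_seed(seed, {
    vegan::metaMDS(dist, k = k, trymax = trymax, trace = 0,
                   autotransform = FALSE, wascores = FALSE)
  })
  pts <- as_tibble(fit$points, rownames = "sample")
  names(pts) <- c("sample", paste0("NMDS", seq_len(k)))
  structure(list(points = pts, stress = fit$stress,
                 converged = isTRUE(fit$converged > 0) || isTRUE(fit$converged)),
            class = "wb_nmds")
}

#' @export
print.wb_nmds <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d points, stress = %.4f\n",
              nrow(x$points), x$stress))
  invisible(x)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Pseudo-F from squared dissimilarities: `SS_total = (1/n) sum_{i<j}
#' d_ij^2`, `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, `pseudo_F =
#' ((SS_total - SS_within)/(k-1)) / (SS_within/(n-k))`; the p-value is the
#' permutation tail `(#{F_perm >= F_obs} + 1)/(n_perm + 1)`, shuffling
#' labels freely or within `strata` (e.g. pig) when given.
#'
#' @param dist a `dist` object.
#' @param grouping factor/character of group labels, one per sample in
#'   `dist` order.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param strata optional labels restricting permutations to occur within
#'   each stratum.
#' @return a `wb_permanova` tibble row: `pseudo_F`, `R2`, `df_between`,
#'   `df_within`, `p_value`, `n_perm`.
#' @export
permanova <- function(dist, grouping, n_perm = 999L, seed = 1L, strata = NULL) {
  n <- attr(dist, "Size")
  f <- factor(grouping)
  if (length(f) != n) abort("grouping length must match the distance matrix.")
  if (nlevels(f) < 2) abort("Need at least 2 groups.")
  D2 <- as.matrix(dist)^2
  k <- nlevels(f)
  ss_w <- function(lab) {
    tot <- 0
    for (lev in levels(f)) {
      idx <- which(lab == lev)
      tot <- tot + sum(D2[idx, idx]) / (2 * length(idx))
    }
    tot
  }
  ss_t <- sum(D2) / (2 * n)
  ssw_obs <- ss_w(f)
  f_stat <- function(ssw) ((ss_t - ssw) / (k - 1)) / (ssw / (n - k))
  F_obs <- f_stat(ssw_obs)
  F_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- if (is.null(strata)) {
        sample.int(n)
      } else {
        out <- seq_len(n)
        for (s in unique(strata)) {
          w <- which(strata == s)
          out[w] <- w[sample.int(length(w))]
        }
        out
      }
      f_stat(ss_w(f[idx]))
    }, 0)
  })
  p <- (sum(F_perm >= F_obs - 1e-12) + 1) / (n_perm + 1)
  structure(
    tibble(pseudo_F = F_obs, R2 = 1 - ssw_obs / ss_t,
           df_between = k - 1L, df_within = n - k,
           p_value = p, n_perm = as.integer(n_perm)),
    class = c("wb_permanova", class(tibble())),
    F_perm = F_perm
  )
}
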