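#' Per-sample Firmicutes:Bacteroidetes ratio
#'
#' Sums the (normalized) values of all taxa with phylum Firmicutes and
#' phylum Bacteroidetes per sample and takes their ratio. Samples with a
#' zero Bacteroidetes sum have an undefined ratio and are excluded with a
#' warning.
#'
#' @param norm_table an `otu_tbl` (CSS-normalized in the pipeline) whose
#'   lineages include the phylum rank.
#' @return tibble `sample`, `pig`, `treatment`, `timepoint`, `period`,
#'   `firmicutes`, `bacteroidetes`, `ratio`.
#' @export
fb_ratio <- function(norm_table) {
  stopifnot(is_otu_table(norm_table))
  lin <- otu_lineages(norm_table)
  if (!"phylum" %in% names(lin)) abort("Table lacks phylum-level lineages.")
  m <- otu_counts(norm_table)
  firm <- colSums(m[lin$phylum == "Firmicutes", , drop = FALSE])
  bact <- colSums(m[lin$phylum == "Bacteroidetes", , drop = FALSE])
  md <- sample_meta(norm_table)
  out <- md[, c("sample", "pig", "treatment", "timepoint", "period")]
  out$firmicutes <- unname(firm[out$sample])
  out$bacteroidetes <- unname(bact[out$sample])
  bad <- out$bacteroidetes == 0
  if (any(bad)) {
    warn(sprintf("Excluding %d sample(s) with zero Bacteroidetes sum (undefined ratio).",
                 sum(bad)))
    out <- out[!bad, ]
  }
  out$ratio <- out$firmicutes / out$bacteroidetes
  out
}

#' Median F:B ratio per treatment x period cell
#'
#' @param fb tibble from [fb_ratio()].
#' @return tibble `treatment`, `period`, `n`, `median_fb`.
#' @export
fb_cell_summary <- function(fb) {
  fb |>
    group_by(.data$treatment, .data$period) |>
    summarise(n = dplyr::n(), median_fb = median(.data$ratio), .groups = "drop")
}

#' Repeated-measures model for the F:B ratio
#'
#' Fits `ratio ~ timepoint + treatment + timepoint:treatment` — where
#' "timepoint" is the pre/post-weaning period — with the pig random
#' intercept and AR(1) residual correlation of [fit_repeated_model()]. The
#' three-term ANOVA table is the published layout for this analysis.
#'
#' @param fb tibble from [fb_ratio()].
#' @param interaction `FALSE` drops the interaction term (the main-effects
#'   model).
#' @param ... passed to [fit_repeated_model()].
#' @return a `wb_rmfit`.
#' @export
fb_model <- function(fb, interaction = TRUE, ...) {
  if (nlevels(droplevels(fb$treatment)) < 2 || nlevels(droplevels(fb$period)) < 2) {
    abort("Need at least 2 treatments and both periods.")
  }
  d <- fb
  d$timepoint_term <- d$period
  form <- if (interaction) {
    ratio ~ timepoint_term + treatment + timepoint_term:treatment
  } else {
    ratio ~ timepoint_term + treatment
  }
  fit <- fit_repeated_model(d, form, pig = "pig", time = "timepoint", ...)
  fit$terms$term <- sub("timepoint_term", "timepoint", fit$terms$term)
  names(fit$coefficients) <- sub("timepoint_term", "timepoint",
                                 names(fit$coefficients))
  fit
}

#' Bootstrap inference for the F:B ratio
#'
#' Resamples the data with replacement `n_boot` times, recomputes every
#' sample's F:B ratio in each replicate, and refits the repeated-measures
#' model to each replicate. Resampling is stratified within treatment x
#' timepoint cells so each replicate preserves the design's cell sizes.
#' With `resample = "sample"` (default) the unit is the sample; copies of
#' the same pig drawn more than once are split into pseudo-pigs, each
#' holding at most one draw per timepoint, so the AR(1) covariance stays
#' positive-definite while the pig-level clustering of the copies is kept.
#' `resample = "pig"` draws whole pigs (with all their timepoints) within
#' treatment, the cluster bootstrap.
#'
#' @param norm_table a CSS-normalized `otu_tbl`.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param resample `"sample"` or `"pig"`.
#' @param interaction refit the interaction model (default) or the
#'   main-effects model in each replicate.
#' @param .indices internal: list of `n_boot` integer vectors of row indices
#'   into the F:B table, overriding the resampling (used for exactness
#'   checks).
#' @return a `wb_fb_boot` object: `observed` (the [fb_model()] fit on the
#'   original data), `term_summary` (per term: observed statistic/p plus
#'   bootstrap medians `statistic_bstr`, `p_value_bstr`), `cell_summary`
#'   (per treatment x period: observed `median_fb` plus bootstrap quartiles
#'   `q1_bstr`, `q3_bstr`), the full per-replicate tibbles, `n_boot`,
#'   `n_redrawn`, `seed`.
#' @export
bootstrap_fb <- function(norm_table, n_boot = 1000L, seed = 1L,
                         resample = c("sample", "pig"), interaction = TRUE,
                         .indices = NULL) {
  resample <- match.arg(resample)
  fb <- fb_ratio(norm_table)
  observed <- fb_model(fb, interaction = interaction)
  obs_cells <- fb_cell_summary(fb)
  cell <- interaction(fb$treatment, fb$timepoint, drop = TRUE)
  cell_idx <- split(seq_len(nrow(fb)), cell)
  pig_group <- fb |> distinct(.data$pig, .data$treatment)
  pigs_by_tr <- split(pig_group$pig, pig_group$treatment)
  rows_by_pig <- split(seq_len(nrow(fb)), fb$pig)

  draw_indices <- function() {
    if (resample == "sample") {
      unlist(lapply(cell_idx, function(ix) ix[sample.int(length(ix), length(ix), replace = TRUE)]),
             use.names = FALSE)
    } else {
      unlist(lapply(pigs_by_tr, function(pp) {
        drawn <- pp[sample.int(length(pp), length(pp), replace = TRUE)]
        unlist(lapply(seq_along(drawn), function(i) {
          r <- rows_by_pig[[drawn[i]]]
          names(r) <- NULL
          r
        }), use.names = FALSE)
      }), use.names = FALSE)
    }
  }

  n_redrawn <- 0L
  # replicate refits warm-start at the observed fit's variance estimates
  warm <- c(phi = unname(observed$sigma2_pig / max(observed$sigma2_e, 1e-12)),
            rho = unname(observed$rho))
  one_rep <- function(idx) {
    d <- fb[idx, ]
    # split a pig's repeated draws into pseudo-pigs: copy k of a
    # (pig, timepoint) pair goes to pseudo-pig k
    # (under pig resampling the kth drawn block of a pig is exactly copy k
    # at every timepoint, so the same rule yields per-draw clusters)
    copy <- stats::ave(seq_along(idx), d$pig, d$timepoint, FUN = seq_along)
    d$pig <- paste(d$pig, copy, sep = ".")
    fit <- fb_model(d, interaction = interaction, start = warm,
                    optim_control = list(factr = 1e10))
    med <- tapply(d$ratio, list(d$treatment, d$period), median)
    cells <- tibble(
      treatment = factor(rep(rownames(med), ncol(med)), levels(fb$treatment)),
      period = factor(rep(colnames(med), each = nrow(med)), levels(fb$period)),
      median_fb = c(med)
    )
    list(terms = fit$terms[, c("term", "statistic", "p_value")], cells = cells)
  }

  reps_terms <- vector("list", n_boot)
  reps_cells <- vector("list", n_boot)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (try in 1:100) {
        idx <- if (!is.null(.indices)) .indices[[b]] else draw_indices()
        ok <- all(table(factor(fb$treatment[idx], levels = levels(fb$treatment)),
                        factor(fb$period[idx], levels = levels(fb$period))) > 0)
        if (ok) break
        n_redrawn <- n_redrawn + 1L
      }
      r <- one_rep(idx)
      r$terms$replicate <- b
      r$cells$replicate <- b
      reps_terms[[b]] <- r$terms
      reps_cells[[b]] <- r$cells
    }
  })
  reps_terms <- bind_rows(reps_terms)
  reps_cells <- bind_rows(reps_cells)
  term_summary <- reps_terms |>
    group_by(.data$term) |>
    summarise(statistic_bstr = median(.data$statistic),
              p_value_bstr = median(.data$p_value), .groups = "drop") |>
    right_join(observed$terms[, c("term", "statistic", "p_value")], by = "term") |>
    select("term", "statistic", "p_value", "statistic_bstr", "p_value_bstr")
  term_summary <- term_summary[match(observed$terms$term, term_summary$term), ]
  cell_summary <- reps_cells |>
    group_by(.data$treatment, .data$period) |>
    summarise(q1_bstr = quantile(.data$median_fb, 0.25, names = FALSE),
              q3_bstr = quantile(.data$median_fb, 0.75, names = FALSE),
              .groups = "drop") |>
    right_join(obs_cells[, c("treatment", "period", "median_fb")],
               by = c("treatment", "period")) |>
    select("treatment", "period", "median_fb", "q1_bstr", "q3_bstr") |>
    arrange(.data$treatment, .data$period)
  structure(list(
    observed = observed,
    term_summary = term_summary,
    cell_summary = cell_summary,
    replicate_terms = reps_terms,
    replicate_cells = reps_cells,
    n_boot = as.integer(n_boot),
    n_redrawn = n_redrawn,
    seed = seed,
    resample = resample
  ), class = "wb_fb_boot")
}

#' @export
print.wb_fb_boot <- function(x, ...) {
  cat(sprintf("F:B bootstrap: %d replicates (%s resampling, %d redrawn)\n",
              x$n_boot, x$resample, x$n_redrawn))
  print(as.data.frame(x$term_summary), row.names = FALSE)
  print(as.data.frame(x$cell_summary), row.names = FALSE)
  invisible(x)
}
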