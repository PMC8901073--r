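#' Plot alpha-diversity trends per diet group
#'
#' Mean index value per treatment over timepoints, faceted by index; set
#' `adjusted = TRUE` on a [baseline_adjust()] result to show the
#' baseline-adjusted series (all groups start at 0).
#'
#' @param adjusted_alpha long tibble from [baseline_adjust()].
#' @param adjusted plot the `adjusted` (default) or raw `value` column.
#' @return a ggplot.
#' @export
plot_alpha_trends <- function(adjusted_alpha, adjusted = TRUE) {
  ycol <- if (adjusted) "adjusted" else "value"
  dat <- adjusted_alpha |>
    group_by(.data$treatment, .data$timepoint, .data$index) |>
    summarise(y = mean(.data[[ycol]]), .groups = "drop")
  ggplot(dat, aes(x = .data$timepoint, y = .data$y,
                  colour = .data$treatment, group = .data$treatment)) +
    geom_line() +
    geom_point() +
    facet_wrap(~index, scales = "free_y") +
    labs(x = "timepoint",
         y = if (adjusted) "baseline-adjusted index" else "index",
         colour = "diet") +
    theme_minimal()
}

#' Ordination scatter plot of an NMDS result
#'
#' @param object a `wb_nmds`.
#' @param metadata optional [sample_metadata()] tibble joined on `sample`.
#' @param colour,shape metadata columns mapped to aesthetics.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.wb_nmds <- function(object, metadata = NULL, colour = "treatment",
                             shape = "period", ...) {
  dat <- object$points
  if (!is.null(metadata)) dat <- left_join(dat, metadata, by = "sample")
  p <- ggplot(dat, aes(x = .data$NMDS1, y = .data$NMDS2))
  if (!is.null(metadata)) {
    p <- p + geom_point(aes(colour = .data[[colour]], shape = .data[[shape]]))
  } else {
    p <- p + geom_point()
  }
  p + labs(caption = sprintf("stress = %.3f", object$stress)) + theme_minimal()
}

#' Plot per-sample F:B ratios by diet and period
#'
#' @param fb tibble from [fb_ratio()].
#' @return a ggplot (log-scaled boxplots).
#' @export
plot_fb <- function(fb) {
  ggplot(fb, aes(x = .data$treatment, y = .data$ratio,
                 fill = .data$period)) +
    geom_boxplot() +
    scale_y_log10() +
    labs(x = "diet", y = "Firmicutes:Bacteroidetes ratio", fill = "period") +
    theme_minimal()
}

#' Histogram of bootstrap p-values per model term
#'
#' @param object a `wb_fb_boot`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.wb_fb_boot <- function(object, ...) {
  ggplot(object$replicate_terms, aes(x = .data$p_value)) +
    geom_histogram(bins = 30, boundary = 0) +
    facet_wrap(~term) +
    labs(x = "bootstrap p-value", y = "replicates") +
    theme_minimal()
}

#' Plot rarefaction curves
#'
#' @param curves tibble from [rarefaction_curves()].
#' @return a ggplot.
#' @export
plot_rarefaction <- function(curves) {
  ggplot(curves, aes(x = .data$depth, y = .data$mean,
                     group = .data$unit, colour = .data$unit)) +
    geom_line(show.legend = nrow(curves) < 200) +
    labs(x = if (all(curves$mode == "sample")) "number of samples" else "reads",
         y = "observed taxa") +
    theme_minimal()
}

#' Stacked relative-abundance bars per treatment and timepoint
#'
#' @param rel tibble from [relative_abundance()].
#' @return a ggplot.
#' @export
plot_relative_abundance <- function(rel) {
  ggplot(rel, aes(x = .data$timepoint, y = .data$proportion,
                  fill = .data$taxon)) +
    geom_col() +
    facet_wrap(~treatment) +
    labs(x = "timepoint", y = "relative abundance") +
    theme_minimal()
}
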