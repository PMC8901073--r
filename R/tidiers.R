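#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a repeated-measures fit
#'
#' @param x a `wb_rmfit`.
#' @param ... unused.
#' @return the per-term ANOVA tibble: `term`, `df`, `ddf`, `statistic`
#'   (sequential F), `p_value`.
#' @export
tidy.wb_rmfit <- function(x, ...) {
  x$terms
}

#' @rdname tidy.wb_rmfit
#' @export
glance.wb_rmfit <- function(x, ...) {
  tibble(
    sigma2_pig = x$sigma2_pig, sigma2_e = x$sigma2_e, rho = x$rho,
    n = x$n, n_pigs = x$n_pigs, rank = x$rank, ddf = x$ddf,
    converged = x$converged, boundary = x$boundary,
    reml_criterion = x$reml_criterion
  )
}

#' Tidy the F:B bootstrap
#'
#' @param x a `wb_fb_boot`.
#' @param ... unused.
#' @return `tidy()`: the three-term table with observed and bootstrap-median
#'   statistics (`term`, `statistic`, `p_value`, `statistic_bstr`,
#'   `p_value_bstr`); `glance()`: one row of bookkeeping.
#' @export
tidy.wb_fb_boot <- function(x, ...) {
  x$term_summary
}

#' @rdname tidy.wb_fb_boot
#' @export
glance.wb_fb_boot <- function(x, ...) {
  tibble(n_boot = x$n_boot, resample = x$resample, n_redrawn = x$n_redrawn,
         seed = x$seed)
}

#' Tidy a PERMANOVA result
#'
#' @param x a `wb_permanova`.
#' @param ... unused.
#' @return one-row tibble `pseudo_F`, `R2`, `df_between`, `df_within`,
#'   `p_value`, `n_perm`.
#' @export
tidy.wb_permanova <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' Tidy an NMDS ordination
#'
#' @param x a `wb_nmds`.
#' @param ... unused.
#' @return `tidy()`: the coordinate tibble; `glance()`: stress and
#'   convergence.
#' @export
tidy.wb_nmds <- function(x, ...) {
  x$points
}

#' @rdname tidy.wb_nmds
#' @export
glance.wb_nmds <- function(x, ...) {
  tibble(stress = x$stress, converged = x$converged,
         k = ncol(x$points) - 1L, n = nrow(x$points))
}
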