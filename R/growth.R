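#' Average daily gain
#'
#' `(bw_end - bw_start) / days`. In the study design the pre-weaning span is
#' 26 days (day 1 to 26) and the post-weaning span 32 days (day 26 to 58).
#'
#' @param bw_start,bw_end body weights (kg).
#' @param days length of the period, > 0.
#' @return gain in kg/day.
#' @export
adg <- function(bw_start, bw_end, days) {
  if (any(days <= 0)) abort("days must be positive.")
  (bw_end - bw_start) / days
}

#' Classical one-way ANOVA
#'
#' F with `(k - 1, n - k)` degrees of freedom and the F survival-function
#' p-value; applied alike to continuous traits and to 0/1 mortality
#' indicators. When both the between- and within-group variation are zero,
#' F is defined as 0 with p = 1. `method = "chisq"` offers a chi-squared
#' test of independence for 0/1 indicators instead.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param method `"anova"` (default) or `"chisq"`.
#' @return tibble `statistic`, `df1`, `df2`, `p_value`.
#' @export
oneway_anova <- function(values, groups, method = c("anova", "chisq")) {
  method <- match.arg(method)
  keep <- !is.na(values)
  values <- values[keep]
  g <- droplevels(factor(groups[keep]))
  if (nlevels(g) < 2) abort("Need at least 2 groups with values.")
  if (method == "chisq") {
    tab <- table(g, values)
    ct <- suppressWarnings(stats::chisq.test(tab))
    return(tibble(statistic = unname(ct$statistic), df1 = unname(ct$parameter),
                  df2 = NA_integer_, p_value = ct$p.value))
  }
  n <- length(values)
  k <- nlevels(g)
  if (n - k < 1) abort("Need at least one group with 2+ values.")
  if (var(values) <= 1e-20 * (abs(mean(values)) + 1)^2) {
    # no variation at all: zero between and within
    return(tibble(statistic = 0, df1 = k - 1L, df2 = n - k, p_value = 1))
  }
  fit <- aov(values ~ g)
  tab <- summary(fit)[[1]]
  Fv <- tab$`F value`[1]
  pv <- tab$`Pr(>F)`[1]
  if (!is.finite(Fv)) {  # zero within-group variance
    between <- tab$`Sum Sq`[1]
    Fv <- if (between <= 1e-24) 0 else Inf
    pv <- if (Fv == 0) 1 else 0
  }
  tibble(statistic = Fv, df1 = k - 1L, df2 = n - k, p_value = pv)
}

#' Group-level growth and mortality summary
#'
#' Per group: N, mean body weight at each day over the animals alive (and
#' weighed) then, the mean per-animal ADG over each period, and the pre- and
#' post-weaning mortality as deaths over the *initial* group size; plus
#' one-way ANOVA p-values per column (mortality tested on the per-animal 0/1
#' indicators). With a single group the p-value rows are omitted.
#'
#' @param records growth tibble (see [read_growth_table()]).
#' @param days_pre,days_post period lengths for the ADG denominators.
#' @return list with `summary` (per-group tibble) and `p_values` (one row
#'   per tested column, `NULL` for a single group).
#' @export
group_summary <- function(records, days_pre = 26L, days_post = 32L) {
  g <- validate_growth(records)
  g$adg_pre <- adg(g$bw_d1, g$bw_d26, days_pre)
  g$adg_post <- adg(g$bw_d26, g$bw_d58, days_post)
  g$died_pre <- as.numeric(!g$alive_pre)
  g$died_post <- as.numeric(g$alive_pre & !g$alive_post)
  summ <- g |>
    group_by(group = .data$group) |>
    summarise(
      n = dplyr::n(),
      bw_d1 = mean(.data$bw_d1, na.rm = TRUE),
      bw_d26 = mean(.data$bw_d26, na.rm = TRUE),
      bw_d58 = mean(.data$bw_d58, na.rm = TRUE),
      adg_pre = mean(.data$adg_pre, na.rm = TRUE),
      adg_post = mean(.data$adg_post, na.rm = TRUE),
      mortality_pre = mean(.data$died_pre),
      mortality_post = mean(.data$died_post),
      .groups = "drop"
    )
  p_values <- NULL
  if (length(unique(g$group)) >= 2) {
    cols <- c("bw_d1", "bw_d26", "bw_d58", "adg_pre", "adg_post",
              "died_pre", "died_post")
    labels <- c("bw_d1", "bw_d26", "bw_d58", "adg_pre", "adg_post",
                "mortality_pre", "mortality_post")
    p_values <- purrr::map2_dfr(cols, labels, function(cc, lab) {
      v <- g[[cc]]
      if (sum(!is.na(v)) < 3 || length(unique(g$group[!is.na(v)])) < 2) {
        return(tibble(column = lab, statistic = NA_real_, p_value = NA_real_))
      }
      a <- oneway_anova(v, g$group)
      tibble(column = lab, statistic = a$statistic, p_value = a$p_value)
    })
  }
  list(summary = summ, p_values = p_values)
}
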