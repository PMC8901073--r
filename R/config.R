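#' Pipeline configuration
#'
#' Bundles every tunable constant of the pipeline, with defaults matching the
#' study protocol the package implements: Phred quality threshold 19 with at
#' most 3 consecutive low-quality calls and a minimum retained fraction of
#' 0.75 for read QC; OTU filter total >= 10 in >= 2 samples; CSS at the
#' median of positive counts scaled to 1000; 90% core prevalence; 999
#' PERMANOVA permutations; 1000 bootstrap replicates; alpha = 0.05. All
#' randomness derives from the single `seed` via named substreams, so stages
#' can be reordered without changing each other's draws.
#'
#' @param seed integer root seed.
#' @param quality_threshold Phred score at or below which a base call is
#'   low-quality.
#' @param max_bad_run maximum allowed run of consecutive low-quality calls.
#' @param min_fraction minimum retained fraction of a read after truncation.
#' @param min_total,min_samples OTU filter: minimum total count and minimum
#'   number of samples with a nonzero count.
#' @param css_quantile quantile of positive counts defining the CSS scaling
#'   factor.
#' @param scale_constant multiplier applied after CSS division.
#' @param core_prevalence prevalence threshold for core-taxon membership.
#' @param n_permutations PERMANOVA permutations.
#' @param n_bootstrap bootstrap replicates for the F:B analysis.
#' @param significance_alpha significance cut-off for per-OTU tests.
#' @param output_dir directory for [run_pipeline()] outputs.
#' @return a `wb_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            quality_threshold = 19L,
                            max_bad_run = 3L,
                            min_fraction = 0.75,
                            min_total = 10L,
                            min_samples = 2L,
                            css_quantile = 0.5,
                            scale_constant = 1000,
                            core_prevalence = 0.9,
                            n_permutations = 999L,
                            n_bootstrap = 1000L,
                            significance_alpha = 0.05,
                            output_dir = "weanbiome-out") {
  cfg <- list(
    seed = seed,
    quality_threshold = quality_threshold,
    max_bad_run = max_bad_run,
    min_fraction = min_fraction,
    min_total = min_total,
    min_samples = min_samples,
    css_quantile = css_quantile,
    scale_constant = scale_constant,
    core_prevalence = core_prevalence,
    n_permutations = n_permutations,
    n_bootstrap = n_bootstrap,
    significance_alpha = significance_alpha,
    output_dir = output_dir
  )
  cfg <- validate_config(cfg)
  ints <- c("seed", "quality_threshold", "max_bad_run", "min_total",
            "min_samples", "n_permutations", "n_bootstrap")
  cfg[ints] <- lapply(cfg[ints], as.integer)
  validate_config(unclass(cfg))
}

validate_config <- function(cfg) {
  props <- c("min_fraction", "css_quantile", "core_prevalence",
             "significance_alpha")
  for (p in props) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort(sprintf("Config field '%s' must be a proportion in [0, 1].", p))
    }
  }
  counts <- c("quality_threshold", "max_bad_run", "min_total", "min_samples",
              "n_permutations", "n_bootstrap")
  for (p in counts) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 1 || cfg[[p]] != round(cfg[[p]])) {
      abort(sprintf("Config field '%s' must be a positive integer.", p))
    }
  }
  if (cfg$scale_constant <= 0) abort("scale_constant must be positive.")
  structure(cfg, class = "wb_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param cfg a `wb_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "wb_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
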