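#' Run the whole analysis pipeline
#'
#' Chains every stage on either real inputs (OTU table + metadata TSVs,
#' optionally FASTQ reads and a growth table) or on data simulated from
#' `sim`: read QC, OTU filtering, CSS normalization, core microbiome
#' extraction (pre/post weaning and their overlap), alpha diversity with
#' baseline adjustment, Bray-Curtis distances with NMDS and PERMANOVA
#' (treatment, period, and treatment-by-period groupings), per-taxon
#' differential-abundance tests, the F:B ratio with bootstrap inference, and
#' the growth summary. Per-stage TSV/JSON outputs and a YAML log recording
#' the seed and configuration are written under `config$output_dir`. All
#' randomness derives from `config$seed` through named per-stage substreams,
#' so identical config + seed gives identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param otu_path,metadata_path input TSVs (omit to simulate).
#' @param fastq_path optional FASTQ to quality-filter.
#' @param growth_path optional growth-table TSV (simulated runs generate
#'   one).
#' @param sim a [sim_params()] used when simulating.
#' @param otu_test_ranks taxonomic levels for the per-taxon tests.
#' @return invisibly, a list with the per-stage result objects and the
#'   vector of files written.
#' @export
run_pipeline <- function(config, otu_path = NULL, metadata_path = NULL,
                         fastq_path = NULL, growth_path = NULL,
                         sim = NULL,
                         otu_test_ranks = c("phylum", "genus")) {
  stopifnot(inherits(config, "wb_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name) {
    path <- file.path(out_dir, name)
    files <<- c(files, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  res <- list()

  # --- inputs -------------------------------------------------------------
  if (is.null(otu_path)) {
    sim <- sim %||% sim_params(seed = derive_seed(config$seed, "simulate"))
    stage("simulate", {
      design <- generate_design(sim)
      gen <- generate_otu_table(design, sim,
                                seed = derive_seed(config$seed, "simulate"))
      res$table <- gen$table
      res$truth <- gen$truth
      write_otu_table(gen$table, emit("otu_raw.tsv"), emit("metadata.tsv"))
      jsonlite::write_json(
        list(library_sizes = as.list(gen$truth$library_sizes),
             true_fb = gen$truth$true_fb$by_period),
        emit("truth.json"), auto_unbox = TRUE, digits = NA)
    })
  } else {
    stage("read", {
      res$table <- read_otu_table(otu_path, metadata_path)
    })
  }

  # --- read QC ------------------------------------------------------------
  if (!is.null(fastq_path)) {
    stage("qc", {
      reads <- read_fastq(fastq_path)
      qc <- filter_reads(reads,
                         threshold = config$quality_threshold,
                         max_bad_run = config$max_bad_run,
                         min_fraction = config$min_fraction)
      res$qc_stats <- qc$stats
      write_fastq(qc$kept, emit("reads_kept.fastq"))
      jsonlite::write_json(as.list(qc$stats), emit("qc_stats.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }

  # --- filter + normalize ---------------------------------------------------
  stage("filter", {
    res$filtered <- filter_otus(res$table, config$min_total, config$min_samples)
    write_otu_table(res$filtered, emit("otu_filtered.tsv"))
  })
  stage("normalize", {
    res$normalized <- css_normalize(res$filtered, config$css_quantile,
                                     config$scale_constant)
    write_otu_table(res$normalized, emit("otu_css.tsv"))
  })

  # --- core microbiome ------------------------------------------------------
  stage("core", {
    pre <- core_taxa(res$filtered, "pre",
                     prevalence_threshold = config$core_prevalence)
    post <- core_taxa(res$filtered, "post",
                      prevalence_threshold = config$core_prevalence)
    cmp <- compare_cores(pre, post)
    res$core <- list(pre = pre, post = post, overlap = cmp)
    readr::write_tsv(as_tibble(as.data.frame(pre)), emit("core_pre.tsv"),
                     progress = FALSE)
    readr::write_tsv(as_tibble(as.data.frame(post)), emit("core_post.tsv"),
                     progress = FALSE)
    jsonlite::write_json(cmp[c("n_pre", "n_post", "n_shared")],
                         emit("core_overlap.json"), auto_unbox = TRUE)
  })

  # --- alpha diversity ------------------------------------------------------
  stage("diversity", {
    alpha <- alpha_diversity(res$filtered, normalized = res$normalized)
    md <- sample_meta(res$filtered)
    adj <- baseline_adjust(alpha, md)
    res$alpha <- alpha
    res$alpha_adjusted <- adj
    readr::write_tsv(alpha, emit("alpha.tsv"), progress = FALSE)
    readr::write_tsv(alpha_summary(alpha, md), emit("alpha_summary.tsv"),
                     progress = FALSE)
    readr::write_tsv(adj, emit("alpha_adjusted.tsv"), progress = FALSE)
  })

  # --- beta diversity -------------------------------------------------------
  stage("betadiv", {
    d <- bray_curtis(res$normalized)
    md <- sample_meta(res$normalized)
    ord <- nmds(d, seed = derive_seed(config$seed, "nmds"))
    groupings <- list(
      treatment = md$treatment,
      period = md$period,
      treatment_by_period = interaction(md$treatment, md$period)
    )
    perma <- purrr::imap(groupings, function(gr, nm) {
      tidy(permanova(d, gr, n_perm = config$n_permutations,
                     seed = derive_seed(config$seed, paste0("permanova_", nm))))
    })
    res$bray <- d
    res$nmds <- ord
    res$permanova <- bind_rows(perma, .id = "grouping")
    dm <- as.matrix(d)
    readr::write_tsv(as_tibble(dm, rownames = "sample"),
                     emit("bray_curtis.tsv"), progress = FALSE)
    readr::write_tsv(ord$points, emit("nmds.tsv"), progress = FALSE)
    jsonlite::write_json(res$permanova, emit("permanova.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  # --- per-taxon tests ------------------------------------------------------
  stage("fit", {
    res$otu_tests <- per_otu_tests(res$normalized,
                                    alpha = config$significance_alpha,
                                    ranks = otu_test_ranks)
    readr::write_tsv(res$otu_tests, emit("per_otu_tests.tsv"), progress = FALSE)
  })

  # --- F:B ratio + bootstrap ------------------------------------------------
  stage("fb", {
    fb <- fb_ratio(res$normalized)
    boot <- bootstrap_fb(res$normalized, n_boot = config$n_bootstrap,
                         seed = derive_seed(config$seed, "bootstrap"))
    res$fb <- fb
    res$fb_boot <- boot
    readr::write_tsv(fb, emit("fb.tsv"), progress = FALSE)
    readr::write_tsv(boot$cell_summary, emit("fb_cells.tsv"), progress = FALSE)
    readr::write_tsv(boot$term_summary, emit("fb_terms.tsv"), progress = FALSE)
  })

  # --- growth ---------------------------------------------------------------
  growth <- NULL
  if (!is.null(growth_path)) {
    growth <- stage("growth_read", read_growth_table(growth_path))
  } else if (is.null(otu_path)) {
    growth <- stage("growth_simulate", {
      generate_growth_table(seed = derive_seed(config$seed, "growth"))
    })
  }
  if (!is.null(growth)) {
    stage("growth", {
      gs <- group_summary(growth)
      res$growth <- gs
      readr::write_tsv(gs$summary, emit("growth_summary.tsv"), progress = FALSE)
      if (!is.null(gs$p_values)) {
        readr::write_tsv(gs$p_values, emit("growth_pvalues.tsv"), progress = FALSE)
      }
    })
  }

  # --- log ------------------------------------------------------------------
  yaml::write_yaml(list(seed = config$seed, config = unclass(config),
                        files = basename(files)),
                   emit("run_log.yaml"))
  res$files <- files
  invisible(res)
}
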