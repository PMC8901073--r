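#' Simulation parameters for the synthetic study generator
#'
#' Defaults reproduce the design of the longitudinal feeding study the
#' package implements: 17 pigs split 5/6/6 over the white / traditional /
#' oil diets, sampled at four timepoints (days 1, 12, 26, 58; weaning at day
#' 26), i.e. 68 samples. Counts follow a logistic-normal-multinomial model:
#' per-taxon latent log-abundance = baseline + treatment effect + timepoint
#' effect + pig random effect + stationary AR(1) Gaussian noise across the
#' pig's timepoints; each sample's counts are multinomial with the softmax
#' composition and a log-normal library size.
#'
#' The default taxon panel is the built-in [core_reference()] collapsed to
#' its 46 distinct lineages, with baselines `log(avg_count)` — a realistic
#' rank-abundance shape. Default effects emulate the study's headline
#' patterns: Firmicutes up ~1.85-fold after weaning, and up ~1.5-fold
#' (traditional) / ~1.85-fold (oil) relative to the white diet, so the
#' Firmicutes:Bacteroidetes ratio carries both a weaning and a diet signal.
#' The study reports no variance components, so `sigma_pig` (0.4), `sigma_e`
#' (0.7) and `rho` (0.5) are the package's own choices of realistic
#' within-pig heterogeneity and temporal persistence (log scale).
#'
#' @param n_pigs total number of pigs.
#' @param group_sizes named integer vector of pigs per treatment; must sum
#'   to `n_pigs`.
#' @param timepoints named integer vector: timepoint label -> day of age.
#' @param taxa tibble with `taxon_id`, the rank columns and `baseline_log`;
#'   default [sim_taxa_panel()].
#' @param sigma_pig SD of the per-(pig, taxon) random effect (log scale).
#' @param sigma_e marginal SD of the AR(1) noise (log scale).
#' @param rho lag-1 autocorrelation across consecutive timepoints, |rho| < 1.
#' @param treatment_effects,timepoint_effects numeric matrices (taxa x
#'   treatments / taxa x timepoints) of log-fold effects; `NULL` uses the
#'   defaults above.
#' @param library_size_meanlog,library_size_sdlog log-normal library-size
#'   parameters (default ~85,000 reads/sample, matching post-QC depth).
#' @param read_length generated read length (bases) for [generate_reads()].
#' @param seed root seed used when the `generate_*` functions are not given
#'   one explicitly.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_pigs = 17L,
                       group_sizes = c(white = 5L, traditional = 6L, oil = 6L),
                       timepoints = wb_timepoints(),
                       taxa = sim_taxa_panel(),
                       sigma_pig = 0.4,
                       sigma_e = 0.7,
                       rho = 0.5,
                       treatment_effects = NULL,
                       timepoint_effects = NULL,
                       library_size_meanlog = log(85000),
                       library_size_sdlog = 0.35,
                       read_length = 300L,
                       seed = 1L) {
  if (sum(group_sizes) != n_pigs) {
    abort("group_sizes must sum to n_pigs.")
  }
  if (abs(rho) >= 1) abort("|rho| must be < 1.")
  if (sigma_pig < 0 || sigma_e < 0) abort("Variance parameters must be >= 0.")
  if (!all(is.finite(taxa$baseline_log))) abort("Baseline log-abundances must be finite.")
  firm <- taxa$phylum == "Firmicutes"
  if (is.null(treatment_effects)) {
    treatment_effects <- matrix(0, nrow(taxa), length(group_sizes),
                                dimnames = list(taxa$taxon_id, names(group_sizes)))
    if ("traditional" %in% colnames(treatment_effects)) {
      treatment_effects[firm, "traditional"] <- log(1.5)
    }
    if ("oil" %in% colnames(treatment_effects)) {
      treatment_effects[firm, "oil"] <- log(1.85)
    }
  }
  if (is.null(timepoint_effects)) {
    timepoint_effects <- matrix(0, nrow(taxa), length(timepoints),
                                dimnames = list(taxa$taxon_id, names(timepoints)))
    post <- names(timepoints)[timepoint_period(names(timepoints)) == "post"]
    timepoint_effects[firm, post] <- log(1.85)
  }
  structure(list(
    n_pigs = as.integer(n_pigs), group_sizes = group_sizes,
    timepoints = timepoints, taxa = taxa,
    sigma_pig = sigma_pig, sigma_e = sigma_e, rho = rho,
    treatment_effects = treatment_effects,
    timepoint_effects = timepoint_effects,
    library_size_meanlog = library_size_meanlog,
    library_size_sdlog = library_size_sdlog,
    read_length = as.integer(read_length),
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @rdname sim_params
#' @export
sim_taxa_panel <- function() {
  panel <- core_reference() |>
    group_by(across(all_of(wb_ranks()))) |>
    summarise(baseline_log = log(mean(.data$avg_count)), .groups = "drop") |>
    arrange(desc(.data$baseline_log))
  panel$taxon_id <- sprintf("OTU%03d", seq_len(nrow(panel)))
  panel[, c("taxon_id", wb_ranks(), "baseline_log")]
}

#' Generate the longitudinal sampling design
#'
#' One sample per pig x timepoint, pigs nested in exactly one treatment
#' group; the default parameters give the study design of 68 samples from 17
#' pigs (20/24/24 samples in the white/traditional/oil groups).
#'
#' @param params a [sim_params()] object.
#' @return a [sample_metadata()] tibble.
#' @export
generate_design <- function(params = sim_params()) {
  groups <- rep(names(params$group_sizes), params$group_sizes)
  pigs <- sprintf("pig%02d", seq_len(params$n_pigs))
  tps <- names(params$timepoints)
  sample_metadata(tibble(
    sample = paste(rep(pigs, each = length(tps)), rep(tps, params$n_pigs), sep = "_"),
    pig = rep(pigs, each = length(tps)),
    treatment = rep(groups, each = length(tps)),
    timepoint = rep(tps, params$n_pigs)
  ))
}

#' Generate a synthetic OTU table with known ground truth
#'
#' Draws counts from the logistic-normal-multinomial model described in
#' [sim_params()] and records every latent quantity in a truth list, so that
#' downstream estimators (CSS, diversity, the repeated-measures model, the
#' F:B bootstrap) can be checked against known values.
#'
#' @param design metadata from [generate_design()].
#' @param params a [sim_params()] object.
#' @param seed integer; defaults to `params$seed`.
#' @return list with `table` (a raw `otu_tbl`) and `truth`: `library_sizes`
#'   (named, equal to the table's column sums), `pig_effects` (taxa x pigs),
#'   `latent` (taxa x samples log-abundances), the effect matrices, and
#'   `true_fb` (per treatment x timepoint and per treatment x period
#'   population F:B ratio of the latent composition).
#' @export
generate_otu_table <- function(design, params = sim_params(), seed = NULL) {
  seed <- seed %||% params$seed
  taxa <- params$taxa
  n_taxa <- nrow(taxa)
  tps <- names(params$timepoints)
  pigs <- unique(design$pig)
  withr::with_seed(seed, {
    pig_eff <- matrix(rnorm(n_taxa * length(pigs), 0, params$sigma_pig),
                      n_taxa, length(pigs), dimnames = list(taxa$taxon_id, pigs))
    # stationary AR(1) per (taxon, pig) across the ordered timepoints
    eps <- array(0, c(n_taxa, length(pigs), length(tps)))
    eps[, , 1] <- rnorm(n_taxa * length(pigs), 0, params$sigma_e)
    if (length(tps) > 1) {
      innov_sd <- params$sigma_e * sqrt(1 - params$rho^2)
      for (t in 2:length(tps)) {
        eps[, , t] <- params$rho * eps[, , t - 1] +
          rnorm(n_taxa * length(pigs), 0, innov_sd)
      }
    }
    latent <- matrix(NA_real_, n_taxa, nrow(design),
                     dimnames = list(taxa$taxon_id, design$sample))
    for (s in seq_len(nrow(design))) {
      p_i <- match(design$pig[s], pigs)
      t_i <- match(as.character(design$timepoint[s]), tps)
      latent[, s] <- taxa$baseline_log +
        params$treatment_effects[, as.character(design$treatment[s])] +
        params$timepoint_effects[, t_i] +
        pig_eff[, p_i] + eps[, p_i, t_i]
    }
    if (!all(is.finite(latent))) {
      bad <- rownames(latent)[which(!is.finite(latent), arr.ind = TRUE)[1, 1]]
      abort(sprintf("Non-finite latent abundance for taxon '%s'.", bad))
    }
    lib <- round(rlnorm(nrow(design), params$library_size_meanlog,
                        params$library_size_sdlog))
    lib <- pmax(lib, n_taxa)  # guard against empty samples
    counts <- matrix(0, n_taxa, nrow(design),
                     dimnames = list(taxa$taxon_id, design$sample))
    for (s in seq_len(nrow(design))) {
      w <- exp(latent[, s] - max(latent[, s]))
      counts[, s] <- rmultinom(1, lib[s], w / sum(w))
    }
  })
  tab <- otu_table(counts, taxa[, c("taxon_id", wb_ranks())], design)
  truth <- list(
    library_sizes = setNames(as.numeric(lib), design$sample),
    pig_effects = pig_eff,
    latent = latent,
    treatment_effects = params$treatment_effects,
    timepoint_effects = params$timepoint_effects,
    sigma_pig = params$sigma_pig, sigma_e = params$sigma_e, rho = params$rho,
    true_fb = true_fb_table(params)
  )
  list(table = tab, truth = truth)
}

#' Population F:B ratio of a simulation configuration
#'
#' The ground-truth Firmicutes:Bacteroidetes ratio per treatment x
#' timepoint (and per treatment x period) cell implied by a [sim_params()]
#' configuration. Two definitions are recorded: `fb_composition`, the ratio
#' of the latent-median composition (Firmicutes sum over Bacteroidetes sum
#' of `exp(mu)`), and `fb`, the population *median* of the per-sample ratio
#' of sums of lognormal abundances — the estimand that the observed
#' per-cell median F:B targets (the ratio of sums is skewed upward by
#' denominator noise, so the two differ unless `sigma_pig = sigma_e = 0`).
#' The median is evaluated by a fixed-seed Monte-Carlo integral,
#' independent of the user's RNG stream. A uniform log-fold effect on all
#' Firmicutes taxa multiplies both definitions exactly.
#'
#' @param params a [sim_params()] object.
#' @param n_mc Monte-Carlo draws per cell for the median.
#' @return list of tibbles `by_timepoint` and `by_period` with columns
#'   `treatment`, (`timepoint`,) `period`, `fb`, `fb_composition`.
#' @export
true_fb_table <- function(params, n_mc = 40000L) {
  taxa <- params$taxa
  firm <- taxa$phylum == "Firmicutes"
  bact <- taxa$phylum == "Bacteroidetes"
  sig <- sqrt(params$sigma_pig^2 + params$sigma_e^2)
  cells <- expand.grid(treatment = colnames(params$treatment_effects),
                       timepoint = names(params$timepoints),
                       stringsAsFactors = FALSE)
  mu_cell <- lapply(seq_len(nrow(cells)), function(i) {
    taxa$baseline_log +
      params$treatment_effects[, cells$treatment[i]] +
      params$timepoint_effects[, cells$timepoint[i]]
  })
  cells$fb_composition <- vapply(mu_cell, function(mu) {
    sum(exp(mu)[firm]) / sum(exp(mu)[bact])
  }, 0)
  ratios <- withr::with_seed(20260922L, {
    z <- matrix(rnorm(n_mc * nrow(taxa), 0, sig), nrow(taxa), n_mc)
    lapply(mu_cell, function(mu) {
      w <- exp(mu + z)
      colSums(w[firm, , drop = FALSE]) / colSums(w[bact, , drop = FALSE])
    })
  })
  cells$fb <- vapply(ratios, median, 0)
  cells$period <- timepoint_period(cells$timepoint)
  out <- as_tibble(cells)[, c("treatment", "timepoint", "period",
                              "fb", "fb_composition")]
  per_period <- distinct(out[, c("treatment", "period")])
  per_period$fb <- NA_real_
  per_period$fb_composition <- NA_real_
  for (i in seq_len(nrow(per_period))) {
    idx <- which(cells$treatment == per_period$treatment[i] &
                   cells$period == per_period$period[i])
    per_period$fb[i] <- median(unlist(ratios[idx], use.names = FALSE))
    per_period$fb_composition[i] <- mean(cells$fb_composition[idx])
  }
  list(by_timepoint = out, by_period = per_period)
}

#' Generate FASTQ reads with a known QC-violation mix
#'
#' Builds reads whose fate under [filter_reads()] is unambiguous, for testing
#' the QC rules: `clean` (all Q40), `long_run` (a disqualifying low-quality
#' run at the start: retained fraction 0), `low_fraction` (a disqualifying
#' run after 60% of the read: retained fraction 0.6 < 0.75), and
#' `contains_n` (a single mid-read `N`, quality otherwise perfect).
#'
#' @param n_reads number of reads.
#' @param params a [sim_params()] object (supplies `read_length`, `seed`).
#' @param violation_mix named proportions over
#'   `c("clean", "long_run", "low_fraction", "contains_n")`; must sum to 1.
#' @param seed integer; defaults to `params$seed`.
#' @return list with `reads` (tibble `id`, `sequence`, `quality`) and
#'   `manifest` (tibble `id`, `class`).
#' @export
generate_reads <- function(n_reads, params = sim_params(),
                           violation_mix = c(clean = 1), seed = NULL) {
  seed <- seed %||% params$seed
  classes <- c("clean", "long_run", "low_fraction", "contains_n")
  mix <- setNames(rep(0, 4), classes)
  bad <- setdiff(names(violation_mix), classes)
  if (length(bad) > 0) abort(paste0("Unknown read class: ", bad[1]))
  mix[names(violation_mix)] <- violation_mix
  if (abs(sum(mix) - 1) > 1e-8) abort("violation_mix proportions must sum to 1.")
  n_per <- diff(c(0, round(cumsum(mix) * n_reads)))
  cls <- rep(classes, n_per)
  L <- params$read_length
  run_len <- 4L  # one more than the default max_bad_run of 3
  hi <- strrep(rawToChar(as.raw(40 + 33)), L)
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_reads), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
    order_idx <- sample.int(n_reads)
  })
  cls <- cls[order_idx]
  quals <- rep(hi, n_reads)
  lowq <- rawToChar(as.raw(10 + 33))
  for (i in seq_len(n_reads)) {
    if (cls[i] == "long_run") {
      substr(quals[i], 1L, run_len) <- strrep(lowq, run_len)
    } else if (cls[i] == "low_fraction") {
      s <- floor(0.6 * L) + 1L
      substr(quals[i], s, s + run_len - 1L) <- strrep(lowq, run_len)
    } else if (cls[i] == "contains_n") {
      mid <- L %/% 2L
      substr(seqs[i], mid, mid) <- "N"
      substr(quals[i], mid, mid) <- rawToChar(as.raw(2 + 33))
    }
  }
  ids <- sprintf("read%05d", seq_len(n_reads))
  list(
    reads = tibble(id = ids, sequence = seqs, quality = quals),
    manifest = tibble(id = ids, class = cls)
  )
}

#' Generate a synthetic per-piglet growth table
#'
#' Per-piglet body weights Gaussian around the group means (violations of
#' monotone growth are resampled), with Bernoulli deaths; piglets dying
#' before weaning lack the later weights, piglets dying after weaning lack
#' the final weight. Post-weaning mortality probabilities are interpreted as
#' proportions of the initial group, so the conditional death probability
#' among weaning survivors is adjusted accordingly.
#'
#' @param group_means tibble with `group`, `bw_d1`, `bw_d26`, `bw_d58`
#'   (kg); defaults to the full-cohort [growth_reference()] means.
#' @param sd common SD (kg) of individual weights around the group mean.
#' @param mortality_probs tibble with `group`, `pre`, `post` death
#'   probabilities (proportions of initial N); default 0.
#' @param n_per_group named integer vector of piglets per group.
#' @param seed integer seed.
#' @return a growth tibble (see [read_growth_table()]).
#' @export
generate_growth_table <- function(group_means = NULL, sd = 0.5,
                                  mortality_probs = NULL,
                                  n_per_group = c(white = 57L, traditional = 68L, oil = 72L),
                                  seed = 1L) {
  if (is.null(group_means)) {
    gr <- growth_reference()
    gr <- gr[gr$cohort == "all", ]
    group_means <- gr[, c("group", "bw_d1", "bw_d26", "bw_d58")]
  }
  if (any(as.matrix(group_means[, -1]) <= 0)) abort("Group mean weights must be positive.")
  if (sd < 0) abort("sd must be >= 0.")
  if (is.null(mortality_probs)) {
    mortality_probs <- tibble(group = group_means$group, pre = 0, post = 0)
  }
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(group_means$group, function(g) {
      n <- n_per_group[[g]]
      mu <- unlist(group_means[group_means$group == g, c("bw_d1", "bw_d26", "bw_d58")])
      mp <- mortality_probs[mortality_probs$group == g, ]
      bw <- t(vapply(seq_len(n), function(i) {
        for (try in 1:200) {
          w <- rnorm(3, mu, sd)
          if (all(w > 0) && all(diff(w) >= 0)) return(w)
        }
        sort(abs(rnorm(3, mu, sd)))
      }, numeric(3)))
      dead_pre <- rbinom(n, 1, mp$pre) == 1
      p_post_cond <- if (mp$pre >= 1) 0 else min(1, mp$post / (1 - mp$pre))
      dead_post <- !dead_pre & rbinom(n, 1, p_post_cond) == 1
      tibble(
        pig = sprintf("%s%03d", substr(g, 1, 2), seq_len(n)),
        group = g,
        bw_d1 = bw[, 1],
        bw_d26 = ifelse(dead_pre, NA_real_, bw[, 2]),
        bw_d58 = ifelse(dead_pre | dead_post, NA_real_, bw[, 3]),
        alive_pre = !dead_pre,
        alive_post = !dead_pre & !dead_post
      )
    })
  })
  validate_growth(rows)
}
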