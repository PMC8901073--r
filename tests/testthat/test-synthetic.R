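test_that("default design reproduces the study layout", {
  d <- generate_design(sim_params())
  expect_equal(nrow(d), 68L)
  expect_equal(length(unique(d$pig)), 17L)
  expect_equal(as.vector(table(d$treatment)), c(20L, 24L, 24L))
  expect_equal(anyDuplicated(d[, c("pig", "timepoint")]), 0L)
  # each pig sits in exactly one treatment
  expect_true(all(tapply(d$treatment, d$pig, function(x) length(unique(x))) == 1))
})

test_that("degenerate designs work and inconsistent group sizes error", {
  p1 <- sim_params(n_pigs = 1L, group_sizes = c(white = 1L))
  d1 <- generate_design(p1)
  expect_equal(nrow(d1), 4L)
  expect_equal(length(unique(d1$pig)), 1L)
  expect_error(sim_params(n_pigs = 10L, group_sizes = c(white = 3L, oil = 3L)),
               "sum to n_pigs")
  expect_error(sim_params(rho = 1), "rho")
})

test_that("count generation is deterministic for a fixed seed", {
  p <- null_sim_params(n_taxa = 40, seed = 2)
  d <- generate_design(p)
  g1 <- generate_otu_table(d, p, seed = 11)
  g2 <- generate_otu_table(d, p, seed = 11)
  expect_identical(otu_counts(g1$table), otu_counts(g2$table))
  g3 <- generate_otu_table(d, p, seed = 12)
  expect_false(identical(otu_counts(g1$table), otu_counts(g3$table)))
})

test_that("noise-free compositions converge to the softmax of the baselines", {
  p <- null_sim_params(n_taxa = 30, seed = 3, sigma_pig = 0, sigma_e = 0,
                       library_size_meanlog = log(2e5), library_size_sdlog = 0)
  d <- generate_design(sim_params(n_pigs = 2L, group_sizes = c(white = 2L)))
  gen <- generate_otu_table(d, p, seed = 21)
  m <- otu_counts(gen$table)
  p0 <- exp(p$taxa$baseline_log) / sum(exp(p$taxa$baseline_log))
  for (j in seq_len(ncol(m))) {
    n_j <- sum(m[, j])
    se <- sqrt(p0 * (1 - p0) / n_j)
    # 4.5 SE: ~240 taxon-by-sample comparisons, so a 3 SE bound would fail
    # by chance alone
    expect_true(all(abs(m[, j] / n_j - p0) <= 4.5 * se + 1e-9))
  }
})

test_that("a +log(2) treatment effect doubles that taxon's mean abundance", {
  n_taxa <- 30
  lin <- fixture_lineages(n_taxa, seed = 5)
  lin$phylum[5] <- "Firmicutes"
  lin$baseline_log <- rep(4, n_taxa)
  ztr <- matrix(0, n_taxa, 2, dimnames = list(lin$taxon_id, c("white", "oil")))
  ztr[5, "oil"] <- log(2)
  ztp <- matrix(0, n_taxa, 4, dimnames = list(lin$taxon_id, paste0("T", 0:3)))
  p <- sim_params(n_pigs = 200L, group_sizes = c(white = 100L, oil = 100L),
                  taxa = lin, treatment_effects = ztr, timepoint_effects = ztp,
                  sigma_pig = 0.2, sigma_e = 0.3,
                  library_size_meanlog = log(5e4), library_size_sdlog = 0.1)
  gen <- generate_otu_table(generate_design(p), p, seed = 31)
  m <- otu_counts(gen$table)
  md <- sample_meta(gen$table)
  ratio <- mean(m[5, md$treatment == "oil"]) / mean(m[5, md$treatment == "white"])
  expect_gt(ratio, 2 * 0.9)
  expect_lt(ratio, 2 * 1.1)
})

test_that("latent AR(1) residuals reproduce rho, and decorrelate when rho = 0", {
  for (rho in c(0.5, 0)) {
    p <- null_sim_params(n_taxa = 8, seed = 6, rho = rho, sigma_pig = 0)
    p$n_pigs <- 500L
    p$group_sizes <- c(white = 500L)
    d <- generate_design(p)
    gen <- generate_otu_table(d, p, seed = 41 + rho * 10)
    # strip the fixed part and the pig effect: what is left is the AR(1) noise
    md <- sample_meta(gen$table)
    eps <- gen$truth$latent -
      matrix(p$taxa$baseline_log, nrow(p$taxa), nrow(md)) -
      gen$truth$pig_effects[, md$pig]
    tp <- as.character(md$timepoint)
    lag_cor <- cor(
      as.vector(eps[, tp %in% c("T0", "T1", "T2")]),
      as.vector(eps[, tp %in% c("T1", "T2", "T3")])
    )
    expect_lt(abs(lag_cor - rho), 0.05)
  }
})

test_that("read generator mixes are honoured exactly by the QC filter", {
  p <- sim_params(read_length = 100L)
  gr <- generate_reads(400, p, violation_mix = c(clean = 1), seed = 1)
  res <- filter_reads(gr$reads)
  expect_equal(res$stats$retention_rate, 1)

  gr_n <- generate_reads(400, p, violation_mix = c(contains_n = 1), seed = 2)
  res_n <- filter_reads(gr_n$reads)
  expect_equal(res_n$stats$retention_rate, 0)
  expect_equal(res_n$stats$n_contains_n, 400L)

  expect_error(generate_reads(10, p, violation_mix = c(clean = 0.5)), "sum to 1")
  expect_error(generate_reads(10, p, violation_mix = c(clean = 0.5, junk = 0.5)),
               "Unknown read class")
})

test_that("growth generator reproduces its inputs in the noise-free limit", {
  means <- tibble::tibble(group = c("white", "oil"),
                          bw_d1 = c(1.3, 1.4), bw_d26 = c(6, 7),
                          bw_d58 = c(20, 21))
  g <- generate_growth_table(means, sd = 0,
                             n_per_group = c(white = 4L, oil = 4L), seed = 1)
  gs <- group_summary(g)
  ord <- match(gs$summary$group, means$group)
  expect_equal(gs$summary$bw_d1, means$bw_d1[ord])
  expect_equal(gs$summary$bw_d26, means$bw_d26[ord])
  expect_equal(gs$summary$bw_d58, means$bw_d58[ord])
  expect_equal(gs$summary$mortality_pre, c(0, 0))

  # full pre-weaning mortality leaves no later weights
  mort <- tibble::tibble(group = c("white", "oil"), pre = c(1, 1), post = c(0, 0))
  g2 <- generate_growth_table(means, sd = 0, mortality_probs = mort,
                              n_per_group = c(white = 4L, oil = 4L), seed = 2)
  expect_true(all(is.na(g2$bw_d26)))
  expect_true(all(is.na(g2$bw_d58)))
})

test_that("growth generator means satisfy a CLT bound at large n", {
  means <- growth_reference()[growth_reference()$cohort == "all",
                              c("group", "bw_d1", "bw_d26", "bw_d58")]
  # sd small relative to the day-1 mean weight, so the positivity and
  # monotonicity constraints leave the Gaussian means untouched
  sd_kg <- 0.25
  n <- 4000L
  g <- generate_growth_table(means, sd = sd_kg,
                             n_per_group = c(white = n, traditional = n, oil = n),
                             seed = 7)
  gs <- group_summary(g)$summary
  se <- sd_kg / sqrt(n)
  for (col in c("bw_d1", "bw_d26", "bw_d58")) {
    expect_true(all(abs(gs[[col]] - means[[col]][match(gs$group, means$group)])
                    <= 3.5 * se))
  }
})
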