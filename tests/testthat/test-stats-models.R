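test_that("with no random effect and no correlation the fit is exactly OLS", {
  d <- simulate_rm_data(n_pigs = 9, rho = 0, sigma2_pig = 0, seed = 31)
  fit <- fit_repeated_model(d, y ~ treatment + timepoint,
                            correlation = "none", random_pig = FALSE)
  ref <- anova(lm(y ~ treatment + timepoint, d))
  expect_equal(fit$terms$statistic, ref$`F value`[1:2], tolerance = 1e-8)
  expect_equal(fit$terms$p_value, ref$`Pr(>F)`[1:2], tolerance = 1e-8)
  expect_equal(unname(fit$coefficients),
               unname(coef(lm(y ~ treatment + timepoint, d))),
               tolerance = 1e-10)
  expect_equal(fit$sigma2_e, summary(lm(y ~ treatment + timepoint, d))$sigma^2,
               tolerance = 1e-10)
})

test_that("a constant response gives zero F statistics and p = 1", {
  d <- simulate_rm_data(n_pigs = 6, rho = 0.4, sigma2_pig = 0.5, seed = 32)
  d$y <- 3.7
  fit <- fit_repeated_model(d, y ~ treatment + timepoint)
  expect_true(all(fit$terms$statistic == 0))
  expect_true(all(fit$terms$p_value == 1))
})

test_that("estimates agree with nlme::lme on the same model", {
  skip_if_not_installed("nlme")
  d <- simulate_rm_data(n_pigs = 40, rho = 0.5, sigma2_pig = 0.8,
                        treat_effects = c(a = 0, b = 0.4, c = 0.8),
                        tp_effects = c(0, 0.2, 0.4, 0.6), seed = 33)
  fit <- fit_repeated_model(d, y ~ treatment + timepoint)
  d$tindex <- as.integer(d$timepoint)
  ref <- nlme::lme(y ~ treatment + timepoint, random = ~1 | pig,
                   correlation = nlme::corAR1(form = ~tindex | pig), data = d)
  vc <- as.numeric(nlme::VarCorr(ref)[, 1])
  expect_equal(fit$sigma2_pig, vc[1], tolerance = 0.02)
  expect_equal(fit$sigma2_e, vc[2], tolerance = 0.02)
  rho_ref <- as.numeric(coef(ref$modelStruct$corStruct, unconstrained = FALSE))
  expect_equal(fit$rho, rho_ref, tolerance = 0.02)
  expect_equal(unname(fit$coefficients), unname(nlme::fixef(ref)),
               tolerance = 1e-3)
})

test_that("the returned optimum beats 50 random admissible parameter points", {
  d <- simulate_rm_data(n_pigs = 15, rho = 0.3, sigma2_pig = 0.6, seed = 34)
  fit <- fit_repeated_model(d, y ~ treatment + timepoint)
  at_opt <- fit$reml_criterion
  withr::with_seed(35, {
    rand <- replicate(50, {
      fit$crit_fn(exp(runif(1, -8, 4)), runif(1, -0.95, 0.95))
    })
  })
  expect_true(all(rand >= at_opt - 1e-6))
})

test_that("with independent data the F test tracks one-way ANOVA on average", {
  fs <- t(vapply(1:200, function(s) {
    d <- simulate_rm_data(n_pigs = 30, rho = 0, sigma2_pig = 0, seed = 400 + s)
    fit <- fit_repeated_model(d, y ~ treatment)
    c(fit$terms$statistic[1], anova(lm(y ~ treatment, d))$`F value`[1])
  }, numeric(2)))
  expect_equal(mean(fs[, 1]) / mean(fs[, 2]), 1, tolerance = 0.02)
})

test_that("variance parameters are recovered on synthetic data", {
  est <- vapply(1:25, function(s) {
    d <- simulate_rm_data(n_pigs = 200, rho = 0.5, sigma2_pig = 1,
                          treat_effects = c(a = 0, b = 0.3, c = 0.1),
                          tp_effects = c(0, 0.2, 0.1, 0.3), seed = 500 + s)
    fit <- fit_repeated_model(d, y ~ treatment + timepoint)
    c(fit$sigma2_pig, fit$rho)
  }, numeric(2))
  expect_equal(mean(est[1, ]), 1, tolerance = 0.1)
  expect_equal(mean(est[2, ]), 0.5, tolerance = 0.1)
})

test_that("per-taxon tests flag a strong effect and honour alpha = 0", {
  n_taxa <- 25
  lin <- fixture_lineages(n_taxa, seed = 41)
  lin$baseline_log <- rep(4.5, n_taxa)
  ztr <- matrix(0, n_taxa, 2, dimnames = list(lin$taxon_id, c("white", "oil")))
  ztr[7, "oil"] <- log(4)
  ztp <- matrix(0, n_taxa, 4, dimnames = list(lin$taxon_id, paste0("T", 0:3)))
  p <- sim_params(n_pigs = 50L, group_sizes = c(white = 25L, oil = 25L),
                  taxa = lin, treatment_effects = ztr, timepoint_effects = ztp,
                  sigma_pig = 0.3, sigma_e = 0.5)
  hits <- vapply(1:10, function(s) {
    gen <- generate_otu_table(generate_design(p), p, seed = 600 + s)
    norm <- css_normalize(filter_otus(gen$table))
    res <- suppressMessages(per_otu_tests(norm, ranks = "otu"))
    res$significant[res$taxon_id == lin$taxon_id[7]]
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  gen <- generate_otu_table(generate_design(p), p, seed = 611)
  norm <- css_normalize(filter_otus(gen$table))
  res0 <- suppressMessages(per_otu_tests(norm, alpha = 0, ranks = "phylum"))
  expect_equal(sum(res0$significant), 0L)
})

test_that("the F:B ratio follows its definition and flags undefined samples", {
  lin <- fixture_lineages(4, seed = 42)
  lin$phylum <- c("Firmicutes", "Firmicutes", "Bacteroidetes", "Proteobacteria")
  md <- fixture_metadata(n_pigs = 1)[1:2, ]
  m <- matrix(c(20, 10, 10, 5,
                6, 6, 12, 1), 4, 2,
              dimnames = list(lin$taxon_id, md$sample))
  fb <- fb_ratio(otu_table(m, lin, md))
  expect_equal(fb$ratio, c(3, 1))

  m2 <- m; m2[3, 2] <- 0
  expect_warning(fb2 <- fb_ratio(otu_table(m2, lin, md)), "zero Bacteroidetes")
  expect_equal(nrow(fb2), 1L)
})

test_that("observed cell medians track the generator's true F:B", {
  p <- null_sim_params(n_taxa = 40, seed = 43, sigma_pig = 0.3, sigma_e = 0.5)
  p$n_pigs <- 120L
  p$group_sizes <- c(white = 120L)
  truth <- generate_otu_table(generate_design(p), p, seed = 71)
  norm <- css_normalize(filter_otus(truth$table))
  cells <- fb_cell_summary(fb_ratio(norm))
  tf <- truth$truth$true_fb$by_period
  for (i in seq_len(nrow(cells))) {
    want <- tf$fb[tf$treatment == as.character(cells$treatment[i]) &
                    tf$period == as.character(cells$period[i])]
    expect_equal(cells$median_fb[i], want, tolerance = 0.1)
  }
})

test_that("the F:B model reproduces the three-term layout and null behaviour", {
  # constant ratios: all F = 0
  md <- generate_design(sim_params())
  fb0 <- tibble::tibble(md[, c("sample", "pig", "treatment", "timepoint",
                               "period")], ratio = 2)
  fit0 <- fb_model(fb0)
  expect_equal(fit0$terms$term,
               c("timepoint", "treatment", "timepoint:treatment"))
  expect_true(all(fit0$terms$statistic == 0))

  # a pure period effect is detected; the interaction stays null
  detections <- vapply(1:20, function(s) {
    d <- simulate_rm_data(n_pigs = 100, rho = 0.3, sigma2_pig = 0.3,
                          tp_effects = c(0, 0, 0.6, 0.6), seed = 700 + s)
    fb <- tibble::tibble(
      sample = paste0(d$pig, "_", d$timepoint), pig = d$pig,
      treatment = factor(d$treatment, levels = c("a", "b", "c")),
      timepoint = d$timepoint, period = timepoint_period(d$timepoint),
      ratio = d$y
    )
    fit <- fb_model(fb)
    c(tp = fit$terms$p_value[1] < 0.05, int = fit$terms$p_value[3])
  }, numeric(2))
  expect_gte(mean(detections["tp", ]), 0.9)
  expect_gt(mean(detections["int", ]), 0.2)  # null interaction p not collapsed
})

test_that("bootstrap with the identity resample reproduces the plain fit", {
  p <- null_sim_params(n_taxa = 30, seed = 44)
  gen <- generate_otu_table(generate_design(p), p, seed = 81)
  norm <- css_normalize(filter_otus(gen$table))
  fb <- fb_ratio(norm)
  bi <- bootstrap_fb(norm, n_boot = 1, seed = 1,
                     .indices = list(seq_len(nrow(fb))))
  expect_equal(bi$term_summary$statistic_bstr, bi$term_summary$statistic,
               tolerance = 1e-3)
  expect_equal(bi$term_summary$p_value_bstr, bi$term_summary$p_value,
               tolerance = 1e-3)
  # identity resample leaves each cell's median untouched
  expect_equal(bi$cell_summary$q1_bstr, bi$cell_summary$median_fb)
  expect_equal(bi$cell_summary$q3_bstr, bi$cell_summary$median_fb)
})

test_that("bootstrap summaries keep their contracts", {
  p <- null_sim_params(n_taxa = 30, seed = 45)
  gen <- generate_otu_table(generate_design(p), p, seed = 91)
  norm <- css_normalize(filter_otus(gen$table))
  bt <- suppressWarnings(bootstrap_fb(norm, n_boot = 40, seed = 6))
  expect_equal(nrow(bt$replicate_terms), 40L * 3L)
  expect_equal(max(bt$replicate_terms$replicate), 40L)
  cs <- bt$cell_summary
  expect_true(all(cs$q1_bstr <= cs$q3_bstr))
  # determinism
  bt2 <- suppressWarnings(bootstrap_fb(norm, n_boot = 40, seed = 6))
  expect_equal(bt$term_summary, bt2$term_summary)
  # pig-level resampling also runs and keeps the design estimable
  btp <- suppressWarnings(bootstrap_fb(norm, n_boot = 10, seed = 7,
                                       resample = "pig"))
  expect_equal(nrow(btp$replicate_terms), 30L)
})

test_that("under a null the bootstrap p-value medians are not collapsed", {
  p <- null_sim_params(n_taxa = 30, seed = 46)
  med_p <- vapply(1:8, function(s) {
    gen <- generate_otu_table(generate_design(p), p, seed = 900 + s)
    norm <- css_normalize(filter_otus(gen$table))
    bt <- suppressWarnings(bootstrap_fb(norm, n_boot = 60, seed = s))
    bt$term_summary$p_value_bstr[bt$term_summary$term == "treatment"]
  }, 0)
  # across null datasets the bootstrap medians should spread like the
  # observed p values, centred well away from 0
  expect_gt(median(med_p), 0.1)
  expect_lt(median(med_p), 0.95)
})
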