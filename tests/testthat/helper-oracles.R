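# Independent brute-force oracles and small fixture builders. Every oracle
# is written as a direct transcription of the defining formula, deliberately
# ignoring how the package computes the same quantity.

oracle_max_run <- function(q, thr) {
  best <- 0L
  run <- 0L
  for (v in q) {
    run <- if (v <= thr) run + 1L else 0L
    best <- max(best, run)
  }
  best
}

# position-by-position truncation scan (vs the package's rle-based one)
oracle_truncation <- function(q, thr, max_bad) {
  run <- 0L
  for (i in seq_along(q)) {
    if (q[i] <= thr) {
      run <- run + 1L
      if (run > max_bad) return(i - run)
    } else {
      run <- 0L
    }
  }
  length(q)
}

oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log2(p))
}

oracle_simpson <- function(x) {
  p <- x[x > 0] / sum(x)
  1 - sum(p^2)
}

oracle_chao1 <- function(x) {
  x <- x[x > 0]
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  length(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_ace <- function(x, cutoff = 10) {
  x <- x[x > 0]
  rare <- x[x <= cutoff]
  s_abund <- sum(x > cutoff)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  ks <- vapply(1:cutoff, function(k) k * (k - 1) * sum(rare == k), 0)
  gamma2 <- max(s_rare / c_ace * sum(ks) / (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

oracle_fisher_alpha <- function(x) {
  x <- x[x > 0]
  S <- length(x)
  N <- sum(x)
  stats::uniroot(function(a) a * log(1 + N / a) - S,
                 c(1e-8, 1e8), tol = 1e-10)$root
}

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# naive double-loop PERMANOVA pseudo-F
oracle_pseudo_f <- function(D, groups) {
  n <- nrow(D)
  f <- factor(groups)
  k <- nlevels(f)
  ss_t <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + D[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (lev in levels(f)) {
    idx <- which(f == lev)
    ng <- length(idx)
    if (ng < 2) next
    acc <- 0
    for (a in seq_len(ng - 1)) for (b in (a + 1):ng) {
      acc <- acc + D[idx[a], idx[b]]^2
    }
    ss_w <- ss_w + acc / ng
  }
  ((ss_t - ss_w) / (k - 1)) / (ss_w / (n - k))
}

oracle_filter_keep <- function(m, min_total, min_samples) {
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    keep[i] <- sum(m[i, ]) >= min_total && sum(m[i, ] > 0) >= min_samples
  }
  keep
}

# ---- fixture builders -----------------------------------------------------

fixture_lineages <- function(n_taxa, seed = 1) {
  withr::with_seed(seed, {
    phyla <- sample(c("Firmicutes", "Bacteroidetes", "Proteobacteria",
                      "Actinobacteria"), n_taxa, replace = TRUE)
    tibble::tibble(
      taxon_id = sprintf("OTU%04d", seq_len(n_taxa)),
      domain = "Bacteria",
      phylum = phyla,
      class = paste0("c_", phyla),
      order = paste0("o_", phyla),
      family = sprintf("fam%02d", seq_len(n_taxa) %% 17),
      genus = sprintf("gen%04d", seq_len(n_taxa))
    )
  })
}

fixture_metadata <- function(n_pigs = 4, timepoints = paste0("T", 0:3),
                             treatments = c("white", "traditional", "oil")) {
  pigs <- sprintf("pig%02d", seq_len(n_pigs))
  tr <- rep_len(treatments, n_pigs)
  tibble::tibble(
    sample = paste(rep(pigs, each = length(timepoints)),
                   rep(timepoints, n_pigs), sep = "_"),
    pig = rep(pigs, each = length(timepoints)),
    treatment = rep(tr, each = length(timepoints)),
    timepoint = rep(timepoints, n_pigs)
  )
}

fixture_table <- function(n_taxa = 30, n_pigs = 4, seed = 1, lambda = 20) {
  md <- fixture_metadata(n_pigs)
  lin <- fixture_lineages(n_taxa, seed = seed)
  counts <- withr::with_seed(seed, {
    matrix(stats::rpois(n_taxa * nrow(md), lambda), n_taxa, nrow(md),
           dimnames = list(lin$taxon_id, md$sample))
  })
  counts[1, ] <- pmax(counts[1, ], 1)  # no all-zero samples
  otu_table(counts, lin, md)
}

# zero-effect sim_params over an arbitrary synthetic panel
null_sim_params <- function(n_taxa = 100, seed = 1, ...) {
  lin <- fixture_lineages(n_taxa, seed = seed)
  lin$baseline_log <- withr::with_seed(seed + 1, stats::rnorm(n_taxa, 4, 1.5))
  ztr <- matrix(0, n_taxa, 3,
                dimnames = list(lin$taxon_id, c("white", "traditional", "oil")))
  ztp <- matrix(0, n_taxa, 4, dimnames = list(lin$taxon_id, paste0("T", 0:3)))
  sim_params(taxa = lin, treatment_effects = ztr, timepoint_effects = ztp,
             seed = seed, ...)
}

# direct Gaussian draw from the repeated-measures model (no OTU layer)
simulate_rm_data <- function(n_pigs, rho, sigma2_pig, sigma2_e = 1,
                             treat_effects = c(a = 0, b = 0, c = 0),
                             tp_effects = c(0, 0, 0, 0), seed = 1) {
  withr::with_seed(seed, {
    tps <- 4
    pig <- rep(sprintf("p%03d", seq_len(n_pigs)), each = tps)
    tp <- factor(rep(paste0("T", 0:3), n_pigs))
    tr <- rep(rep(names(treat_effects), length.out = n_pigs), each = tps)
    u <- rep(stats::rnorm(n_pigs, 0, sqrt(sigma2_pig)), each = tps)
    e <- as.vector(vapply(seq_len(n_pigs), function(i) {
      x <- numeric(tps)
      x[1] <- stats::rnorm(1)
      for (t in 2:tps) x[t] <- rho * x[t - 1] + stats::rnorm(1, 0, sqrt(1 - rho^2))
      x
    }, numeric(tps)))
    y <- 1 + treat_effects[tr] + tp_effects[as.integer(tp)] + u +
      sqrt(sigma2_e) * e
    data.frame(y = unname(y), treatment = tr, timepoint = tp, pig = pig)
  })
}
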