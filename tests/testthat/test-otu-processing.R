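make_table <- function(counts) {
  n_taxa <- nrow(counts)
  md <- fixture_metadata(n_pigs = ceiling(ncol(counts) / 4))[seq_len(ncol(counts)), ]
  colnames(counts) <- md$sample
  lin <- fixture_lineages(n_taxa, seed = 3)
  rownames(counts) <- lin$taxon_id
  otu_table(counts, lin, md)
}

test_that("the OTU filter applies total >= 10 AND presence >= 2, idempotently", {
  counts <- rbind(
    c(9, 0, 0, 0),    # total 9: removed
    c(5, 5, 0, 0),    # total 10, 2 samples: kept
    c(10, 0, 0, 0),   # total 10 but 1 sample: removed
    c(3, 3, 3, 3),    # kept
    c(1, 1, 1, 1),    # total 4: removed
    c(2, 8, 0, 0)     # kept
  )
  tab <- make_table(counts)
  f <- filter_otus(tab)
  expect_equal(sort(f$taxon_id), sort(tab$taxon_id[c(2, 4, 6)]))
  expect_equal(sample_meta(f), sample_meta(tab))
  # idempotent
  expect_equal(otu_counts(filter_otus(f)), otu_counts(f))
  # everything removed is an error
  expect_error(filter_otus(tab, min_total = 1000), "review")
})

test_that("the OTU filter matches a brute-force predicate on a random table", {
  tab <- fixture_table(n_taxa = 500, n_pigs = 6, seed = 11, lambda = 2)
  m <- otu_counts(tab)
  keep <- oracle_filter_keep(m, 10, 2)
  f <- filter_otus(tab)
  expect_setequal(f$taxon_id, rownames(m)[keep])
})

test_that("CSS normalization reproduces hand-evaluated examples", {
  tab <- make_table(rbind(c(10, 1), c(10, 2), c(10, 3), c(10, 4), c(10, 100)))
  norm <- css_normalize(tab)
  m <- otu_counts(norm)
  # sample 1: q = 10, s = 50 -> all 200
  expect_equal(unname(m[, 1]), rep(200, 5))
  # sample 2: q = 3 (type-1 median of 1..4,100), s = 1+2+3 = 6
  expect_equal(unname(m[, 2]),
               c(1, 2, 3, 4, 100) / 6 * 1000, tolerance = 1e-12)
  expect_equal(unname(attr(norm, "scaling_factors")), c(50, 6))
})

test_that("CSS is scale-invariant and preserves within-sample rank order", {
  counts <- withr::with_seed(5, matrix(rpois(40, 8) + 1, 10, 4))
  counts[, 2] <- counts[, 1] * 2  # proportional columns
  tab <- make_table(counts)
  norm <- otu_counts(css_normalize(tab))
  expect_equal(norm[, 1], norm[, 2], ignore_attr = TRUE)
  for (j in 1:4) {
    expect_equal(order(norm[, j]), order(counts[, j]))
  }
})

test_that("taxonomic aggregation sums lineage groups and conserves totals", {
  lin <- fixture_lineages(4, seed = 2)
  lin$genus <- c("g1", "g1", "g2", "g3")
  lin$family <- c("f1", "f1", "f1", "f2")
  lin$phylum <- c("P1", "P1", "P1", "P2")
  lin$class <- c("c1", "c1", "c1", "c2")
  lin$order <- c("o1", "o1", "o1", "o2")
  md <- fixture_metadata(n_pigs = 1)
  counts <- matrix(1:16, 4, 4, dimnames = list(lin$taxon_id, md$sample))
  tab <- otu_table(counts, lin, md)
  g <- aggregate_taxonomy(tab, "genus")
  expect_equal(nrow(g), 3L)
  expect_equal(unname(colSums(otu_counts(g))), unname(colSums(counts)))
  merged <- otu_counts(g)[paste("Bacteria", "P1", "c1", "o1", "f1", "g1", sep = ";"), ]
  expect_equal(unname(merged), unname(counts[1, ] + counts[2, ]))
})

test_that("the reference panel aggregates to exactly the five expected phyla", {
  panel <- sim_taxa_panel()
  md <- fixture_metadata(n_pigs = 1)
  counts <- matrix(1L, nrow(panel), 4,
                   dimnames = list(panel$taxon_id, md$sample))
  tab <- otu_table(counts, panel[, c("taxon_id", wb_ranks())], md)
  ph <- aggregate_taxonomy(tab, "phylum")
  expect_setequal(otu_lineages(ph)$phylum,
                  c("Firmicutes", "Bacteroidetes", "Proteobacteria",
                    "Actinobacteria", "Fusobacteria"))
})

test_that("relative abundance pools rare taxa and sums to one per cell", {
  tab <- make_table(rbind(c(30, 5), c(70, 5), c(0, 990)))
  rel <- relative_abundance(tab, min_rel = 0)
  one <- rel[rel$timepoint == "T0", ]
  expect_equal(one$proportion[match(tab$taxon_id[1:2], one$taxon)], c(0.3, 0.7))
  expect_false("other" %in% rel$taxon)
  sums <- tapply(rel$proportion, list(rel$treatment, rel$timepoint), sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))

  rel2 <- relative_abundance(tab, min_rel = 0.02)
  expect_true("other" %in% rel2$taxon)
  sums2 <- tapply(rel2$proportion, list(rel2$treatment, rel2$timepoint), sum)
  expect_true(all(abs(sums2[!is.na(sums2)] - 1) < 1e-12))
})

test_that("relative abundance equals brute-force column-normalised means", {
  tab <- fixture_table(n_taxa = 25, n_pigs = 4, seed = 8)
  rel <- relative_abundance(tab, min_rel = 0)
  m <- otu_counts(tab)
  props <- sweep(m, 2, colSums(m), "/")
  md <- sample_meta(tab)
  for (i in sample(nrow(rel), 20)) {
    cols <- md$sample[md$treatment == rel$treatment[i] &
                        md$timepoint == rel$timepoint[i]]
    expect_equal(rel$proportion[i], mean(props[rel$taxon[i], cols]))
  }
})

test_that("aggregation and relative abundance commute at a common rank", {
  tab <- fixture_table(n_taxa = 40, n_pigs = 3, seed = 10)
  direct <- relative_abundance(tab, rank = "phylum", min_rel = 0)
  via_genus <- relative_abundance(aggregate_taxonomy(tab, "genus"),
                                  rank = "phylum", min_rel = 0)
  direct$taxon <- sub(";.*", "", sub("^Bacteria;", "", direct$taxon))
  via_genus$taxon <- sub(";.*", "", sub("^Bacteria;", "", via_genus$taxon))
  expect_equal(dplyr::arrange(direct, treatment, timepoint, taxon),
               dplyr::arrange(via_genus, treatment, timepoint, taxon))
})

test_that("rarefaction curves hit the exact endpoints and increase monotonely", {
  tab <- fixture_table(n_taxa = 15, n_pigs = 2, seed = 12, lambda = 5)
  m <- otu_counts(tab)
  smp <- colnames(m)[1]
  full <- sum(m[, smp])
  cur <- rarefaction_curves(tab, depths = c(1, 5, 20, full), reps = 30, seed = 3)
  one <- cur[cur$unit == smp, ]
  expect_equal(one$mean[one$depth == 1], 1)
  expect_equal(one$mean[one$depth == full], sum(m[, smp] > 0))
  expect_true(all(diff(one$mean) >= 0))

  cs <- rarefaction_curves(tab, depths = 1:8, reps = 20, mode = "sample",
                           seed = 4)
  expect_true(all(diff(cs$mean) >= 0))
  expect_equal(cs$mean[cs$depth == 8], sum(rowSums(m > 0) > 0))
  expect_error(rarefaction_curves(tab, depths = 100, mode = "sample"),
               "number of samples")
})
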