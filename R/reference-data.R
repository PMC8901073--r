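#' Reference core-taxon panel of the piglet rectal microbiome
#'
#' Genus-level lineages observed in at least 90% of rectal-swab samples of a
#' longitudinal piglet study, before (`pre`, days 1-26) and after (`post`,
#' days 26-58) weaning, together with the average (normalized) count of each
#' taxon in its period. The panel spans 5 phyla (Firmicutes, Bacteroidetes,
#' Proteobacteria, Actinobacteria, Fusobacteria) and contains 10 pre-weaning
#' and 43 post-weaning entries (46 distinct lineages; 7 shared). `"uncultured"`
#' / `"uncultured bacterium"` are real taxonomic labels, not missing values.
#'
#' This panel doubles as the default taxon set of [generate_otu_table()]: the
#' log average counts give the generator a realistic rank-abundance shape.
#'
#' @param period `"pre"`, `"post"` or `"all"` (default): which rows to return.
#' @return tibble with columns `period`, `domain` .. `genus`, `avg_count`.
#' @export
core_reference <- function(period = c("all", "pre", "post")) {
  period <- match.arg(period)
  rows <- c(
    "pre|Bacteroidetes|Bacteroidia|Bacteroidales|Bacteroidaceae|Bacteroides|1701.22",
    "pre|Bacteroidetes|Bacteroidia|Bacteroidales|Prevotellaceae|Prevotella 9|379.38",
    "pre|Firmicutes|Bacilli|Lactobacillales|Lactobacillaceae|Lactobacillus|235.67",
    "pre|Firmicutes|Clostridia|Clostridiales|Clostridiaceae 1|Clostridium sensu stricto 1|12.26",
    "pre|Firmicutes|Erysipelotrichia|Erysipelotrichales|Erysipelotrichaceae|Solobacterium|279.41",
    "pre|Firmicutes|Negativicutes|Selenomonadales|Acidaminococcaceae|Phascolarctobacterium|716.12",
    "pre|Firmicutes|Negativicutes|Selenomonadales|Veillonellaceae|Veillonella|127.03",
    "pre|Fusobacteria|Fusobacteriia|Fusobacteriales|CFT112H7|uncultured bacterium|1607.82",
    "pre|Fusobacteria|Fusobacteriia|Fusobacteriales|Fusobacteriaceae|Fusobacterium|2221.41",
    "pre|Proteobacteria|Gammaproteobacteria|Enterobacteriales|Enterobacteriaceae|Escherichia-Shigella|6867.47",
    "post|Actinobacteria|Coriobacteriia|Coriobacteriales|Coriobacteriaceae|Collinsella|71.94",
    "post|Bacteroidetes|Bacteroidia|Bacteroidales|Bacteroidaceae|Bacteroides|394.49",
    "post|Bacteroidetes|Bacteroidia|Bacteroidales|Bacteroidales S24-7 group|uncultured bacterium|837.35",
    "post|Bacteroidetes|Bacteroidia|Bacteroidales|Prevotellaceae|Alloprevotella|345.68",
    "post|Bacteroidetes|Bacteroidia|Bacteroidales|Prevotellaceae|Prevotella 1|637.91",
    "post|Bacteroidetes|Bacteroidia|Bacteroidales|Prevotellaceae|Prevotella 2|559.63",
    "post|Bacteroidetes|Bacteroidia|Bacteroidales|Prevotellaceae|Prevotella 7|2034.15",
    "post|Bacteroidetes|Bacteroidia|Bacteroidales|Prevotellaceae|Prevotella 9|1844.45",
    "post|Bacteroidetes|Bacteroidia|Bacteroidales|Prevotellaceae|Prevotellaceae NK3B31 group|451.12",
    "post|Bacteroidetes|Bacteroidia|Bacteroidales|Prevotellaceae|Prevotellaceae UCG-001|484.29",
    "post|Bacteroidetes|Bacteroidia|Bacteroidales|Prevotellaceae|uncultured|778.53",
    "post|Bacteroidetes|Bacteroidia|Bacteroidales|Rikenellaceae|Rikenellaceae RC9 gut group|639.62",
    "post|Bacteroidetes|Bacteroidia|Bacteroidales|uncultured|uncultured bacterium|136.62",
    "post|Firmicutes|Bacilli|Lactobacillales|Lactobacillaceae|Lactobacillus|327.90",
    "post|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|[Ruminococcus] gauvreauii group|59.41",
    "post|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Blautia|74.71",
    "post|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Coprococcus 3|31.41",
    "post|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Dorea|128.53",
    "post|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Fusicatenibacter|98.26",
    "post|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Lachnoclostridium|63.80",
    "post|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Lachnospiraceae NK4A136 group|109.21",
    "post|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Lachnospiraceae UCG-004|670.65",
    "post|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Lachnospiraceae UCG-008|9.71",
    "post|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Pseudobutyrivibrio|447.88",
    "post|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|Roseburia|734.65",
    "post|Firmicutes|Clostridia|Clostridiales|Lachnospiraceae|uncultured|21.03",
    "post|Firmicutes|Clostridia|Clostridiales|Ruminococcaceae|[Eubacterium] coprostanoligenes group|509.50",
    "post|Firmicutes|Clostridia|Clostridiales|Ruminococcaceae|Faecalibacterium|588.15",
    "post|Firmicutes|Clostridia|Clostridiales|Ruminococcaceae|Ruminiclostridium 9|184.18",
    "post|Firmicutes|Clostridia|Clostridiales|Ruminococcaceae|Ruminococcaceae UCG-002|532.85",
    "post|Firmicutes|Clostridia|Clostridiales|Ruminococcaceae|Ruminococcaceae UCG-005|112.04",
    "post|Firmicutes|Clostridia|Clostridiales|Ruminococcaceae|Ruminococcaceae UCG-014|89.06",
    "post|Firmicutes|Clostridia|Clostridiales|Ruminococcaceae|Subdoligranulum|147.72",
    "post|Firmicutes|Clostridia|Clostridiales|Ruminococcaceae|uncultured|18.94",
    "post|Firmicutes|Erysipelotrichia|Erysipelotrichales|Erysipelotrichaceae|Catenibacterium|81.85",
    "post|Firmicutes|Erysipelotrichia|Erysipelotrichales|Erysipelotrichaceae|Solobacterium|2971.06",
    "post|Firmicutes|Negativicutes|Selenomonadales|Acidaminococcaceae|Acidaminococcus|555.88",
    "post|Firmicutes|Negativicutes|Selenomonadales|Acidaminococcaceae|Phascolarctobacterium|719.92",
    "post|Firmicutes|Negativicutes|Selenomonadales|Veillonellaceae|Anaerovibrio|1776.03",
    "post|Firmicutes|Negativicutes|Selenomonadales|Veillonellaceae|Megasphaera|740.88",
    "post|Fusobacteria|Fusobacteriia|Fusobacteriales|CFT112H7|uncultured bacterium|362.94",
    "post|Proteobacteria|Epsilonproteobacteria|Campylobacterales|Helicobacteraceae|Helicobacter|597.76",
    "post|Proteobacteria|Gammaproteobacteria|Enterobacteriales|Enterobacteriaceae|Escherichia-Shigella|943.12"
  )
  parts <- strsplit(rows, "|", fixed = TRUE)
  out <- tibble(
    period = vapply(parts, `[[`, "", 1),
    domain = "Bacteria",
    phylum = vapply(parts, `[[`, "", 2),
    class = vapply(parts, `[[`, "", 3),
    order = vapply(parts, `[[`, "", 4),
    family = vapply(parts, `[[`, "", 5),
    genus = vapply(parts, `[[`, "", 6),
    avg_count = as.numeric(vapply(parts, `[[`, "", 7))
  )
  if (period != "all") out <- out[out$period == period, ]
  out
}

#' Reference alpha-diversity summary across the weaning transition
#'
#' Mean alpha-diversity indices of piglet rectal samples by period (pre/post
#' weaning) and diet group (white = no supplementation, traditional = in-feed
#' antibiotics, oil = essential oils), as observed in the longitudinal study
#' the synthetic generator emulates, with p-values for the treatment and
#' weaning (pre vs post) contrasts from the baseline-adjusted repeated-measures
#' model. Shannon is in bits (log base 2) and equitability is Shannon evenness
#' H / log2(S); the `overall` cells are means over all samples of a period
#' (5/6/6 pigs in the white/traditional/oil groups).
#'
#' @return tibble with columns `index`, `period`, `group`
#'   (`overall`/`white`/`oil`/`traditional`), `value`, `p_treatment`,
#'   `p_weaning`.
#' @export
alpha_reference <- function() {
  idx <- c("chao1", "fisher_alpha", "observed_otus", "observed_species",
           "shannon", "simpson", "equitability", "simpson_e", "ACE")
  vals <- rbind(
    c(950.67, 1537.03, 876.37, 955.26, 1008.01, 1700.61, 1444.47, 1493.26),
    c(124.70, 198.60, 115.18, 118.00, 139.34, 216.74, 190.75, 191.34),
    c(717.44, 1181.94, 658.30, 721.92, 762.25, 1300.00, 1091.92, 1173.58),
    c(717.44, 1181.94, 658.30, 721.92, 762.25, 1300.00, 1091.92, 1173.58),
    c(5.02, 6.55, 4.36, 4.95, 5.63, 6.74, 6.53, 6.42),
    c(0.85, 0.97, 0.74, 0.87, 0.91, 0.97, 0.96, 0.97),
    c(0.53, 0.65, 0.47, 0.52, 0.59, 0.65, 0.65, 0.64),
    c(0.02, 0.03, 0.02, 0.02, 0.03, 0.04, 0.03, 0.04),
    c(1477.18, 2229.95, 1285.03, 1506.04, 1608.43, 2452.06, 2124.21, 2150.60)
  )
  p_treat <- c(0.3052217, 0.4259763, 0.5885714, 0.5885714, 0.0019982,
               0.0000131, 0.0012893, 0.4187639, 0.1367301)
  p_wean <- c(1.15e-10, 3.53e-10, 5.95e-10, 5.95e-10, 5.55e-09, 3.21e-07,
              6.08e-07, 3.51e-02, 3.08e-10)
  cells <- tibble(
    period = rep(c("pre", "post", "pre", "pre", "pre", "post", "post", "post"),
                 times = length(idx)),
    group = rep(c("overall", "overall", "white", "oil", "traditional",
                  "white", "oil", "traditional"), times = length(idx)),
    index = rep(idx, each = 8),
    value = as.vector(t(vals))
  )
  left_join(cells,
            tibble(index = idx, p_treatment = p_treat, p_weaning = p_wean),
            by = "index")[, c("index", "period", "group", "value",
                              "p_treatment", "p_weaning")]
}

#' Reference growth-performance summary
#'
#' Group-level body weight (kg, at days 1, 26 and 58), average daily gain
#' (kg/day) and mortality (proportion of the initial group, before and after
#' weaning) for the full cohort (`all`, 197 piglets) and the sequenced subset
#' (`sequenced`, 17 piglets) of the longitudinal study the package emulates.
#' The pre-weaning ADG spans 26 days (day 1 to 26) and the post-weaning ADG
#' 32 days (day 26 to 58).
#'
#' @return tibble with columns `cohort`, `group`, `n`, `bw_d1`, `bw_d26`,
#'   `bw_d58`, `adg_pre`, `adg_post`, `mortality_pre`, `mortality_post`.
#' @export
growth_reference <- function() {
  tibble(
    cohort = rep(c("all", "sequenced"), each = 3),
    group = rep(c("white", "traditional", "oil"), 2),
    n = c(57L, 68L, 72L, 5L, 6L, 6L),
    bw_d1 = c(1.279, 1.248, 1.240, 1.310, 1.342, 1.350),
    bw_d26 = c(6.907, 7.444, 6.944, 5.720, 7.392, 7.333),
    bw_d58 = c(19.992, 20.685, 20.699, 20.342, 20.966, 21.019),
    adg_pre = c(0.215, 0.240, 0.221, 0.170, 0.233, 0.230),
    adg_post = c(0.409, 0.412, 0.428, 0.457, 0.424, 0.428),
    mortality_pre = c(0.123, 0.074, 0.167, 0, 0, 0),
    mortality_post = c(0.018, 0.015, 0.014, 0, 0, 0)
  )
}
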