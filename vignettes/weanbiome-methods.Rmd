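---
title: "Methods and design choices in weanbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in weanbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

weanbiome implements a complete longitudinal 16S analysis for a piglet
feeding trial in which three post-weaning-diarrhea (PWD) prophylaxis diets —
an unsupplemented control ("white"), in-feed antibiotics ("traditional"),
and an essential-oil mix ("oil") — are compared on rectal-swab microbiomes
sampled at days 1, 12, 26 (weaning) and 58 from pigs nested in diet groups.
This vignette explains the statistical machinery, the defaults and why they
were chosen, and what the synthetic-data generator does and does not
emulate.

## The data model

The central object is the OTU table: a taxa-by-samples count matrix with a
six-rank lineage (`domain;phylum;class;order;family;genus`) per row and
per-sample metadata (pig, diet, timepoint, derived pre/post-weaning period)
attached. `"uncultured"` and `"unclassified"` are treated as real lineage
labels, never as missing values — published core-microbiome tables use them
as row identities. Tables are written and read as plain TSV; a transposed
table is detected (its row ids match metadata sample ids) and rejected
rather than silently flipped.

## Read quality control

Joined reads are filtered by three rules, with Phred 19 as the quality
threshold: a base call is low-quality when its score is `<= 19` (the QIIME
convention for a stated threshold of 19; the rule's "< 19"/"> 19" phrasing
leaves Q19 unassigned, and the toolchain this protocol derives from counts
it as low). The rules are:

1. truncate the read immediately before the first run of more than 3
   consecutive low-quality calls;
2. require the retained fraction of the read to be at least 0.75;
3. allow no uncalled `N` base in the retained portion.

Whether the original analysis truncated reads or merely tested the longest
high-quality stretch cannot be decided from the protocol text alone.
Truncation (`mode = "truncate"`) is the default because it matches the
QIIME 1.9 `split_libraries` semantics the protocol derives from; the
non-truncating
longest-stretch reading is implemented as `mode = "longest_run"` and unit
tested alongside. Failures are counted once, under the first failing rule,
so QC statistics partition the input exactly.

## OTU filtering and CSS normalization

The rare-OTU filter retains taxa with **total count >= 10 and a nonzero
count in >= 2 samples**. The source protocol states this rule in three
slightly different ways; this conjunction is the standard reading that all
three phrasings approximate, and both thresholds are configurable.

Cumulative sum scaling (CSS) divides each sample by the sum of its counts
at or below a chosen quantile of its positive counts, then multiplies by a
constant (default 1000). The quantile is fixed at the median (type-1, lower
empirical quantile of the *positive* counts; ties at the quantile are
included in the sum), which keeps the operation deterministic; the
reference method's adaptive quantile selection is intentionally out of
scope. CSS is scale-free per sample, so proportional samples normalize
identically and within-sample rank order is preserved.

## Core microbiome

Core membership is evaluated at genus rank on the rank-aggregated table:
a lineage is core for a period when it has a nonzero count in at least 90%
of that period's samples, with the pre core pooling all T0+T1 columns and
the post core all T2+T3 columns. The threshold comparison is
`presence >= 0.9 * n` with a `1e-9` guard so that floating-point noise in
the product can never flip a boundary case (9 of 10 samples passes).
Prevalence is computed on the filtered raw table by default — presence/
absence is unaffected by CSS, so the choice only matters for the reported
average counts. Core sets are compared on the full six-rank lineage, which
keeps the three distinct `uncultured` genera of different families apart.

## Alpha diversity

Richness estimators (bias-corrected Chao1 `S + F1(F1-1)/(2(F2+1))`, ACE
with rare-taxon cutoff 10, Fisher's alpha solving `S = a log(1 + N/a)`)
require integer frequencies-of-frequencies and are computed on the raw
filtered counts; Shannon, Simpson (`1 - sum p^2`), Pielou equitability and
Simpson evenness are computed on proportions from the CSS table. Shannon
uses **log base 2** and equitability is `H / log2(S)`: this convention is
verified against the published per-cell summary, where every one of the
eight cells satisfies `|equitability - shannon/log2(observed)| <= 0.02`
(means of ratios differ slightly from ratios of means, hence the band).
When a sample has no rare taxa (all abundances above the ACE cutoff) the
ACE correction is undefined (0/0) and the package falls back to observed
richness, the only value the estimator can justify there.

Baseline adjustment subtracts each diet group's mean day-1 value from the
group's whole series, per index, so groups start at exactly zero and
between-timepoint contrasts are untouched; it removes confounding from
individual variability at the first sampling day.

## Beta diversity

Bray-Curtis dissimilarities (`sum|x-y| / sum(x+y)`) feed NMDS (Kruskal
stress-1 via vegan's engine, seeded for reproducibility) and a one-way
PERMANOVA implemented from the defining sums of squared dissimilarities,
with `p = (#{F_perm >= F_obs} + 1)/(n_perm + 1)` over 999 label
permutations by default. Free permutation is the default — matching the
original analysis, which reports no repeated-measures restriction — and
`strata =` (for example, pig) restricts permutations within strata as the
statistically defensible alternative for longitudinal data; note that a
grouping constant within strata then becomes untestable by construction
(p = 1).

## The repeated-measures model

Diversity indices, per-taxon normalized counts and F:B ratios are analysed
with the Gaussian model

y = X beta + pig + e,

a random intercept per pig plus residuals that follow a stationary AR(1)
process across the pig's timepoints: `cor(e_s, e_t) = rho^|s-t|` on the
timepoint *order*. The unequal day spacing (1, 12, 26, 58) is deliberately
ignored — correlation decays per sampling step, as the model statement in
the source protocol implies. Variance parameters `(sigma2_pig, sigma2_e,
rho)` maximize the restricted likelihood; the profiled criterion
`(n-p) log RSS + log|V0| + log|X'V0^-1 X|` is optimized over
`(log(sigma2_pig/sigma2_e), atanh(rho))` with L-BFGS-B, and fixed effects
come from generalized least squares at the optimum. A pig-variance ratio
estimated at its lower bound (~0) is a common, benign outcome and is not
flagged; a correlation pinned near ±1 is.

Each fixed-effect term gets a sequential (type-I) F statistic computed on
the whitened data, in the order the formula states — timepoint, treatment,
interaction for the F:B model, mirroring the published three-row table.
The denominator degrees of freedom use the containment convention
`n_obs - n_pigs - rank(X) + 1`; no exact small-sample df exists for this
covariance, and the choice is documented rather than hidden. With the
random effect and the correlation disabled the fit collapses to ordinary
least squares *exactly*, which the tests assert to 1e-8, and the full model
agrees with an independent mixed-model implementation (nlme) to within 2%
on variance components.

Per-taxon differential-abundance tests fit `value ~ treatment + timepoint`
to every taxon at each requested rank and flag treatment p-values below
0.05 with **no multiple-testing correction**, as in the original analysis;
taxa all-zero in any treatment-by-timepoint cell are skipped and counted.

## F:B ratio and its bootstrap

The Firmicutes:Bacteroidetes ratio is the per-sample ratio of summed
normalized counts of the two phyla; samples with a zero Bacteroidetes sum
are excluded with a warning (the ratio is undefined there). Cell summaries
report medians per diet-by-period cell.

The bootstrap draws `n_boot` replicates (1000 by default) by resampling
samples with replacement **stratified within treatment-by-timepoint cells**,
so every replicate preserves the design's cell sizes, recomputes each
sample's F:B, and refits the interaction model. Two details deserve
explanation:

* *Pseudo-pigs.* If a pig's sample is drawn twice at the same timepoint,
  the AR(1) covariance of the naive design is singular (two rows at
  correlation 1). Drawn copies are therefore split into pseudo-pigs — copy
  k of a pig's samples forms pseudo-pig k, each holding at most one draw
  per timepoint — which keeps the covariance positive-definite while
  preserving the pig-level clustering of each copy. A pig-level cluster
  bootstrap (whole pigs redrawn within treatment) is available as
  `resample = "pig"`.
* *Which model is refitted.* The published account is internally ambiguous
  about whether replicates refit the main-effects or the interaction
  model, while its results table reports bootstrap values for all three
  terms; the interaction model is therefore the default and
  `interaction = FALSE` gives the main-effects refit.

Replicate refits warm-start at the observed fit's variance estimates with
a slightly looser optimizer tolerance; with the identity resample the
replicate reproduces the plain fit to ~1e-4 relative. Summaries are the
per-term medians of the replicate statistics and p-values and the per-cell
bootstrap quartiles (Q1/Q3) around the observed median F:B. Bootstrap
p-values are summarized by medians and kept unadjusted.

*Known limitation.* At study scale (17 pigs, 12 samples per diet-by-period
cell) the bootstrap distribution of a cell *median* is underdispersed: the
interquartile interval is roughly 60% as wide as the sampling distribution
of the median across datasets, because the median of a dozen clustered
(pig-correlated) draws concentrates on few order statistics and within-cell
resampling cannot see the between-pig variance component. The acceptance
suite measures the resulting interquartile coverage of the true cell value
(~30–40% rather than the nominal ~50%, for both resampling schemes); the
quartiles should therefore be read as a stability band around the observed
median, not as a calibrated 50% confidence interval.

## Growth and mortality

Average daily gain uses spans of 26 days (day 1–26) and 32 days (day
26–58); these divisors are derived, not stated — they are the only pair
that reproduces all six published sequenced-subset ADG cells from the
published body-weight means. The published whole-cohort "overall ADG"
column is *not* reproducible from any divisor of the printed means
(survivor composition changes between periods), so the package does not
emit an overall-ADG column. Mortality is deaths over the *initial* group
size for both periods, compared by one-way ANOVA on per-animal 0/1
indicators — this reproduces the published p-values (0.245 pre-weaning,
0.985 post-weaning) through the exact closed form
`p = (1 + 2F/d2)^(-d2/2)` for two numerator df; a chi-squared test is
available behind `method = "chisq"`. With zero between- and within-group
variation F is defined as 0 with p = 1.

## The synthetic-data generator

The generator exists so that every downstream stage is testable without
the study's raw sequences. It emulates the study design exactly: 17 pigs
split 5/6/6 across white/traditional/oil, four timepoints, 68 samples.
Counts follow a logistic-normal–multinomial model — per-taxon latent
log-abundance = baseline + treatment effect + timepoint effect +
per-(pig, taxon) random effect + stationary AR(1) noise, mapped through a
softmax to a composition and drawn multinomially at a log-normal library
size (~85,000 reads/sample, matching the study's post-QC depth). The
logistic-normal choice (rather than Dirichlet-multinomial) is deliberate:
pig effects and AR(1) correlation enter *additively on the log scale*,
exactly the structure the repeated-measures model assumes, which makes
parameter recovery well-posed.

The default taxon panel is the built-in reference core table collapsed to
its 46 distinct lineages with baselines `log(avg_count)` — a realistic
rank-abundance shape spanning five phyla. Default effects reproduce the
study's headline patterns: Firmicutes up 1.85-fold after weaning and up
1.5-/1.85-fold under the traditional/oil diets, so the F:B ratio carries
both signals with the published ordering (oil > traditional > white). The
study reports no variance components, so `sigma_pig = 0.4`, `sigma_e =
0.7` and `rho = 0.5` (log scale) are the package's own choices of
plausible within-pig heterogeneity and temporal persistence; they are
inputs of the simulation, not estimates of the study.

The recorded "true" cell-level F:B is the *population median* of the
per-sample ratio of sums of log-normal abundances, evaluated by a
fixed-seed Monte-Carlo integral (the plug-in composition ratio is recorded
alongside; a uniform log-fold effect on all Firmicutes taxa multiplies
both exactly). What the generator does **not** emulate: sequencing error
and chimeras, taxonomic mis-assignment, overdispersion beyond the
logistic-normal layer, varying pig availability (dropout), and any
phylogenetic signal. Passing tests therefore demonstrate correctness of
the estimators under the model's own assumptions, not robustness to every
artefact of real amplicon data.

Read generation is a separate, deliberately constructive fixture: reads
are built so their QC fate is unambiguous (clean / disqualifying run at
the start / run at 60% of the read / a single mid-read N), which lets
tests demand *exact* agreement between QC output and the generator
manifest.

## Reproducibility and problem sizes

All randomness flows from one root seed; every pipeline stage derives a
named substream, so stages can be reordered without changing each other's
draws, and two runs with the same config and seed produce byte-identical
outputs. The test suite and the acceptance script use scaled problem
sizes chosen to keep a full run comfortable on one CPU: 1000-case oracle
sweeps, 500 null simulations for each calibration check (PERMANOVA at 199
permutations; 500 null taxa pooled over five independent synthetic
studies), 200 synthetic datasets of 200 pigs for variance-parameter
recovery, and 100 study-scale datasets at 200 bootstrap replicates
(scaled down from the production default of 1000) for the interquartile
coverage measurement.
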