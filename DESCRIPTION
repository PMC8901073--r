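Package: weanbiome
Title: Longitudinal Analysis of the Piglet Gut Microbiome Across Weaning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for longitudinal 16S rRNA amplicon
    studies of the piglet gut microbiome under alternative post-weaning
    diarrhea prophylaxis diets. Covers read quality filtering, OTU-table
    filtering and cumulative sum scaling (CSS) normalization, prevalence-based
    core-microbiome extraction, alpha diversity with baseline adjustment,
    Bray-Curtis beta diversity with NMDS and PERMANOVA, repeated-measures
    mixed models with a pig random effect and AR(1) residual correlation,
    Firmicutes:Bacteroidetes ratio analysis with stratified bootstrap
    inference, and growth/mortality summaries. Includes a synthetic-data
    generator that emulates the longitudinal study design (pigs nested in
    diet groups, repeated timepoints, compositional counts) so the whole
    pipeline is testable without raw sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    Biostrings,
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
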