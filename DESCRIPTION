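Package: aridnet
Title: Aridity-Gradient Microbiome Diversity and Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of prokaryotic community composition along an ordered
    climatic aridity gradient, in the rhizosphere and root endosphere. Provides
    readers for OTU count tables (TSV and BIOM), taxonomy maps, sample metadata
    and soil physicochemical profiles; organelle filtering, relative abundance
    and taxonomy aggregation; rarefaction and alpha diversity (Shannon,
    Simpson, observed OTUs) with one-way ANOVA and Tukey HSD group tests;
    Bray-Curtis ordination (NMDS) and PERMANOVA; classification of OTUs as
    increased, decreased or neutral along the gradient by correlation of their
    abundance profiles with zone rank; and a signed, FDR-controlled
    co-occurrence network linking trend-classified OTUs with soil parameters,
    with subnetwork extraction, hub ranking and Cytoscape-compatible export.
    Includes a Dirichlet-multinomial synthetic community generator with planted
    monotone trends and known ground truth for end-to-end validation.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate: 
    'abundance.R'
    'aridnet-package.R'
    'diversity.R'
    'io.R'
    'network.R'
    'ordination.R'
    'pipeline.R'
    'plots.R'
    'simulate.R'
    'tidiers.R'
    'trend.R'
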