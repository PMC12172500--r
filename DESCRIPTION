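Package: mischkit
Title: Multi-Kingdom Scalp Microbiome Profiling and the Microbial Index of
    Scalp Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for multi-kingdom (bacterial 16S and fungal
    ITS1) scalp microbiome profiles in androgenetic alopecia (AGA) cohorts.
    Provides typed abundance-table containers with kingdom merging and
    taxonomic aggregation, alpha diversity (Shannon, Simpson, Chao1),
    Jensen-Shannon divergence beta diversity with principal coordinate
    analysis and PERMANOVA effect sizes, a random-forest microbial-age
    protocol (subsampled importance ranking, forward feature selection with
    grouped cross-validation), a multi-class AGA-stage classifier with
    subject-exclusive splits and repeated one-vs-rest evaluation, and the
    Microbial Index of Scalp Health (MiSCH): a distance-weighted 0-100
    score with severity categories and high-risk discordance detection.
    Includes a Dirichlet-multinomial synthetic cohort generator so the
    whole pipeline is exercisable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    ranger,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    permute,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
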