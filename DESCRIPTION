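Package: cdkflow
Title: Single-Cell CDK Activity Quantification and Size-Resolved Division
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies a nuclear-translocation CDK activity biosensor from
    single-cell microscopy images of fission yeast and computes size-resolved
    division statistics: division hazards (P(Div)), Hill and sigmoid
    dose-response fits, size-binned C-CDK activation-threshold curves,
    tyrosine-phosphorylation/PP2A synergy decomposition, bistability scores,
    and ploidy-dependent EC50 shifts. Ships a synthetic-data generator that
    emulates the statistical structure of imaging-flow-cytometry and
    time-lapse data (cell geometry, level-size scaling, graded or bistable
    activity responses, lineages with division and degradation events, and
    rendered multi-channel cell images) with ground truth retained, so the
    whole pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
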