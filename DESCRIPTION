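Package: gapscore
Title: Multicriteria Gap Scoring of Medical Conditions for Innovation
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores medical conditions on public health burden, health care
    cost, and biomedical product innovation activity, and integrates the three
    domains with a TOPSIS (Technique for Order of Preference by Similarity to
    Ideal Solution) multicriteria model into an overall gap score. Conditions
    are rank-ordered and classified into interquartile-range tiers to flag
    innovation-investment opportunities, i.e. conditions where innovation
    activity lags relative to burden and cost. Includes derived indicators
    (disparity summary rate ratio, longitudinal trends, innovation deficit),
    CSV/YAML/JSON readers and writers, a synthetic metric-table generator with
    plantable gap structure for validation, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
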