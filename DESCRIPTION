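Package: pathner
Title: Named Entity Recognition for Breast Pathology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts cancer subtype, cancer grade and lesion position
    entities from free-text breast pathology reports. Implements the IO
    tagging scheme with subword encoding and first-subtoken supervision, a
    trainable sequence tagger with small-transformer and LSTM encoder
    backends, four data augmentation operators for sequence labelling
    (mention replacement, synonym replacement, label-wise token
    replacement, shuffle within segments) composed under a Bernoulli-gated
    fixed-order policy, rule-based and TF-IDF gradient-boosting report
    classification baselines, exact-match entity-level evaluation, and a
    seeded generator of annotated synthetic pathology reports with
    controllable dialect shift for benchmarking robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
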