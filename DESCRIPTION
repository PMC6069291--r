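Package: qarm
Title: Query-Constraint-Based Association Rule Mining for Clinical Yes/No Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines concise, query-specific association rules from
    patient-level clinical datasets whose variables take yes/no/unknown
    values. Reads dictionary-mapped CSV datasets, merges semantically
    similar variables through canonical mappings, combines multi-visit
    records, restricts to the sub-cohort satisfying a query constraint,
    mines the top-k non-redundant rules above a confidence floor, and
    removes general rules (those also found in the complement cohort) and
    structurally subsumed rules. Includes an exact reference miner, a
    best-first top-k search, a synthetic clinical cohort generator with
    planted associations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
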