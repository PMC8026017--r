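Package: narragraph
Title: Speech Graph Analysis of Narrative Discourse
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds directed word multigraphs from narrative transcripts and
    computes speech graph attributes (node/edge counts, short- and long-range
    recurrence measures, connectivity and global topology measures), with a
    moving-window scheme that controls attribute estimates for verbosity.
    Includes ASRS symptom-checklist scoring, Spearman and covariate-adjusted
    (partial) Spearman correlation tables with Bonferroni thresholds, and a
    synthetic narrative-cohort generator with known recurrence structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
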