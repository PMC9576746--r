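Package: selandscape
Title: Super-Enhancer Landscape Analysis for Matched Tumor/Normal Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls super-enhancers per sample from enhancer peaks and
    H3K27ac ChIP-seq coverage using the ROSE rank-ordering procedure
    (promoter exclusion, 12.5 kb stitching, signal-density ranking, and a
    scaled rank-curve inflection cutoff), builds a cross-sample consensus
    catalog with promoter-normalized signal matrices, computes differential
    super-enhancer statistics between sample groups, recurrence and
    discovery-saturation summaries, prioritizes recurrently gained
    candidates, and assigns super-enhancer target genes by windowed
    signal-expression regression. Includes a deterministic synthetic
    matched-cohort generator with a planted truth set so the whole pipeline
    can be exercised and scored offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
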