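Package: glycopipe
Title: Intact N-Glycopeptide Annotation, Filtering, and Microheterogeneity Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational analysis of intact N-glycopeptide
    tandem mass spectrometry data: glycan composition parsing and
    monoisotopic mass calculus, theoretical fragment-ion generation for
    glycopeptides (b/y/c/z backbone ions with glycan retention modes,
    Y-ion ladders, B/oxonium ions), spectrum annotation with backbone and
    glycan coverage metrics, explained ion current partitioning, and
    diagnostic oxonium-ion intensity ratios; a target-decoy q-value
    estimator and a six-step identification filter cascade with
    glycopeptide-specific FDR accounting; systems-level glycan
    microheterogeneity analytics (site tables, co-occurrence matrices and
    networks, subcellular glycosylation profiles with Euclidean distances,
    and protein-domain glyco-type statistics); and seeded synthetic-data
    generators that emit every input format the pipeline consumes with
    known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
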