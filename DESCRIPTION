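Package: duomod
Title: Subtraction-Free Base-Resolution Analysis of 5mC and 5hmC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the independent, subtraction-free detection of
    5-methylcytosine and 5-hydroxymethylcytosine from paired
    conversion-sequencing assays. Models the five cytosine conversion
    chemistries (BS-seq, TAB-seq, ACE-seq, CD-seq, CT-seq) as compositions
    of probabilistic enzymatic steps, generates seeded synthetic methylomes
    with fully modified spike-in controls and assay-converted pileups,
    estimates per-assay false-positive and conversion rates from the
    spike-ins, calls modified cytosines with a spike-in-calibrated binomial
    test under Benjamini-Hochberg correction, joins 5mC and 5hmC calls into
    per-site paired tables, segments differentially (hydroxy)methylated
    regions, and relates modification levels to gene expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
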