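Package: bsamapr
Title: Bulked Segregant Mapping and Resistance Genetics for Insect Toxin Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping recessive toxin-resistance loci in insects from
    phenotype-selected pooled sequencing and for the companion resistance
    genetics: delta-SNP-index bulked segregant analysis with windowing, local
    regression smoothing and top-percentile candidate-region calling; probit
    dose-response fits with Abbott's control correction, EC50 confidence
    intervals, resistance ratios and dominance estimation; Mendelian
    monogenic-model tests; detection of a transposable-element insertion
    allele from junction-spanning short reads with a read-count calling rule;
    and relative transcript quantification from qPCR cycle thresholds. A
    simulation layer generates genetic crosses, selected bulks, pooled allele
    counts, junction reads and Ct tables so every stage can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
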