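Package: dmrevert
Title: Methylation Reversion, Clonality and Synergy Analysis for Drug
    Resistance Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for tracking the gain and loss of drug resistance through
    DNA methylation dynamics across four cell states (parental, resistant,
    and two drug-withdrawal passages P5 and P12). Implements smoothing-based
    detection of differentially methylated regions (DMRs) required in two
    cell lines, a reversion score that classifies DMRs whose methylation
    returns toward the parental level after drug withdrawal, bp-resolution
    genomic-context annotation (CpG island/shore/shelf/ocean and
    exon/intron/intergenic), Monte-Carlo feature enrichment against random
    regions matched on length and CpG count, variant-allele-fraction based
    clonal-expansion analysis with bisulfite-aware variant filtering, and
    three-parameter log-logistic dose-response fitting with Loewe-additivity
    synergy surfaces. A synthetic-data generator with planted ground truth
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
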