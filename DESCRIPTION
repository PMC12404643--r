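Package: chdnet
Title: Systems-Genetics Prioritization of Congenital Heart Defect Candidate Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for nominating candidate congenital heart
    defect (CHD) genes by intersecting genes under strong selective constraint
    (high heterozygote selection coefficient, s_het) with genes expressed in
    the embryonic cardiac muscle cell lineage, embedding the candidates with
    known disease genes in a confidence-thresholded protein-protein
    interaction network, scoring functional clusters for their richness in
    novel candidates, extracting first-neighbor subnetworks around a chosen
    cluster, and running gene-set over-representation with Bonferroni
    correction. Includes a decile burden test for de novo variant gene lists,
    measurement formulas for zebrafish cardiac phenotyping (heart rate,
    ventricular fractional area change, delta-delta-Ct fold change), and a
    synthetic-data generator with planted disease modules so every stage can
    be exercised and calibrated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
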