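Package: goscape
Title: Threshold-Free Gene Ontology Enrichment Sweeps for Two-Group
    RNA-Seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Count-based two-group differential expression with
    median-of-ratios normalization and Welch tests, followed by a
    threshold-free stepwise Gene Ontology over-representation sweep:
    hypergeometric enrichment is evaluated at a grid of top-n cutoffs
    along the significance-ranked gene list, p-values are
    Benjamini-Hochberg adjusted across terms within each step, the most
    significant terms over the whole range are selected, and a
    gene-by-term heatmap of peak significance is produced. Includes a
    negative-binomial synthetic-data generator with planted differential
    expression and planted term enrichment for benchmarking, plus TSV
    and GAF 2.x readers and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    pheatmap,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
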