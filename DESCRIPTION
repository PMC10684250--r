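Package: mdngscreen
Title: miRNA-Regulated Drug-Pathway Networks for Drug Repurposing Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Network-based drug repurposing from pathway co-enrichment.
    Builds tripartite miRNA-drug-pathway networks (MDNG) from hypergeometric
    pathway over-representation of disease risk genes, miRNA target sets and
    drug target sets; scores each drug against the disease by the joint
    enrichment on their most significantly shared pathway; and screens
    candidates with a permutation Z-score null (Z > 1.96). Includes network
    topology summaries (degree distributions, log-log power-law fits,
    topological coefficients), readers and writers for GMT, SIF, gene-list
    and two-column target-map formats, and a synthetic-study generator with
    planted risk pathways and responsive regulators for end-to-end
    validation of the screen.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'enrichment.R'
    'io.R'
    'network.R'
    'screening.R'
    'synthetic.R'
    'pipeline.R'
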