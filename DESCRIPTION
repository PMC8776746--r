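Package: stresspan
Title: Environmental Stress and Bacterial Pangenome Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how environmental stress gradients structure bacterial
    pangenomes. Provides standardisation of raw environmental measurements into
    oriented stress gradients, negative-binomial mixed models of per-strain gene
    richness and per-soil-sample pangenome diversity, per-gene binomial
    occurrence models yielding stress-response z-scores, gene functional traits
    from protein-interaction networks (betweenness, mean cosine similarity,
    duplication level), trait meta-regression and barycentric loss weighting,
    beta- and binomial-regression summaries of codon-level selection (dN/dS),
    stress-stratified Hudson Fst with permutation inference, and Gaussian
    process smoothing of gene statistics on circular genomes. A synthetic-data
    generator with planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: glmmTMB, graphics, grDevices, igraph, jsonlite, MASS, Matrix,
    sandwich, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
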