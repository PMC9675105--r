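Package: phnet
Title: Protein Function Prediction by Propagation on Heterogeneous
    Protein-Domain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts Gene Ontology annotations for proteins by random walk
    with restart on a heterogeneous biological network that fuses a
    protein-protein interaction network, protein-complex co-membership and
    protein-domain associations.  A weighted protein layer is built from
    local network topology (direct and level-2 neighbours) blended with a
    complex co-membership module similarity; a domain layer is derived from
    the weighted protein layer through the protein-domain incidence; the two
    layers are coupled into one block transition matrix and propagated with
    restart to rank functional partners.  A target protein is annotated with
    the top-L aggregated terms of its partners.  Includes readers for edge
    lists, complex catalogs, Pfam-style association tables and GAF 2.x
    annotation files, a planted-module synthetic data generator, and the
    full cross-validation evaluation protocol (leave-one-out, k-fold,
    precision/recall/F-measure, top-K ROC and AUROC, and a beta sweep).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    graphics,
    jsonlite,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
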