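Package: surfcamd
Title: Decomposition-Based Computer-Aided Molecular Design of Surfactants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fragment-based de novo design of surfactant molecules by
    decomposition into hydrophilic heads and hydrophobic tails. Molecular
    graphs over user-defined building-block groups are enumerated
    exhaustively under valence, connectivity and occurrence constraints
    with integer-cut deduplication; fragments are expanded to atom-level
    bond matrices, fused at dummy-atom attachment points and emitted as
    sanitized canonical SMILES. Candidate libraries are scored with
    linear quantitative structure-property (QSPR) models (partial least
    squares or lasso with cross-validation) for critical micelle
    concentration, Krafft point, surface tension, aquatic toxicity,
    biodegradability and synthetic accessibility, and ranked by
    epsilon-constraint multiobjective enumeration with Pareto filtering
    and TOPSIS closeness scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    glmnet,
    mixOmics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
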