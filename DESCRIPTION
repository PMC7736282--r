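Package: varsite
Title: Active-Site Shell Analysis and Variant Fitness Characterisation for
    mRNA Methyltransferases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising engineered variants of mRNA
    cap-methyltransferases such as Vaccinia virus VP39. Assigns residues to
    distance-defined shells around a catalytic lysine from PDB structures,
    builds and annotates sequence-similarity networks of a protein family,
    fits one- and two-transition sigmoid models to barycentric-mean
    fluorescence melt curves, quantifies coupled-assay methyltransferase
    activity relative to wild-type and knock-out controls, computes melting
    temperature epistasis for multi-mutants, derives hydrogen-bond occurrence
    networks, catalytic distances and side-chain rigidity from molecular
    dynamics trajectories, and classifies variants by foldedness, stability
    and activity. Includes synthetic-data generators with known ground truth
    for every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    igraph,
    minpack.lm,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
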