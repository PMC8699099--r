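Package: domalign
Title: Structure-Based Comparison and Clustering of Protein Domain Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing predicted and experimental protein structures
    at the C-alpha level and deriving family-wide relationships from the
    comparisons. Reads PDB/mmCIF coordinate files into a uniform CA-trace
    model carrying per-residue pLDDT confidence, segments chains into
    confident folded domains versus low-confidence disordered regions,
    performs distance-matrix ("elastic") structural alignment with Dali-style
    Z-score calibration, computes Kabsch superposition RMSDs, builds
    average-linkage dendrograms directly on structural similarity with Newick
    export, and projects structures into two dimensions by correspondence
    analysis. Includes a synthetic toy-structure generator (ideal helices and
    strands, multi-domain chains with disordered linkers, planted structural
    families) so the whole pipeline is testable without downloading models,
    plus packaged similarity and domain-boundary tables for the human KCTD
    protein family.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    MASS,
    optparse,
    jsonlite
Config/testthat/edition: 3
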