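Package: GraphSol
Title: Intrinsic Solubility from pH-Dependent Assays and a Multi-Task Graph Transformer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives intrinsic solubility (S0) of ionizable drug-like compounds from
    pH-dependent solubility measurements and predicted pKa values using
    Henderson-Hasselbalch speciation, curates multi-assay data into a sparse
    eight-task property table, trains a multi-task graph transformer
    (GraphGPS-style blocks with an exponential hop-distance decay mask on the
    attention weights and random-walk structural encodings) to predict S0 and
    seven related physicochemical properties, and reconstructs full pH 0-12
    solubility profiles from predicted S0 and pKa's. Includes a synthetic-data
    generator emulating high-throughput pH 2 / pH 7 solubility assays with
    censoring, solid-state labels, salts and duplicates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    graphics,
    grDevices,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
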