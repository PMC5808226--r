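Package: aquaflux
Title: Oocyte Swelling Assays, Aquaporin Sequence Hallmarks, and
    Relative Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the functional characterization of water-channel
    proteins (aquaporins). Simulates and analyses Xenopus oocyte swelling
    assays, estimating the osmotic water permeability coefficient (Pf) and
    the apparent solute permeability (Psol) from silhouette-area time
    series; segments oocyte silhouettes in grayscale image frames to
    produce those time series; annotates aquaporin sequence hallmarks on
    cDNA and protein sequences (open reading frame, molecular weight and
    isoelectric point, NPA boxes, C-terminal motif, Kyte-Doolittle
    hydropathy, aromatic/arginine selectivity-filter mapping, degenerate
    in-silico PCR); and quantifies relative gene expression from qPCR Ct
    tables by the 2^-ddCt method with the field's standard group
    statistics. Seeded synthetic-data generators with recorded ground
    truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    car,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
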