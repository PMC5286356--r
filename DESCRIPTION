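Package: softcontact
Title: Quantitative Analysis of Soft Protein-Protein Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying "soft and specific" protein-protein
    interfaces of the kind found in transient electron-transfer complexes:
    classification of interfacial crystallographic waters into bridging,
    non-bridging and non-interacting categories with their hydrogen-bond
    network; polar-contact inventories and shortest inter-chain distances
    (including crystal symmetry mates); Shrake-Rupley solvent-accessible and
    contact surface areas; B-factor "fulcrum" profiling against interface
    anchor residues; and an empirical Pathways-model search for the
    best-coupled electron tunneling route between a donor and an acceptor
    atom. Includes a seeded generator of toy two-chain complexes with
    ground-truth water categories for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
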