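Package: peptiter
Title: Grain-Discriminating Peptide Hapten Selection and ELISA Endpoint-Titer
    Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An in-silico pipeline for selecting synthetic peptide haptens
    that discriminate between the gluten protein families of cereal grains,
    together with the immunoassay statistics used to evaluate the resulting
    antisera. From per-family multiple sequence alignments the package builds
    modal consensus sequences, mines segments unique to one grain by exact
    k-mer co-occurrence, screens them against off-target prolamins, filters
    on Kyte-Doolittle hydropathy, residue-repeat runs and length, ranks the
    survivors and emits synthesis-ready peptide strings. The serology side
    implements endpoint titers on serial dilution series (discrete and
    log2-interpolated), the Frey blank-based statistical cutoff, serum
    retention rules and categorical cross-reactivity banding. A synthetic
    data module generates grain families with planted ground truth and
    four-parameter-logistic ELISA plates so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
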