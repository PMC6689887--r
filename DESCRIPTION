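Package: synthon
Title: Data-Driven Retrosynthetic Analysis from Atom-Mapped Reaction Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Learns reverse-reaction templates from atom-mapped reaction
    collections and applies them to deconstruct target molecules into
    synthons. A training phase standardizes and reverses mapped reactions,
    detects changing atoms (the reaction core) by comparing configurable
    atomic properties across reaction sides, expands the core to circular
    environments of increasing bond radius, serializes each extended core
    as a canonical signature string, and clusters reactions by signature
    identity into a template repository with support counts and provenance.
    A design phase compiles each template into a substructure query,
    matches hypothesis molecules, performs the reverse transformation to
    produce candidate building blocks, looks them up in a local inventory
    collection, and can recurse into multi-step routes. Includes a
    deterministic generator of decorated reaction corpora from common
    reaction families (ester hydrolysis, amide couplings, N-alkylation,
    nitro reduction, nucleophilic aromatic substitution) for testing and
    benchmarking without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
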