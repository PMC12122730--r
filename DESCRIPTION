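Package: neaokg
Title: Knowledge Graphs of Neuroelectrophysiology Analysis Provenance with NEAO
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Describes electrophysiology data analyses with the
    Neuroelectrophysiology Analysis Ontology (NEAO). Builds an in-memory subset
    of the ontology with normalization-based (OWL2-RL style) inference,
    attaches NEAO semantic annotations to analysis routines, captures execution
    provenance as PROV-style RDF, maps the captured provenance into NEAO
    descriptions, and answers competency questions over the resulting knowledge
    graph with both native traversals and a small SPARQL engine. Ships three
    demonstration analyses (power spectral densities of local field potentials,
    interspike-interval histograms of spike-train surrogates, and artificial
    Poisson/gamma spike trains) that run end-to-end on a synthetic recording
    session.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cli,
    graphics,
    grDevices,
    dplyr,
    generics,
    ggplot2,
    igraph,
    png,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
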