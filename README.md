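# neaokg

Semantic description and querying of neuroelectrophysiology data analyses
with the **Neuroelectrophysiology Analysis Ontology (NEAO)**, implemented as
an R package.

Analyses of electrophysiology recordings are hard to describe unambiguously:
the same quantity (say, a power spectral density) can be estimated by
different algorithms (Welch, multitaper), the same algorithm is implemented
by different toolboxes under different function and parameter names, and
result files on disk rarely say which of these produced them. NEAO addresses
this by modeling an analysis as a sequence of atomic **analysis steps**, each
linked to its **data** inputs/outputs, its **parameters**, and its
**software implementation**, with cross-cutting semantic groupings (e.g. "all
PSD estimation methods", "all functional-connectivity methods") defined
through Rector-normalization axioms that a reasoner can expand.

This package provides the full machinery at desk scale, for researchers and
tool builders who want to annotate analysis code, capture what actually ran,
and query collections of results semantically:

- **Ontology model** (`build_neao_subset()`, `materialize_inferences()`):
  the NEAO core (AnalysisStep / Data / AnalysisParameter, software
  description classes), the step/data/parameter classes used by the demo
  analyses, SKOS labels, synonyms, abbreviations and bibliographic
  references, and an OWL2-RL-style rule engine that materializes the
  subclass closure entailed by the `hasPurpose` / `isDirected` value
  restrictions (e.g. `CoherenceAnalysis` is *inferred* under both
  `FunctionalConnectivityAnalysis` and `NonDirectedAnalysis`).
- **Annotation registry** (`register_annotation()`): attach NEAO classes to
  analysis routines — the step class, per-argument Data/Parameter classes,
  per-return Data classes — using CURIEs against the six NEAO namespaces.
- **Provenance capture** (`run_context()`, `track_execution()`,
  `record_file_event()`): content-addressed PROV-style records of every
  routine execution (inputs, outputs, parameters, container membership, file
  reads/writes), serialized as Turtle sidecars.
- **NEAO mapping** (`build_knowledge_graph()`, `apply_mappings()`,
  `map_container_outputs()`): rewrites the capture vocabulary into NEAO
  properties (`hasInput`, `hasOutput`, `usesParameter`, `isImplementedIn`,
  `isImplementedInPackage`), shipped both as native traversals and as
  SPARQL UPDATE texts (`inst/sparql/`) that produce identical graphs.
- **Query engine** (`files_derived_from()`, `steps_for_files()`,
  `parameters_for_step()`, `software_for_step()`, `step_preceding()`, ...):
  competency-question queries over the knowledge graph, returning tidy
  tibbles with deterministic row order, plus a small SPARQL SELECT engine.
- **Demo analyses** (`run_demo_analyses()`): three end-to-end scenarios on a
  synthetic recording session — per-trial LFP power spectra (Welch by two
  parameterizations and multitaper, behind two software identities),
  interspike-interval histograms of spike-train surrogates (uniform
  dithering vs. trial shifting), and ISI statistics of artificial
  Poisson/gamma spike trains — each annotated, captured, mapped, and
  queryable.

## Worked example

```r
library(neaokg)

onto <- materialize_inferences(build_neao_subset())

# disambiguation: abbreviations and synonyms resolve to the controlled class
lookup_term(onto, "PSD")
#> [1] "http://purl.org/neao/data#PowerSpectralDensity"

# normalization inference: coherence is grouped (not asserted!) under
# functional-connectivity analyses
is_subclass_of(onto, "neao_steps:CoherenceAnalysis",
               "neao_steps:FunctionalConnectivityAnalysis")
#> [1] TRUE

# run two demo analyses and build the mapped knowledge graph
out <- file.path(tempdir(), "neao-demo")
res <- run_demo_analyses(out, seed = 1, variants = c("1.1", "3"))
kg <- demo_knowledge_graph(res$runs, onto)

aggregate_by_folder(all_saved_files(kg), "output", 2)
#> # A tibble: 2 × 2
#>   folder                       n
#>   <chr>                    <int>
#> 1 isi_histograms             200
#> 2 reach2grasp/psd_by_trial   160

parameters_for_step(kg, onto, "neao_steps:ComputePowerSpectralDensityWelch") |>
  dplyr::count(parameter_class = sub(".*#", "", parameter_class), value)
#> # A tibble: 3 × 3
#>   parameter_class     value      n
#>   <chr>               <chr>  <int>
#> 1 FrequencyResolution 2.0 Hz   160
#> 2 WindowFunction      hann     160
#> 3 WindowOverlapFactor 0.5      160
```

The first table says the two runs saved 200 ISI-histogram plots of
artificial data and 160 per-trial PSD plots (one of the 161 generated trials
is too short for the requested 2 Hz spectral resolution and is skipped); the
second recovers, for every PSD file, the exact Welch parameterization used to
compute it — without reading any analysis code.

A command-line front end over the same functions is available at
`inst/cli/neaokg.R` (`demo` and `query` subcommands).

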