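onto <- materialize_inferences(build_neao_subset())

test_that("the core model and demo-required classes are present", {
  base <- neao_namespaces()[["neao_base"]]
  core_props <- c("hasInput", "hasOutput", "usesParameter", "isImplementedIn",
                  "isImplementedInPackage", "hasSubstep", "hasPurpose",
                  "isDirected", "hasBibliographicReference", "abbreviation",
                  "nameInDefinition", "programName", "packageName",
                  "packageVersion", "version")
  expect_true(all(paste0(base, core_props) %in% onto$properties$uri))

  core_classes <- c("AnalysisStep", "Data", "AnalysisParameter",
                    "SoftwareImplementation", "Function", "Program",
                    "SoftwarePackage", "ElectrophysiologySignalSource",
                    "DataRepresentation", "AnalysisPurpose")
  expect_true(all(paste0(base, core_classes) %in% onto$classes$uri))

  steps <- neao_namespaces()[["neao_steps"]]
  demo_steps <- c("ApplyButterworthFilter", "ApplyDownsampling",
                  "ComputePowerSpectralDensityWelch",
                  "ComputePowerSpectralDensityMultitaper",
                  "ComputeInterspikeIntervals",
                  "ComputeInterspikeIntervalHistogram", "ComputeMean",
                  "ComputeStandardDeviation", "ApplySum", "ComputeCV2",
                  "GenerateStationaryPoissonProcess",
                  "GenerateStationaryGammaProcess",
                  "GenerateUniformSpikeDitheringSurrogate",
                  "GenerateTrialShiftingSurrogate", "SpectralAnalysis",
                  "PowerSpectralDensityAnalysis", "CoherenceAnalysis",
                  "CrossCorrelationAnalysis", "FunctionalConnectivityAnalysis",
                  "DirectedAnalysis", "NonDirectedAnalysis", "DigitalFiltering",
                  "ArtificialDataGeneration", "SpikeTrainSurrogateGeneration",
                  "InterspikeIntervalVariabilityAnalysis",
                  "ExecuteASSETAnalysis", "ASSETAnalysisSubstep",
                  "NeuronalActivityPatternDetectionAnalysis",
                  "CompoundAnalysis")
  expect_true(all(paste0(steps, demo_steps) %in% onto$classes$uri))
})

test_that("the asserted PSD taxonomy follows the step grouping", {
  expect_true(is_subclass_of(onto,
    "neao_steps:ComputePowerSpectralDensityWelch",
    "neao_steps:PowerSpectralDensityAnalysis"))
  expect_true(is_subclass_of(onto,
    "neao_steps:PowerSpectralDensityAnalysis",
    "neao_steps:SpectralAnalysis"))
})

test_that("every step class has a comment and exactly one pref_label", {
  steps <- subclasses_of(onto, "neao_base:AnalysisStep")
  cls <- onto$classes[onto$classes$uri %in% steps, ]
  expect_equal(nrow(cls), length(steps))     # one row (one label) each
  expect_true(all(nzchar(cls$pref_label)))
  expect_true(all(nzchar(cls$comment)))
})

test_that("duplicate class URIs fail construction naming the URI", {
  o <- build_neao_subset()
  uri <- paste0(neao_namespaces()[["neao_steps"]], "ComputeCV2")
  expect_error(neaokg:::onto_add_class(o, uri, "x"), "ComputeCV2")
})

test_that("normalization inference entails the cross-cutting groupings", {
  expect_true(is_subclass_of(onto, "neao_steps:CoherenceAnalysis",
                             "neao_steps:FunctionalConnectivityAnalysis"))
  expect_true(is_subclass_of(onto, "neao_steps:CoherenceAnalysis",
                             "neao_steps:NonDirectedAnalysis"))
  expect_true(is_subclass_of(onto, "neao_steps:CrossCorrelationAnalysis",
                             "neao_steps:DirectedAnalysis"))
  expect_false(is_subclass_of(onto, "neao_steps:CrossCorrelationAnalysis",
                              "neao_steps:NonDirectedAnalysis"))
})

test_that("an individual with a hasSubstep assertion is typed CompoundAnalysis", {
  o <- build_neao_subset()
  steps <- function(x) paste0(neao_namespaces()[["neao_steps"]], x)
  o <- neaokg:::onto_add_individual(o, steps("run1"),
                                    steps("ExecuteASSETAnalysis"))
  o$statements <- tibble::tibble(
    s = steps("run1"),
    p = paste0(neao_namespaces()[["neao_base"]], "hasSubstep"),
    o = steps("substep1"))
  o <- materialize_inferences(o)
  types <- o$individuals$type[o$individuals$uri == steps("run1")]
  expect_true(steps("CompoundAnalysis") %in% types)
  expect_true(paste0(neao_namespaces()[["neao_base"]], "AnalysisStep") %in%
                types)
})

test_that("inference equals the brute-force fixpoint on small random graphs", {
  for (seed in 1:5) {
    o <- random_small_ontology(n_classes = sample(5:25, 1) + seed,
                               n_edges = 20, n_groups = seed %% 3, seed = seed)
    got <- materialize_inferences(o)$inferred
    expect_identical(arrange_all_cols(got),
                     arrange_all_cols(brute_force_inference(o)),
                     info = paste("seed", seed))
  }
})

test_that("without restriction axioms, inference is the reflexive-transitive closure", {
  o <- random_small_ontology(n_classes = 12, n_edges = 15, n_groups = 0,
                             seed = 42)
  got <- materialize_inferences(o)$inferred
  expect_identical(arrange_all_cols(got),
                   arrange_all_cols(brute_force_inference(o)))
})

test_that("adding a restriction axiom never removes inferred pairs", {
  o <- random_small_ontology(n_classes = 10, n_edges = 12, n_groups = 1,
                             seed = 3)
  before <- materialize_inferences(o)$inferred
  prop <- paste0(neao_namespaces()[["neao_base"]], "isDirected")
  o2 <- neaokg:::onto_add_restriction(o, o$classes$uri[1],
                                      "equivalent_to_restriction", prop,
                                      "true", "boolean")
  o2 <- neaokg:::onto_add_restriction(o2, o$classes$uri[5],
                                      "subclass_of_restriction", prop,
                                      "true", "boolean")
  after <- materialize_inferences(o2)$inferred
  merged <- dplyr::anti_join(before, after, by = c("sub", "super"))
  expect_equal(nrow(merged), 0)
})

test_that("term lookup resolves labels, synonyms and abbreviations", {
  psd <- paste0(neao_namespaces()[["neao_data"]], "PowerSpectralDensity")
  expect_equal(lookup_term(onto, "PSD"), psd)
  expect_equal(lookup_term(onto, "psd"), psd)          # case-insensitive
  expect_equal(lookup_term(onto, "power spectral density"), psd)
  expect_equal(lookup_term(onto, "spectrum"), psd)     # altLabel
  expect_length(lookup_term(onto, "zzz-not-a-term"), 0)
})

test_that("ontology serialization round-trips classes, axioms and annotations", {
  o <- build_neao_subset()
  o2 <- parse_ontology(serialize_ontology(o))
  expect_identical(arrange_all_cols(o$classes), arrange_all_cols(o2$classes))
  expect_identical(arrange_all_cols(o$subclass), arrange_all_cols(o2$subclass))
  expect_identical(arrange_all_cols(o$alt_labels),
                   arrange_all_cols(o2$alt_labels))
  expect_identical(arrange_all_cols(o$abbreviations),
                   arrange_all_cols(o2$abbreviations))
  expect_identical(arrange_all_cols(o$restrictions),
                   arrange_all_cols(o2$restrictions))
  expect_identical(arrange_all_cols(o$bib), arrange_all_cols(o2$bib))
  # inference on the round-tripped ontology agrees
  expect_identical(materialize_inferences(o)$inferred,
                   materialize_inferences(o2)$inferred)
})

test_that("unsupported serialization formats are rejected by name", {
  expect_error(serialize_ontology(build_neao_subset(), format = "rdfxml"),
               "rdfxml")
})

test_that("bibliographic references carry citation text and a resolvable-shaped id", {
  b <- onto$bib
  expect_gt(nrow(b), 2)
  expect_true(all(nzchar(b$citation)))
  expect_true(all(grepl("^https://doi\\.org/", b$resource)))
  welch <- paste0(neao_namespaces()[["neao_steps"]],
                  "ComputePowerSpectralDensityWelch")
  expect_true(welch %in% b$class_uri)
})
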