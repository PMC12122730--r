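# NEAO ontology subset: class/property model, annotations, normalization
# axioms, and rule-based inference materialization.
#
# The ontology is an S3 container of tibbles:
#   classes       (uri, pref_label, comment)
#   alt_labels    (uri, label)
#   abbreviations (uri, abbrev)
#   properties    (uri, kind)          kind: object / data / annotation
#   subclass      (sub, super)         asserted named-class subclass axioms
#   restrictions  (class, kind, property, value, value_kind)
#                 kind: subclass_of_restriction / equivalent_to_restriction /
#                       has_substep_some
#   individuals   (uri, type)
#   statements    (s, p, o)            object-property assertions on individuals
#   bib           (class_uri, ref_uri, citation, resource)
#   inferred      (sub, super)         filled by materialize_inferences()

new_ontology <- function() {
  structure(list(
    classes = tibble::tibble(uri = character(), pref_label = character(),
                             comment = character()),
    alt_labels = tibble::tibble(uri = character(), label = character()),
    abbreviations = tibble::tibble(uri = character(), abbrev = character()),
    properties = tibble::tibble(uri = character(), kind = character()),
    subclass = tibble::tibble(sub = character(), super = character()),
    restrictions = tibble::tibble(class = character(), kind = character(),
                                  property = character(), value = character(),
                                  value_kind = character()),
    individuals = tibble::tibble(uri = character(), type = character()),
    statements = tibble::tibble(s = character(), p = character(),
                                o = character()),
    bib = tibble::tibble(class_uri = character(), ref_uri = character(),
                         citation = character(), resource = character()),
    inferred = NULL
  ), class = "neao_ontology")
}

onto_namespace_ok <- function(uri) {
  ns <- neao_namespaces()[c("neao", "neao_base", "neao_data", "neao_steps",
                            "neao_params", "neao_bib")]
  any(vapply(ns, function(b) startsWith(uri, b), logical(1)))
}

onto_add_class <- function(onto, uri, pref_label, comment = "",
                           parents = character(0), alt_labels = character(0),
                           abbreviations = character(0)) {
  if (uri %in% onto$classes$uri) {
    stop(sprintf("duplicate class URI: %s", uri), call. = FALSE)
  }
  if (!onto_namespace_ok(uri)) {
    stop(sprintf("class URI outside NEAO namespaces: %s", uri), call. = FALSE)
  }
  onto$classes <- dplyr::bind_rows(
    onto$classes,
    tibble::tibble(uri = uri, pref_label = pref_label, comment = comment)
  )
  if (length(parents)) {
    onto$subclass <- dplyr::bind_rows(
      onto$subclass, tibble::tibble(sub = uri, super = parents)
    )
  }
  if (length(alt_labels)) {
    onto$alt_labels <- dplyr::bind_rows(
      onto$alt_labels, tibble::tibble(uri = uri, label = alt_labels)
    )
  }
  if (length(abbreviations)) {
    onto$abbreviations <- dplyr::bind_rows(
      onto$abbreviations, tibble::tibble(uri = uri, abbrev = abbreviations)
    )
  }
  onto
}

onto_add_property <- function(onto, uri, kind = "object") {
  if (uri %in% onto$properties$uri) {
    stop(sprintf("duplicate property URI: %s", uri), call. = FALSE)
  }
  onto$properties <- dplyr::bind_rows(
    onto$properties, tibble::tibble(uri = uri, kind = kind)
  )
  onto
}

onto_add_restriction <- function(onto, class, kind, property, value,
                                 value_kind = "iri") {
  onto$restrictions <- dplyr::bind_rows(
    onto$restrictions,
    tibble::tibble(class = class, kind = kind, property = property,
                   value = value, value_kind = value_kind)
  )
  onto
}

onto_add_individual <- function(onto, uri, types = character(0)) {
  if (length(types)) {
    onto$individuals <- dplyr::bind_rows(
      onto$individuals, tibble::tibble(uri = uri, type = types)
    )
  } else {
    onto$individuals <- dplyr::bind_rows(
      onto$individuals, tibble::tibble(uri = uri, type = NA_character_)
    )
  }
  onto
}

onto_add_bib <- function(onto, class_uri, ref_uri, citation, resource) {
  stopifnot(nzchar(citation), grepl("^[a-z]+:", resource))
  onto$bib <- dplyr::bind_rows(
    onto$bib,
    tibble::tibble(class_uri = class_uri, ref_uri = ref_uri,
                   citation = citation, resource = resource)
  )
  onto
}

#' Build the NEAO subset used by the demonstration analyses
#'
#' Constructs the core NEAO model (AnalysisStep / Data / AnalysisParameter,
#' software description classes and properties), the analysis-step, data, and
#' parameter classes needed by the three demo analyses, the cross-cutting
#' grouping classes defined through Rector-normalization value restrictions
#' (purpose and directionality), and the ASSET compound-analysis axioms.
#'
#' @return A `neao_ontology` object (inferences not yet materialized; see
#'   [materialize_inferences()]).
#' @export
build_neao_subset <- function() {
  base <- function(x) ns_iri("neao_base", x)
  steps <- function(x) ns_iri("neao_steps", x)
  dat <- function(x) ns_iri("neao_data", x)
  par <- function(x) ns_iri("neao_params", x)
  bib <- function(x) ns_iri("neao_bib", x)

  o <- new_ontology()

  # Core properties
  for (p in c("hasInput", "hasOutput", "usesParameter", "isImplementedIn",
              "isImplementedInPackage", "hasSubstep", "hasPurpose",
              "isDirected")) {
    o <- onto_add_property(o, base(p), "object")
  }
  for (p in c("nameInDefinition", "programName", "packageName",
              "packageVersion", "version")) {
    o <- onto_add_property(o, base(p), "data")
  }
  o <- onto_add_property(o, base("hasBibliographicReference"), "annotation")
  o <- onto_add_property(o, base("abbreviation"), "annotation")

  # Core classes
  o <- onto_add_class(o, base("AnalysisStep"), "analysis step",
    "An atomic process in the analysis that generates, transforms or characterizes data.")
  o <- onto_add_class(o, base("Data"), "data",
    "Information used during the analysis; inputs and outputs of analysis steps.")
  o <- onto_add_class(o, base("AnalysisParameter"), "analysis parameter",
    "A value that modulates the behavior of an analysis step without providing data.")
  o <- onto_add_class(o, base("SoftwareImplementation"), "software implementation",
    "The primary code source used to execute an analysis step.")
  o <- onto_add_class(o, base("Function"), "function",
    "Reusable code used as a building block within a larger program.",
    parents = base("SoftwareImplementation"))
  o <- onto_add_class(o, base("Program"), "program",
    "A full script or compiled executable callable by the operating system.",
    parents = base("SoftwareImplementation"))
  o <- onto_add_class(o, base("SoftwarePackage"), "software package",
    "A collection of software bundling distinct pieces of code, e.g. a toolbox.")
  o <- onto_add_class(o, base("ElectrophysiologySignalSource"),
    "electrophysiology signal source",
    "Abstraction for describing the source of the signal represented by Data.")
  o <- onto_add_class(o, base("DataRepresentation"), "data representation",
    "Abstraction describing how data is structured (array, matrix, scalar).")
  o <- onto_add_class(o, base("AnalysisPurpose"), "analysis purpose",
    "A specific purpose pursued by an analysis step.")

  # Step taxonomy
  o <- onto_add_class(o, steps("DigitalFiltering"), "digital filtering",
    "Grouping of all digital filtering operations applied to time series.",
    parents = base("AnalysisStep"))
  o <- onto_add_class(o, steps("ApplyButterworthFilter"), "apply Butterworth filter",
    "Filter a time series with a Butterworth-type IIR filter.",
    parents = steps("DigitalFiltering"))
  o <- onto_add_class(o, steps("ApplyDownsampling"), "apply downsampling",
    "Reduce the sampling rate of a time series by an integer factor.",
    parents = base("AnalysisStep"))

  o <- onto_add_class(o, steps("SpectralAnalysis"), "spectral analysis",
    "Grouping of analyses based on frequency-domain decompositions of time series.",
    parents = base("AnalysisStep"))
  o <- onto_add_class(o, steps("PowerSpectralDensityAnalysis"),
    "power spectral density analysis",
    "Grouping of all methods to estimate a power spectral density.",
    parents = steps("SpectralAnalysis"),
    abbreviations = "PSD analysis")
  o <- onto_add_class(o, steps("ComputePowerSpectralDensityWelch"),
    "compute power spectral density (Welch)",
    "Estimate a PSD by averaging periodograms of overlapping windowed segments.",
    parents = steps("PowerSpectralDensityAnalysis"))
  o <- onto_add_class(o, steps("ComputePowerSpectralDensityMultitaper"),
    "compute power spectral density (multitaper)",
    "Estimate a PSD by averaging periodograms under orthogonal Slepian tapers.",
    parents = steps("PowerSpectralDensityAnalysis"))

  o <- onto_add_class(o, steps("CoherenceAnalysis"), "coherence analysis",
    "Grouping of methods computing coherence between two signals.",
    parents = steps("SpectralAnalysis"))
  o <- onto_add_class(o, steps("CrossCorrelationAnalysis"),
    "cross-correlation analysis",
    "Grouping of methods computing cross-correlation between two signals in the time domain.",
    parents = base("AnalysisStep"))

  o <- onto_add_class(o, steps("FunctionalConnectivityAnalysis"),
    "functional connectivity analysis",
    "Grouping (by purpose) of all methods used to estimate functional connectivity.",
    parents = base("AnalysisStep"))
  o <- onto_add_class(o, steps("DirectedAnalysis"), "directed analysis",
    "Grouping of analyses producing directed estimates.",
    parents = base("AnalysisStep"))
  o <- onto_add_class(o, steps("NonDirectedAnalysis"), "non-directed analysis",
    "Grouping of analyses producing non-directed estimates.",
    parents = base("AnalysisStep"))

  o <- onto_add_class(o, steps("ArtificialDataGeneration"),
    "artificial data generation",
    "Grouping of steps that generate artificial data instead of transforming recorded data.",
    parents = base("AnalysisStep"))
  o <- onto_add_class(o, steps("GenerateStationaryPoissonProcess"),
    "generate stationary Poisson process",
    "Generate a spike train as a realization of a stationary Poisson point process.",
    parents = steps("ArtificialDataGeneration"))
  o <- onto_add_class(o, steps("GenerateStationaryGammaProcess"),
    "generate stationary gamma process",
    "Generate a spike train whose interspike intervals follow a gamma distribution.",
    parents = steps("ArtificialDataGeneration"))

  o <- onto_add_class(o, steps("SpikeTrainSurrogateGeneration"),
    "spike train surrogate generation",
    "Grouping of methods generating randomized surrogate versions of spike trains.",
    parents = base("AnalysisStep"))
  o <- onto_add_class(o, steps("GenerateUniformSpikeDitheringSurrogate"),
    "generate uniform spike dithering surrogate",
    "Displace each spike independently by a uniform random offset within a dither window.",
    parents = steps("SpikeTrainSurrogateGeneration"))
  o <- onto_add_class(o, steps("GenerateTrialShiftingSurrogate"),
    "generate trial shifting surrogate",
    "Shift all spikes of a trial's spike train by a single uniform random offset.",
    parents = steps("SpikeTrainSurrogateGeneration"))

  o <- onto_add_class(o, steps("ComputeInterspikeIntervals"),
    "compute interspike intervals",
    "Compute the time intervals between consecutive spikes of a spike train.",
    parents = base("AnalysisStep"), abbreviations = "ISI computation")
  o <- onto_add_class(o, steps("ComputeInterspikeIntervalHistogram"),
    "compute interspike interval histogram",
    "Bin interspike intervals into a histogram with uniform bin width.",
    parents = base("AnalysisStep"), abbreviations = "ISIH computation")
  o <- onto_add_class(o, steps("InterspikeIntervalVariabilityAnalysis"),
    "interspike interval variability analysis",
    "Grouping of measures of the variability of interspike intervals.",
    parents = base("AnalysisStep"))
  o <- onto_add_class(o, steps("ComputeCV2"), "compute CV2",
    "Compute the local coefficient of variation CV2 of interspike intervals.",
    parents = steps("InterspikeIntervalVariabilityAnalysis"))

  o <- onto_add_class(o, steps("ComputeMean"), "compute mean",
    "Compute the arithmetic mean across a collection of values.",
    parents = base("AnalysisStep"))
  o <- onto_add_class(o, steps("ComputeStandardDeviation"),
    "compute standard deviation",
    "Compute the standard deviation across a collection of values.",
    parents = base("AnalysisStep"))
  o <- onto_add_class(o, steps("ApplySum"), "apply sum",
    "Compute the element-wise sum across a collection of values.",
    parents = base("AnalysisStep"))

  # Compound analyses and the ASSET axioms (class definitions only)
  o <- onto_add_class(o, steps("CompoundAnalysis"), "compound analysis",
    "An analysis process composed of multiple substeps.",
    parents = base("AnalysisStep"))
  o <- onto_add_class(o, steps("NeuronalActivityPatternDetectionAnalysis"),
    "neuronal activity pattern detection analysis",
    "Grouping of methods to detect patterns in neuronal activity.",
    parents = base("AnalysisStep"))
  o <- onto_add_class(o, steps("ASSETAnalysisSubstep"), "ASSET analysis substep",
    "Grouping of the intermediate substeps of the ASSET analysis.",
    parents = base("AnalysisStep"), abbreviations = "ASSET substep")
  o <- onto_add_class(o, steps("ExecuteASSETAnalysis"), "execute ASSET analysis",
    "Run the Analysis of Sequences of Synchronous Events as a compound analysis.",
    parents = steps("NeuronalActivityPatternDetectionAnalysis"),
    abbreviations = "ASSET")
  o <- onto_add_restriction(o, steps("ExecuteASSETAnalysis"),
    "has_substep_some", base("hasSubstep"), steps("ASSETAnalysisSubstep"))

  # Purpose / directionality normalization axioms
  fcp <- steps("FunctionalConnectivityPurpose")
  o <- onto_add_individual(o, fcp, base("AnalysisPurpose"))
  o <- onto_add_restriction(o, steps("FunctionalConnectivityAnalysis"),
    "equivalent_to_restriction", base("hasPurpose"), fcp)
  o <- onto_add_restriction(o, steps("CoherenceAnalysis"),
    "subclass_of_restriction", base("hasPurpose"), fcp)
  o <- onto_add_restriction(o, steps("CrossCorrelationAnalysis"),
    "subclass_of_restriction", base("hasPurpose"), fcp)
  o <- onto_add_restriction(o, steps("DirectedAnalysis"),
    "equivalent_to_restriction", base("isDirected"), "true", "boolean")
  o <- onto_add_restriction(o, steps("NonDirectedAnalysis"),
    "equivalent_to_restriction", base("isDirected"), "false", "boolean")
  o <- onto_add_restriction(o, steps("CoherenceAnalysis"),
    "subclass_of_restriction", base("isDirected"), "false", "boolean")
  o <- onto_add_restriction(o, steps("CrossCorrelationAnalysis"),
    "subclass_of_restriction", base("isDirected"), "true", "boolean")

  # Data classes
  o <- onto_add_class(o, dat("TimeSeries"), "time series",
    "A sequence of values sampled over time, e.g. an electrode voltage signal.",
    parents = base("Data"))
  o <- onto_add_class(o, dat("PowerSpectralDensity"), "power spectral density",
    "Distribution of the power of a time series over frequency.",
    parents = base("Data"), alt_labels = "spectrum", abbreviations = "PSD")
  o <- onto_add_class(o, dat("SpikeTrain"), "spike train",
    "The ordered spike times of a single neuronal unit within an observation window.",
    parents = base("Data"))
  o <- onto_add_class(o, dat("SpikeTrainSurrogate"), "spike train surrogate",
    "A randomized version of a spike train used to build null distributions.",
    parents = dat("SpikeTrain"))
  o <- onto_add_class(o, dat("InterspikeIntervals"), "interspike intervals",
    "The intervals between consecutive spikes of a spike train.",
    parents = base("Data"), abbreviations = "ISI")
  o <- onto_add_class(o, dat("InterspikeIntervalHistogram"),
    "interspike interval histogram",
    "Histogram of interspike intervals with uniform bin width.",
    parents = base("Data"), abbreviations = "ISIH")
  o <- onto_add_class(o, dat("InterspikeIntervalVariabilityMeasure"),
    "interspike interval variability measure",
    "A statistic quantifying the variability of interspike intervals.",
    parents = base("Data"))
  o <- onto_add_class(o, dat("CV2"), "CV2",
    "Local coefficient of variation of interspike intervals; expectation 1 for a stationary Poisson process.",
    parents = dat("InterspikeIntervalVariabilityMeasure"),
    abbreviations = "CV2")

  # Parameter classes
  params <- c(
    LowPassFrequencyCutoff = "Cutoff frequency of a low-pass filter.",
    FilterOrder = "Order of a digital filter.",
    FrequencyResolution = "Frequency resolution of a spectral estimate.",
    WindowOverlapFactor = "Fractional overlap between consecutive windows.",
    WindowFunction = "Taper applied to each window segment.",
    SamplingFrequency = "Sampling frequency of the input time series.",
    WindowLengthSamples = "Window length in samples.",
    WindowOverlapSamples = "Window overlap in samples.",
    DitheringTime = "Maximum displacement applied when dithering spikes.",
    BinSize = "Width of a histogram bin.",
    FiringRate = "Target firing rate of a generated spike train.",
    ShapeFactor = "Shape factor of a gamma renewal process."
  )
  labels <- c(
    LowPassFrequencyCutoff = "low-pass frequency cutoff",
    FilterOrder = "filter order",
    FrequencyResolution = "frequency resolution",
    WindowOverlapFactor = "window overlap factor",
    WindowFunction = "window function",
    SamplingFrequency = "sampling frequency",
    WindowLengthSamples = "window length in samples",
    WindowOverlapSamples = "window overlap in samples",
    DitheringTime = "dithering time",
    BinSize = "bin size",
    FiringRate = "firing rate",
    ShapeFactor = "shape factor"
  )
  for (nm in names(params)) {
    o <- onto_add_class(o, par(nm), labels[[nm]], params[[nm]],
                        parents = base("AnalysisParameter"))
  }

  # Bibliographic individuals
  o <- onto_add_bib(o, steps("ComputePowerSpectralDensityWelch"),
    bib("Welch1967"),
    paste("Welch, P. The use of fast Fourier transform for the estimation of",
          "power spectra. IEEE Trans. Audio Electroacoust. 15, 70-73 (1967)."),
    "https://doi.org/10.1109/TAU.1967.1161901")
  o <- onto_add_bib(o, steps("ComputePowerSpectralDensityMultitaper"),
    bib("Thomson1982"),
    paste("Thomson, D. J. Spectrum estimation and harmonic analysis.",
          "Proc. IEEE 70, 1055-1096 (1982)."),
    "https://doi.org/10.1109/PROC.1982.12433")
  o <- onto_add_bib(o, steps("ComputeCV2"),
    bib("Holt1996"),
    paste("Holt, G. R., Softky, W. R., Koch, C. & Douglas, R. J. Comparison of",
          "discharge variability in vitro and in vivo in cat visual cortex",
          "neurons. J. Neurophysiol. 75, 1806-1814 (1996)."),
    "https://doi.org/10.1152/jn.1996.75.5.1806")
  o <- onto_add_bib(o, steps("SpikeTrainSurrogateGeneration"),
    bib("Stella2022"),
    paste("Stella, A., Bouss, P., Palm, G. & Gruen, S. Comparing surrogates to",
          "evaluate precisely timed higher-order spike correlations.",
          "eNeuro 9, ENEURO.0505-21.2022 (2022)."),
    "https://doi.org/10.1523/ENEURO.0505-21.2022")

  o
}

# Inference -------------------------------------------------------------------

subclass_closure <- function(pairs, universe) {
  # reflexive-transitive closure of subclass pairs over the named classes
  refl <- tibble::tibble(sub = universe, super = universe)
  rel <- dplyr::distinct(dplyr::bind_rows(pairs, refl))
  repeat {
    step <- dplyr::inner_join(rel, rel, by = c("super" = "sub"),
                              relationship = "many-to-many")
    step <- dplyr::distinct(tibble::tibble(sub = step$sub, super = step$super.y))
    new <- dplyr::distinct(dplyr::bind_rows(rel, step))
    if (nrow(new) == nrow(rel)) break
    rel <- new
  }
  rel
}

#' Materialize the inferences entailed by the normalization axioms
#'
#' Computes the least fixpoint of four rules in the spirit of the OWL2-RL
#' profile: (i) subclass reflexivity and transitivity; (ii) a class asserted
#' under a value restriction that some grouping class is equivalent to becomes
#' a subclass of the grouping class; (iii) individual typing is closed over the
#' inferred hierarchy; (iv) any individual carrying a `hasSubstep` assertion is
#' typed as a compound analysis.
#'
#' @param onto A `neao_ontology`.
#' @return The ontology with `inferred` (subclass pairs) and closed individual
#'   typing.
#' @export
materialize_inferences <- function(onto) {
  universe <- onto$classes$uri
  asserted <- onto$subclass

  restr_key <- function(df) paste(df$property, df$value, df$value_kind)
  holders <- onto$restrictions[onto$restrictions$kind %in%
    c("subclass_of_restriction", "equivalent_to_restriction"), ]
  groups <- onto$restrictions[onto$restrictions$kind ==
                                "equivalent_to_restriction", ]

  rel <- subclass_closure(asserted, universe)
  repeat {
    # rule (ii): C under restriction r, G equivalent to r  =>  C subclass-of G
    hk <- restr_key(holders)
    gk <- restr_key(groups)
    add <- tibble::tibble(sub = character(), super = character())
    if (nrow(holders) && nrow(groups)) {
      m <- dplyr::inner_join(
        tibble::tibble(sub = holders$class, key = hk),
        tibble::tibble(super = groups$class, key = gk),
        by = "key", relationship = "many-to-many"
      )
      add <- dplyr::distinct(m[m$sub != m$super, c("sub", "super")])
    }
    new <- subclass_closure(dplyr::bind_rows(rel, add), universe)
    if (nrow(new) == nrow(rel)) break
    rel <- new
  }

  onto$inferred <- dplyr::arrange(rel, .data$sub, .data$super)

  # rules (iii)/(iv): individual typing
  ind <- onto$individuals[!is.na(onto$individuals$type), ]
  has_substep <- unique(onto$statements$s[
    onto$statements$p == ns_iri("neao_base", "hasSubstep")])
  if (length(has_substep)) {
    ind <- dplyr::bind_rows(ind, tibble::tibble(
      uri = has_substep, type = ns_iri("neao_steps", "CompoundAnalysis")))
  }
  if (nrow(ind)) {
    closed <- dplyr::inner_join(ind, rel, by = c(type = "sub"),
                                relationship = "many-to-many")
    ind <- dplyr::distinct(dplyr::bind_rows(
      ind, tibble::tibble(uri = closed$uri, type = closed$super)))
  }
  others <- onto$individuals[is.na(onto$individuals$type), ]
  others <- others[!others$uri %in% ind$uri, ]
  onto$individuals <- dplyr::distinct(dplyr::bind_rows(ind, others))
  onto
}

#' Test an (inferred) subclass relationship
#' @param onto A materialized `neao_ontology`.
#' @param sub,super Class IRIs (or CURIEs resolved against NEAO namespaces).
#' @return Logical scalar.
#' @export
is_subclass_of <- function(onto, sub, super) {
  rel <- onto_inferred(onto)
  sub <- expand_curie(sub, neao_namespaces())
  super <- expand_curie(super, neao_namespaces())
  any(rel$sub == sub & rel$super == super)
}

onto_inferred <- function(onto) {
  if (is.null(onto$inferred)) {
    stop("ontology inferences not materialized; call materialize_inferences()",
         call. = FALSE)
  }
  onto$inferred
}

#' All (inferred) subclasses of a class, including itself
#' @param onto A materialized `neao_ontology`.
#' @param class Class IRI or CURIE.
#' @return Character vector of class IRIs.
#' @export
subclasses_of <- function(onto, class) {
  class <- expand_curie(class, neao_namespaces())
  rel <- onto_inferred(onto)
  unique(rel$sub[rel$super == class])
}

#' Look up classes by preferred label, alternative label, or abbreviation
#'
#' Matching is case-insensitive and exact (no partial matches): the lookup
#' consolidates the diversity of terms used in the literature onto the
#' controlled vocabulary.
#'
#' @param onto A `neao_ontology`.
#' @param token Non-empty search string.
#' @return Character vector of class IRIs (possibly empty).
#' @export
lookup_term <- function(onto, token) {
  stopifnot(is.character(token), length(token) == 1, nzchar(token))
  t <- tolower(token)
  hits <- c(
    onto$classes$uri[tolower(onto$classes$pref_label) == t],
    onto$alt_labels$uri[tolower(onto$alt_labels$label) == t],
    onto$abbreviations$uri[tolower(onto$abbreviations$abbrev) == t]
  )
  sort(unique(hits))
}

# Serialization ---------------------------------------------------------------

restriction_skolem <- function(property, value, value_kind) {
  paste0("_:r", substr(cli::hash_sha256(paste(property, value, value_kind)),
                       1, 12))
}

#' Convert the ontology to RDF triples
#' @param onto A `neao_ontology`.
#' @param include_inferred Also emit the materialized subclass closure (as
#'   `rdfs:subClassOf` triples, excluding the reflexive pairs).
#' @return An `rdf_graph`.
#' @export
ontology_to_rdf <- function(onto, include_inferred = FALSE) {
  rdf <- function(x) ns_iri("rdf", x)
  rdfs <- function(x) ns_iri("rdfs", x)
  owl <- function(x) ns_iri("owl", x)
  skos <- function(x) ns_iri("skos", x)

  g <- rdf_graph()
  cl <- onto$classes
  g <- rdf_add(g, cl$uri, rdf("type"), owl("Class"))
  g <- rdf_add(g, cl$uri, skos("prefLabel"), cl$pref_label,
               "literal", "string")
  has_comment <- nzchar(cl$comment)
  if (any(has_comment)) {
    g <- rdf_add(g, cl$uri[has_comment], rdfs("comment"),
                 cl$comment[has_comment], "literal", "string")
  }
  if (nrow(onto$alt_labels)) {
    g <- rdf_add(g, onto$alt_labels$uri, skos("altLabel"),
                 onto$alt_labels$label, "literal", "string")
  }
  if (nrow(onto$abbreviations)) {
    g <- rdf_add(g, onto$abbreviations$uri, ns_iri("neao_base", "abbreviation"),
                 onto$abbreviations$abbrev, "literal", "string")
  }
  pk <- c(object = "ObjectProperty", data = "DatatypeProperty",
          annotation = "AnnotationProperty")
  g <- rdf_add(g, onto$properties$uri, rdf("type"),
               owl(unname(pk[onto$properties$kind])))
  if (nrow(onto$subclass)) {
    g <- rdf_add(g, onto$subclass$sub, rdfs("subClassOf"), onto$subclass$super)
  }
  if (nrow(onto$restrictions)) {
    r <- onto$restrictions
    bn <- restriction_skolem(r$property, r$value, r$value_kind)
    g <- rdf_add(g, bn, rdf("type"), owl("Restriction"))
    g <- rdf_add(g, bn, owl("onProperty"), r$property)
    some <- r$kind == "has_substep_some"
    if (any(some)) g <- rdf_add(g, bn[some], owl("someValuesFrom"), r$value[some])
    hv <- !some
    if (any(hv)) {
      g <- rdf_add(g, bn[hv], owl("hasValue"), r$value[hv],
                   ifelse(r$value_kind[hv] == "boolean", "literal", "iri"),
                   ifelse(r$value_kind[hv] == "boolean", "boolean",
                          NA_character_))
    }
    link <- ifelse(r$kind == "equivalent_to_restriction",
                   owl("equivalentClass"), rdfs("subClassOf"))
    g <- rdf_add(g, r$class, link, bn)
  }
  ind <- onto$individuals[!is.na(onto$individuals$type), ]
  if (nrow(ind)) g <- rdf_add(g, ind$uri, rdf("type"), ind$type)
  if (nrow(onto$statements)) {
    g <- rdf_add(g, onto$statements$s, onto$statements$p, onto$statements$o)
  }
  if (nrow(onto$bib)) {
    b <- onto$bib
    g <- rdf_add(g, b$class_uri, ns_iri("neao_base", "hasBibliographicReference"),
                 b$ref_uri)
    g <- rdf_add(g, b$ref_uri, rdf("type"), ns_iri("biro", "BibliographicReference"))
    g <- rdf_add(g, b$ref_uri, ns_iri("dcterms", "bibliographicCitation"),
                 b$citation, "literal", "string")
    g <- rdf_add(g, b$ref_uri, ns_iri("biro", "references"), b$resource)
  }
  if (include_inferred) {
    rel <- onto_inferred(onto)
    rel <- rel[rel$sub != rel$super, ]
    if (nrow(rel)) g <- rdf_add(g, rel$sub, ns_iri("rdfs", "subClassOf"),
                                rel$super)
  }
  g
}

#' Serialize the ontology to Turtle
#' @param onto A `neao_ontology`.
#' @param format Serialization format; only `"turtle"` is supported.
#' @param path Optional output file.
#' @return Character vector of Turtle lines.
#' @export
serialize_ontology <- function(onto, format = "turtle", path = NULL) {
  if (!identical(format, "turtle")) {
    stop(sprintf("unsupported ontology serialization format: %s", format),
         call. = FALSE)
  }
  write_turtle(ontology_to_rdf(onto), path = path)
}

#' Parse a Turtle ontology document back into a `neao_ontology`
#'
#' Inverse of [serialize_ontology()] for documents produced by this package:
#' classes, annotations, axioms (including value restrictions), individuals
#' and bibliographic references are reconstructed.
#'
#' @param text Turtle document (character vector of lines).
#' @return A `neao_ontology` (inferences not materialized).
#' @export
parse_ontology <- function(text) {
  g <- tibble::as_tibble(read_turtle(text))
  rdf <- function(x) ns_iri("rdf", x)
  rdfs <- function(x) ns_iri("rdfs", x)
  owl <- function(x) ns_iri("owl", x)
  skos <- function(x) ns_iri("skos", x)

  o <- new_ontology()
  cls <- g$s[g$p == rdf("type") & g$o == owl("Class")]
  pref <- g[g$p == skos("prefLabel"), ]
  comment <- g[g$p == rdfs("comment"), ]
  o$classes <- tibble::tibble(
    uri = cls,
    pref_label = pref$o[match(cls, pref$s)],
    comment = dplyr::coalesce(comment$o[match(cls, comment$s)], "")
  )
  alt <- g[g$p == skos("altLabel"), ]
  o$alt_labels <- tibble::tibble(uri = alt$s, label = alt$o)
  abbr <- g[g$p == ns_iri("neao_base", "abbreviation"), ]
  o$abbreviations <- tibble::tibble(uri = abbr$s, abbrev = abbr$o)

  ptypes <- c(ObjectProperty = "object", DatatypeProperty = "data",
              AnnotationProperty = "annotation")
  for (nm in names(ptypes)) {
    uris <- g$s[g$p == rdf("type") & g$o == owl(nm)]
    if (length(uris)) {
      o$properties <- dplyr::bind_rows(
        o$properties, tibble::tibble(uri = uris, kind = ptypes[[nm]]))
    }
  }

  restr_nodes <- g$s[g$p == rdf("type") & g$o == owl("Restriction")]
  sub <- g[g$p == rdfs("subClassOf"), ]
  named_sub <- sub[!sub$o %in% restr_nodes, ]
  o$subclass <- tibble::tibble(sub = named_sub$s, super = named_sub$o)

  on_prop <- g[g$p == owl("onProperty"), ]
  has_val <- g[g$p == owl("hasValue"), ]
  some_val <- g[g$p == owl("someValuesFrom"), ]
  restr_sub <- sub[sub$o %in% restr_nodes, ]
  equiv <- g[g$p == owl("equivalentClass"), ]
  link <- dplyr::bind_rows(
    tibble::tibble(class = restr_sub$s, node = restr_sub$o,
                   link = "subclass_of_restriction"),
    tibble::tibble(class = equiv$s, node = equiv$o,
                   link = "equivalent_to_restriction")
  )
  if (nrow(link)) {
    prop <- on_prop$o[match(link$node, on_prop$s)]
    hv_i <- match(link$node, has_val$s)
    sv_i <- match(link$node, some_val$s)
    kind <- ifelse(!is.na(sv_i), "has_substep_some", link$link)
    value <- ifelse(!is.na(sv_i), some_val$o[sv_i], has_val$o[hv_i])
    vkind <- ifelse(!is.na(sv_i), "iri",
                    ifelse(has_val$o_kind[hv_i] == "literal", "boolean", "iri"))
    o$restrictions <- tibble::tibble(class = link$class, kind = kind,
                                     property = prop, value = value,
                                     value_kind = vkind)
  }

  bib_refs <- g$s[g$p == rdf("type") & g$o == ns_iri("biro", "BibliographicReference")]
  links <- g[g$p == ns_iri("neao_base", "hasBibliographicReference"), ]
  cites <- g[g$p == ns_iri("dcterms", "bibliographicCitation"), ]
  res <- g[g$p == ns_iri("biro", "references"), ]
  if (nrow(links)) {
    o$bib <- tibble::tibble(
      class_uri = links$s, ref_uri = links$o,
      citation = cites$o[match(links$o, cites$s)],
      resource = res$o[match(links$o, res$s)]
    )
  }

  typed <- g[g$p == rdf("type") &
               !g$o %in% c(owl("Class"), owl("Restriction"),
                           owl("ObjectProperty"), owl("DatatypeProperty"),
                           owl("AnnotationProperty"),
                           ns_iri("biro", "BibliographicReference")), ]
  typed <- typed[!startsWith(typed$s, "_:"), ]
  o$individuals <- tibble::tibble(uri = typed$s, type = typed$o)

  other_props <- o$properties$uri[o$properties$kind == "object"]
  stmts <- g[g$p %in% other_props & g$o_kind == "iri" &
               !g$s %in% c(cls, restr_nodes), ]
  stmts <- stmts[!stmts$p %in% c(owl("onProperty")), ]
  o$statements <- tibble::tibble(s = stmts$s, p = stmts$p, o = stmts$o)
  o
}

#' @export
tidy.neao_ontology <- function(x, ...) {
  dplyr::left_join(
    x$classes,
    dplyr::summarise(dplyr::group_by(x$abbreviations, .data$uri),
                     abbreviations = paste(.data$abbrev, collapse = "; ")),
    by = "uri"
  )
}

#' @export
glance.neao_ontology <- function(x, ...) {
  tibble::tibble(
    n_classes = nrow(x$classes),
    n_properties = nrow(x$properties),
    n_axioms = nrow(x$subclass) + nrow(x$restrictions),
    n_individuals = dplyr::n_distinct(x$individuals$uri),
    materialized = !is.null(x$inferred)
  )
}

#' @export
print.neao_ontology <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<neao_ontology> %d classes, %d properties, %d axioms, %d individuals%s\n",
    g$n_classes, g$n_properties, g$n_axioms, g$n_individuals,
    if (g$materialized) " (inferences materialized)" else ""))
  invisible(x)
}
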