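# Mapping captured provenance into NEAO descriptions.
#
# The knowledge graph combines the provenance triples with the ontology
# triples and an OWL2-RL style materialization (subclass closure as
# rdfs:subClassOf, plus type closure of individuals). The mapping rules then
# rewrite the capture vocabulary into NEAO properties:
#
#   NEAO property            capture-side pattern (guarded)
#   hasInput                 prov:used          (step-typed exec, Data object)
#   hasOutput                prov:generated     (step-typed exec, Data object)
#   usesParameter            cap:hasParameter   (AnalysisParameter node)
#   isImplementedIn          cap:usedFunction   (-> neao Function individual)
#   nameInDefinition         cap:functionName
#
# plus construction of SoftwarePackage individuals (packageName /
# packageVersion) and the container-output rule (hasOutput to Data-typed
# members of generated containers). All rules add triples only, and are
# idempotent. Equivalent SPARQL UPDATE texts ship under inst/sparql.

#' Build the knowledge graph from provenance and ontology
#'
#' Concatenates one or more provenance graphs with the ontology triples,
#' materializes the inferred subclass closure as `rdfs:subClassOf` triples,
#' and closes `rdf:type` assertions over the hierarchy (so e.g. every
#' execution typed `ComputePowerSpectralDensityWelch` is also typed
#' `PowerSpectralDensityAnalysis`, `SpectralAnalysis`, and `AnalysisStep`).
#'
#' @param prov An `rdf_graph` or list of them.
#' @param onto A materialized `neao_ontology`.
#' @return An `rdf_graph` (the knowledge graph).
#' @export
build_knowledge_graph <- function(prov, onto) {
  if (inherits(prov, "rdf_graph")) prov <- list(prov)
  onto_rdf <- ontology_to_rdf(onto, include_inferred = TRUE)
  kg <- dplyr::distinct(dplyr::bind_rows(
    c(lapply(prov, tibble::as_tibble), list(tibble::as_tibble(onto_rdf)))
  ))

  # type closure over the inferred hierarchy
  rel <- onto_inferred(onto)
  rel <- rel[rel$sub != rel$super, ]
  rdf_type <- ns_iri("rdf", "type")
  types <- kg[kg$p == rdf_type & kg$o_kind == "iri", c("s", "o")]
  closed <- dplyr::inner_join(types, rel, by = c(o = "sub"),
                              relationship = "many-to-many")
  if (nrow(closed)) {
    kg <- dplyr::distinct(dplyr::bind_rows(kg, tibble::tibble(
      s = closed$s, p = rdf_type, o = closed$super,
      o_kind = "iri", o_dtype = NA_character_
    )))
  }
  rdf_graph(kg)
}

typed_as <- function(tr, class_iri) {
  unique(tr$s[tr$p == ns_iri("rdf", "type") & tr$o == class_iri])
}

#' Apply the NEAO property mappings to a knowledge graph
#'
#' For every execution typed with an `AnalysisStep` subclass, adds `hasInput`
#' per `prov:used` edge whose object is typed `Data`, `hasOutput` per
#' `prov:generated` edge likewise, `usesParameter` to each parameter node
#' typed `AnalysisParameter` (exposing the captured value via `rdf:value`),
#' `isImplementedIn` to a NEAO `Function` individual with `nameInDefinition`,
#' and `isImplementedInPackage` to a `SoftwarePackage` individual with
#' `packageName`/`packageVersion`. Original triples are retained; the mapping
#' is monotone and idempotent.
#'
#' @param kg Knowledge graph from [build_knowledge_graph()].
#' @param onto The materialized ontology (unused beyond the materialization
#'   already merged into the graph; kept for interface symmetry).
#' @return The augmented `rdf_graph`.
#' @export
apply_mappings <- function(kg, onto = NULL) {
  tr <- tibble::as_tibble(kg)
  base <- function(x) ns_iri("neao_base", x)
  cap <- function(x) ns_iri("cap", x)

  steps <- typed_as(tr, base("AnalysisStep"))
  data_nodes <- typed_as(tr, base("Data"))
  param_nodes <- typed_as(tr, base("AnalysisParameter"))

  new <- list()
  emit <- function(s, p, o, o_kind = "iri", o_dtype = NA_character_) {
    if (!length(s)) return()
    new[[length(new) + 1L]] <<- tibble::tibble(
      s = s, p = p, o = o, o_kind = o_kind, o_dtype = o_dtype)
  }

  used <- tr[tr$p == ns_iri("prov", "used") & tr$s %in% steps &
               tr$o %in% data_nodes, ]
  emit(used$s, base("hasInput"), used$o)

  gen <- tr[tr$p == ns_iri("prov", "generated") & tr$s %in% steps &
              tr$o %in% data_nodes, ]
  emit(gen$s, base("hasOutput"), gen$o)

  par <- tr[tr$p == cap("hasParameter") & tr$s %in% steps &
              tr$o %in% param_nodes, ]
  emit(par$s, base("usesParameter"), par$o)
  ptext <- tr[tr$p == cap("pairValueText") & tr$s %in% par$o, ]
  emit(ptext$s, ns_iri("rdf", "value"), ptext$o, "literal", "string")

  fn <- tr[tr$p == cap("usedFunction") & tr$s %in% steps, ]
  emit(fn$s, base("isImplementedIn"), fn$o)
  fnodes <- unique(fn$o)
  emit(fnodes, ns_iri("rdf", "type"), base("Function"))
  fname <- tr[tr$p == cap("functionName") & tr$s %in% fnodes, ]
  emit(fname$s, base("nameInDefinition"), fname$o, "literal", "string")

  inpkg <- tr[tr$p == cap("inPackage") & tr$s %in% fnodes, ]
  emit(inpkg$s, base("isImplementedInPackage"), inpkg$o)
  pkgs <- unique(inpkg$o)
  emit(pkgs, ns_iri("rdf", "type"), base("SoftwarePackage"))
  pname <- tr[tr$p == cap("packageName") & tr$s %in% pkgs, ]
  emit(pname$s, base("packageName"), pname$o, "literal", "string")
  pver <- tr[tr$p == cap("packageVersion") & tr$s %in% pkgs, ]
  emit(pver$s, base("packageVersion"), pver$o, "literal", "string")

  out <- dplyr::distinct(dplyr::bind_rows(c(list(tr), new)))
  rdf_graph(out, prefixes = rdf_prefixes(kg))
}

#' Map container outputs to the generating analysis step
#'
#' For each execution that generated a container whose members (linked via
#' `prov:hadMember`) carry NEAO `Data` types, adds a `hasOutput` edge from
#' the execution to each member. Idempotent.
#'
#' @param kg Knowledge graph (after [apply_mappings()]).
#' @param onto Materialized ontology (interface symmetry; the materialization
#'   in the graph is used).
#' @return The augmented `rdf_graph`.
#' @export
map_container_outputs <- function(kg, onto = NULL) {
  tr <- tibble::as_tibble(kg)
  base <- function(x) ns_iri("neao_base", x)
  steps <- typed_as(tr, base("AnalysisStep"))
  data_nodes <- typed_as(tr, base("Data"))

  gen <- tr[tr$p == ns_iri("prov", "generated") & tr$s %in% steps,
            c("s", "o")]
  mem <- tr[tr$p == ns_iri("prov", "hadMember"), c("s", "o")]
  hit <- dplyr::inner_join(gen, mem, by = c(o = "s"),
                           relationship = "many-to-many")
  hit <- hit[hit$o.y %in% data_nodes, ]
  if (nrow(hit)) {
    tr <- dplyr::distinct(dplyr::bind_rows(tr, tibble::tibble(
      s = hit$s, p = base("hasOutput"), o = hit$o.y,
      o_kind = "iri", o_dtype = NA_character_
    )))
  }
  rdf_graph(tr, prefixes = rdf_prefixes(kg))
}

#' Apply the full NEAO mapping via the shipped SPARQL UPDATE texts
#'
#' Executes the SPARQL UPDATE resources under `inst/sparql` in order; the
#' result is identical to [apply_mappings()] followed by
#' [map_container_outputs()] (the equivalence is exercised by the test suite).
#'
#' @param kg Knowledge graph from [build_knowledge_graph()].
#' @return The augmented `rdf_graph`.
#' @export
apply_mappings_sparql <- function(kg) {
  updates <- c(
    "map_has_input.ru", "map_has_output.ru", "map_uses_parameter.ru",
    "map_parameter_value.ru", "map_implemented_in.ru",
    "map_function_individuals.ru", "map_name_in_definition.ru",
    "map_software_package.ru", "map_container_outputs.ru"
  )
  for (u in updates) {
    kg <- sparql_update(kg, sparql_resource(u))
  }
  kg
}
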