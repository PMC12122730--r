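# Semantic annotation registry: attach NEAO classes to analysis routines.
#
# A routine is identified by a caller-supplied "module.name" string. Its
# annotation record maps the routine to an AnalysisStep class, each named
# argument to a Data or AnalysisParameter class, and each return (0-based
# index) to a Data class. Container returns mark indices whose *elements*
# carry the class (e.g. a list of surrogate spike trains).

#' Expand a CURIE against a namespace map
#'
#' Full IRIs (and blank-node labels) pass through unchanged; `prefix:local`
#' tokens are resolved against `namespaces`. Idempotent.
#'
#' @param token CURIE or IRI (character vector).
#' @param namespaces Named character vector of prefix -> IRI.
#' @return Character vector of IRIs.
#' @export
expand_curie <- function(token, namespaces = neao_namespaces()) {
  vapply(token, function(tok) {
    if (grepl("^(https?|urn|file|tag|mailto):", tok) || startsWith(tok, "_:")) {
      return(tok)
    }
    if (!grepl("^[A-Za-z_][A-Za-z0-9_.-]*:", tok)) return(tok)
    pfx <- sub(":.*$", "", tok)
    if (!pfx %in% names(namespaces)) {
      stop(sprintf("unknown CURIE prefix '%s'", pfx), call. = FALSE)
    }
    paste0(namespaces[[pfx]], sub("^[^:]*:", "", tok))
  }, character(1), USE.NAMES = FALSE)
}

#' Create an annotation record for an analysis routine
#'
#' @param step_class CURIE or IRI of the `AnalysisStep` subclass, or `NULL`
#'   for an unannotated routine.
#' @param arguments Named list/vector: argument name -> CURIE/IRI of the Data
#'   or AnalysisParameter class.
#' @param returns List/vector keyed by 0-based return index (as names, e.g.
#'   `"0"`): CURIE/IRI of the Data class of that return.
#' @param container_returns Integer vector of 0-based return indices whose
#'   value is a container whose *elements* carry the class given in `returns`.
#' @param namespaces Namespace map used to resolve CURIEs.
#' @return An `annotation_record`.
#' @export
neao_annotation <- function(step_class = NULL, arguments = list(),
                            returns = list(), container_returns = integer(0),
                            namespaces = neao_namespaces()) {
  arguments <- as.list(arguments)
  returns <- as.list(returns)
  if (length(arguments) && (is.null(names(arguments)) ||
                            anyDuplicated(names(arguments)))) {
    stop("annotation arguments must have unique names", call. = FALSE)
  }
  if (length(returns)) {
    idx <- suppressWarnings(as.integer(names(returns)))
    if (anyNA(idx) || any(idx < 0)) {
      stop("annotation return indices must be non-negative integers",
           call. = FALSE)
    }
  }
  structure(list(step_class = step_class, arguments = arguments,
                 returns = returns,
                 container_returns = as.integer(container_returns),
                 namespaces = namespaces),
            class = "annotation_record")
}

expand_record <- function(record) {
  ns <- record$namespaces
  if (!is.null(record$step_class)) {
    record$step_class <- expand_curie(record$step_class, ns)
  }
  record$arguments <- lapply(record$arguments, expand_curie, namespaces = ns)
  record$returns <- lapply(record$returns, expand_curie, namespaces = ns)
  record
}

#' Create an empty annotation registry
#' @return An `annotation_registry` (environment-backed).
#' @export
annotation_registry <- function() {
  structure(new.env(parent = emptyenv()), class = "annotation_registry")
}

#' Register an annotation record for a routine
#'
#' CURIEs are validated against the record's namespace map at registration
#' time; an unresolvable prefix is an error. Re-registering a routine replaces
#' the previous record with a warning.
#'
#' @param registry An `annotation_registry`.
#' @param routine_id Non-empty routine identifier ("module.name").
#' @param record An `annotation_record` (see [neao_annotation()]).
#' @return The registry, invisibly.
#' @export
register_annotation <- function(registry, routine_id, record) {
  stopifnot(inherits(registry, "annotation_registry"),
            is.character(routine_id), length(routine_id) == 1,
            nzchar(routine_id), inherits(record, "annotation_record"))
  expanded <- expand_record(record)  # errors on unknown prefix
  if (exists(routine_id, envir = registry, inherits = FALSE)) {
    warning(sprintf("replacing existing annotation for routine '%s'",
                    routine_id), call. = FALSE)
  }
  assign(routine_id, expanded, envir = registry)
  invisible(registry)
}

#' Retrieve the annotation record for a routine
#' @param registry An `annotation_registry`.
#' @param routine_id Routine identifier.
#' @return The registered `annotation_record` with all CURIEs expanded to
#'   IRIs, or `NULL` when the routine is unannotated.
#' @export
get_annotation <- function(registry, routine_id) {
  if (is.null(registry)) return(NULL)
  if (!exists(routine_id, envir = registry, inherits = FALSE)) return(NULL)
  get(routine_id, envir = registry, inherits = FALSE)
}

#' Load annotation records from a YAML configuration file
#'
#' The file maps routine ids to records with keys `step_class`, `arguments`,
#' `returns`, `container_returns`, and optionally `namespaces` (merged over
#' the NEAO defaults). Equivalent to programmatic registration.
#'
#' @param path YAML file path.
#' @param registry Registry to fill (a fresh one by default).
#' @return The registry.
#' @export
read_annotation_config <- function(path, registry = annotation_registry()) {
  cfg <- yaml::read_yaml(path)
  for (routine_id in names(cfg)) {
    item <- cfg[[routine_id]]
    ns <- neao_namespaces()
    if (!is.null(item$namespaces)) {
      extra <- unlist(item$namespaces)
      ns[names(extra)] <- extra
    }
    rec <- neao_annotation(
      step_class = item$step_class,
      arguments = if (is.null(item$arguments)) list() else item$arguments,
      returns = if (is.null(item$returns)) list() else item$returns,
      container_returns = if (is.null(item$container_returns)) integer(0)
                          else unlist(item$container_returns),
      namespaces = ns
    )
    register_annotation(registry, routine_id, rec)
  }
  registry
}
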