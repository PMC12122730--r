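# Provenance capture: record executions of (annotated) analysis routines and
# serialize them as PROV-style RDF.
#
# Entities are content-addressed: the IRI is derived from a SHA-256 digest of
# the serialized value, so identical values map to the same node within and
# across runs (stable join keys without object identity). Executions are
# numbered sequentially within a run context. File reads/writes are recorded
# as load/save steps linking file nodes (keyed by path) to data entities.

# Physical quantity helper: a value with a unit, carried into parameter
# literals (value and unit are separate literals; a pre-formatted text
# rendering is captured as well for query tables).

#' Attach a physical unit to a value
#' @param value Numeric scalar.
#' @param unit Unit string (e.g. "Hz", "ms").
#' @return A `quantity` object.
#' @export
qty <- function(value, unit) {
  structure(list(value = as.numeric(value), unit = unit), class = "quantity")
}

#' @export
format.quantity <- function(x, ...) sprintf("%.1f %s", x$value, x$unit)

#' @export
print.quantity <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

qty_value <- function(x) if (inherits(x, "quantity")) x$value else x

#' Convert a quantity to seconds
#' @param x A `quantity` with unit "s" or "ms", or a plain numeric (seconds).
#' @return Numeric scalar in seconds.
#' @export
as_seconds <- function(x) {
  if (!inherits(x, "quantity")) return(as.numeric(x))
  switch(x$unit,
         s = x$value,
         ms = x$value / 1000,
         stop(sprintf("cannot convert unit '%s' to seconds", x$unit),
              call. = FALSE))
}

format_param_text <- function(x) {
  if (inherits(x, "quantity")) return(format(x))
  if (is.character(x)) return(x)
  if (is.integer(x)) return(sprintf("%d", x))
  if (is.logical(x)) return(ifelse(x, "true", "false"))
  sprintf("%.1f", x)
}

#' Content digest of an R value
#' @param value Any R value.
#' @return SHA-256 hex digest of its canonical serialization.
#' @export
content_digest <- function(value) {
  cli::hash_raw_sha256(serialize(value, NULL, xdr = FALSE))
}

#' Reference an already-captured entity
#'
#' Wraps a value together with its known entity IRI (from a previous
#' execution record) so [track_execution()] can link it as an input without
#' re-serializing and re-digesting the value. The routine still receives the
#' plain value.
#'
#' @param id Entity IRI.
#' @param value The value it addresses.
#' @return An `entity_ref`.
#' @export
entity_ref <- function(id, value) {
  structure(list(id = id, value = value), class = "entity_ref")
}

unwrap_value <- function(v) {
  if (inherits(v, "entity_ref")) return(v$value)
  if (inherits(v, "multi_input")) {
    return(structure(lapply(unclass(v), unwrap_value), class = "multi_input"))
  }
  v
}

input_entity_id <- function(ctx, v) {
  if (inherits(v, "entity_ref")) v$id else ctx_entity(ctx, v)
}

#' Mark a list as a collection of separate inputs
#'
#' Inside [track_execution()], a `multi_input()` argument contributes one
#' input entity per element (all typed by the argument's annotation class)
#' instead of a single entity for the whole list.
#'
#' @param x A list of values.
#' @return The list with class `multi_input`.
#' @export
multi_input <- function(x) structure(as.list(x), class = "multi_input")

#' Create a provenance run context
#'
#' @param run_id Identifier of this run (used in execution IRIs).
#' @param out_root Output root directory; recorded file paths are stored
#'   relative to it (POSIX style) for reproducibility.
#' @param registry Optional `annotation_registry` supplying NEAO annotations.
#' @param seed Seed associated with the run (recorded for reference).
#' @param default_package Character vector `c(name=, version=)` describing the
#'   software package attributed to executions unless overridden per call.
#' @return A `run_context` (environment-backed).
#' @export
run_context <- function(run_id, out_root = ".", registry = NULL, seed = NULL,
                        default_package = c(name = "neaokg",
                                            version = "0.1.0")) {
  ctx <- new.env(parent = emptyenv())
  ctx$run_id <- run_id
  ctx$out_root <- normalizePath(out_root, winslash = "/", mustWork = FALSE)
  ctx$registry <- registry
  ctx$seed <- seed
  ctx$default_package <- default_package
  ctx$records <- list()
  ctx$seq <- 0L
  ctx$entity_ids <- new.env(parent = emptyenv())   # digest -> IRI
  ctx$entity_types <- new.env(parent = emptyenv()) # IRI -> class IRIs
  class(ctx) <- "run_context"
  ctx
}

ctx_entity <- function(ctx, value) {
  # Entity IRIs are content-addressed within the run: identical values map to
  # one node inside a run, while different runs keep separate data branches
  # (numerically identical intermediates are common — e.g. a trial-shifted
  # surrogate whose ISI vector equals the original's — and must not merge
  # derivation chains across analyses). Cross-run joins happen on file nodes,
  # which are keyed by path alone.
  digest <- content_digest(value)
  id <- get0(digest, envir = ctx$entity_ids, inherits = FALSE)
  if (is.null(id)) {
    id <- paste0(ns_iri("cap", "entity/"), ctx$run_id, "/", digest)
    assign(digest, id, envir = ctx$entity_ids)
  }
  id
}

ctx_add_type <- function(ctx, id, class_iri) {
  cur <- get0(id, envir = ctx$entity_types, inherits = FALSE)
  assign(id, unique(c(cur, class_iri)), envir = ctx$entity_types)
}

relative_path <- function(path, root) {
  path <- normalizePath(path, winslash = "/", mustWork = FALSE)
  if (startsWith(path, paste0(root, "/"))) {
    substring(path, nchar(root) + 2L)
  } else {
    path
  }
}

file_node_iri <- function(rel_path) {
  paste0(ns_iri("cap", "file/"), cli::hash_sha256(rel_path))
}

#' Execute a routine and record its provenance
#'
#' The routine is executed exactly once via `do.call(fn, c(inputs, params))`.
#' Input and output values are content-addressed into data entities; parameter
#' values are stored as literals. When the routine's annotation declares
#' container returns, the elements of the returned container become member
#' entities linked by `prov:hadMember` pairs. A failing routine leaves a
#' partial record flagged as failed and re-throws the error.
#'
#' @param ctx A `run_context`.
#' @param routine_id Routine identifier (matched against the registry).
#' @param fn The function implementing the routine.
#' @param inputs Named list of data inputs (names matched against the
#'   annotation's argument map for semantic typing).
#' @param params Named list of parameters ([qty()] values keep their units).
#' @param package Optional `c(name=, version=)` software identity override.
#' @return A list with `value` (the routine's return value) and `record` (the
#'   `execution_record`).
#' @export
track_execution <- function(ctx, routine_id, fn, inputs = list(),
                            params = list(), package = NULL) {
  stopifnot(inherits(ctx, "run_context"), nzchar(routine_id))
  if (length(params) && (is.null(names(params)) ||
                         any(!nzchar(names(params))))) {
    stop("parameters must be named", call. = FALSE)
  }
  if (length(intersect(names(inputs), names(params)))) {
    stop("parameter names must be disjoint from input names", call. = FALSE)
  }
  annotation <- get_annotation(ctx$registry, routine_id)
  pkg <- if (is.null(package)) ctx$default_package else package

  # A multi_input() argument contributes one input entity per element (all
  # sharing the argument name for semantic typing).
  input_ids <- character(0)
  input_args <- character(0)
  for (nm in names(inputs)) {
    v <- inputs[[nm]]
    if (inherits(v, "multi_input")) {
      ids <- vapply(unclass(v), function(el) input_entity_id(ctx, el),
                    character(1))
      input_ids <- c(input_ids, unname(ids))
      input_args <- c(input_args, rep(nm, length(ids)))
    } else {
      input_ids <- c(input_ids, input_entity_id(ctx, v))
      input_args <- c(input_args, nm)
    }
  }
  if (!is.null(annotation) && length(annotation$arguments) &&
      length(input_ids)) {
    hit <- input_args %in% names(annotation$arguments)
    for (i in which(hit)) {
      ctx_add_type(ctx, input_ids[i], annotation$arguments[[input_args[i]]])
    }
  }

  ctx$seq <- ctx$seq + 1L
  seq_idx <- ctx$seq
  base_record <- list(
    routine_id = routine_id,
    routine_name = utils::tail(strsplit(routine_id, ".", fixed = TRUE)[[1]], 1),
    package_name = unname(pkg[["name"]]),
    package_version = unname(pkg[["version"]]),
    inputs = unname(input_ids),
    outputs = character(0),
    params = params,
    param_classes = if (is.null(annotation)) list() else annotation$arguments,
    memberships = tibble::tibble(container = character(),
                                 member = character()),
    step_class = if (is.null(annotation)) NULL else annotation$step_class,
    sequence_index = seq_idx,
    failed = FALSE,
    kind = "execution"
  )

  value <- tryCatch(
    do.call(fn, c(lapply(inputs, unwrap_value), params)),
    error = function(e) {
      base_record$failed <- TRUE
      ctx$records[[length(ctx$records) + 1L]] <- base_record
      stop(e)
    }
  )

  # Returns: multiple returns are declared through annotation indices > 0; the
  # routine then returns a list whose elements are the individual returns.
  ret_idx <- if (is.null(annotation)) integer(0) else
    as.integer(names(annotation$returns))
  multi <- length(ret_idx) && max(ret_idx) > 0
  returns <- if (multi) value else list(value)

  out_ids <- character(length(returns))
  memberships <- list()
  for (j in seq_along(returns)) {
    j0 <- j - 1L  # 0-based
    rv <- returns[[j]]
    is_container <- !is.null(annotation) &&
      j0 %in% annotation$container_returns && is.list(rv)
    cls <- if (!is.null(annotation)) annotation$returns[[as.character(j0)]]
    if (is_container) {
      cid <- ctx_entity(ctx, rv)
      member_ids <- vapply(rv, function(m) ctx_entity(ctx, m), character(1))
      if (!is.null(cls)) {
        for (m in member_ids) ctx_add_type(ctx, m, cls)
      }
      memberships[[length(memberships) + 1L]] <-
        tibble::tibble(container = cid, member = unname(member_ids))
      out_ids[j] <- cid
    } else {
      oid <- ctx_entity(ctx, rv)
      if (!is.null(cls)) ctx_add_type(ctx, oid, cls)
      out_ids[j] <- oid
    }
  }

  base_record$outputs <- out_ids
  base_record$memberships <- if (length(memberships)) {
    dplyr::bind_rows(memberships)
  } else {
    base_record$memberships
  }
  ctx$records[[length(ctx$records) + 1L]] <- base_record
  list(value = value, record = base_record)
}

#' Record a file read or write event
#'
#' A write makes the file node the output of a save step that used the given
#' entity; a read makes the file node the origin of a load step generating the
#' entity. File nodes are keyed by (run-relative) path; the content digest is
#' carried as an attribute so identical content written to two paths yields
#' two file nodes sharing a digest.
#'
#' @param ctx A `run_context`.
#' @param path File path (stored relative to the context's output root).
#' @param entity_id Entity IRI (from a previous [track_execution()] record) or
#'   a raw value to be content-addressed.
#' @param kind "write" or "read".
#' @return The `execution_record` of the load/save step, invisibly.
#' @export
record_file_event <- function(ctx, path, entity_id, kind = c("write", "read")) {
  kind <- match.arg(kind)
  stopifnot(nzchar(path))
  if (!is.character(entity_id) || !startsWith(entity_id, ns_iri("cap"))) {
    entity_id <- ctx_entity(ctx, entity_id)
  }
  rel <- relative_path(path, ctx$out_root)
  fid <- file_node_iri(rel)
  ctx$seq <- ctx$seq + 1L
  rec <- list(
    routine_id = if (kind == "write") "io.write_file" else "io.read_file",
    routine_name = if (kind == "write") "write_file" else "read_file",
    package_name = unname(ctx$default_package[["name"]]),
    package_version = unname(ctx$default_package[["version"]]),
    inputs = if (kind == "write") entity_id else fid,
    outputs = if (kind == "write") fid else entity_id,
    params = list(),
    param_classes = list(),
    memberships = tibble::tibble(container = character(), member = character()),
    step_class = NULL,
    sequence_index = ctx$seq,
    failed = FALSE,
    kind = "file_event",
    file_path = rel,
    file_node = fid,
    file_kind = kind,
    content_digest = sub(".*/", "", entity_id)
  )
  ctx$records[[length(ctx$records) + 1L]] <- rec
  invisible(rec)
}

#' Convert captured execution records to a PROV-style RDF graph
#'
#' Emits, per execution: `prov:used` edges to inputs, `prov:generated` edges
#' to outputs, a parameter node per parameter (name/value/unit literals), a
#' `cap:usedFunction` link to a function node carrying the function name and
#' package name/version literals, `prov:hadMember` membership pairs, and the
#' NEAO semantic types collected from the annotation registry (`rdf:type` on
#' the execution, on input/output entities, and on parameter nodes).
#'
#' @param ctx A `run_context` (holding records and the registry), as filled by
#'   [track_execution()] and [record_file_event()].
#' @return An `rdf_graph`.
#' @export
provenance_to_rdf <- function(ctx) {
  cap <- function(x) ns_iri("cap", x)
  rdf_type <- ns_iri("rdf", "type")
  prov_used <- ns_iri("prov", "used")
  prov_generated <- ns_iri("prov", "generated")
  prov_had_member <- ns_iri("prov", "hadMember")

  parts <- vector("list", length(ctx$records) + 2L)
  for (k in seq_along(ctx$records)) {
    r <- ctx$records[[k]]
    exec <- paste0(cap("execution/"), ctx$run_id, "/", r$sequence_index)
    s <- character(0); p <- character(0); o <- character(0)
    kind <- character(0); dtype <- character(0)
    add <- function(ss, pp, oo, kk = "iri", dd = NA_character_) {
      n <- length(oo)
      s <<- c(s, rep_len(ss, n)); p <<- c(p, rep_len(pp, n)); o <<- c(o, oo)
      kind <<- c(kind, rep_len(kk, n)); dtype <<- c(dtype, rep_len(dd, n))
    }
    add(exec, rdf_type, c(cap("FunctionExecution"), ns_iri("prov", "Activity")))
    if (!is.null(r$step_class)) add(exec, rdf_type, r$step_class)
    add(exec, cap("executionIndex"), sprintf("%d", r$sequence_index),
        "literal", "integer")
    if (isTRUE(r$failed)) add(exec, cap("failed"), "true", "literal", "boolean")
    if (length(r$inputs)) add(exec, prov_used, r$inputs)
    if (length(r$outputs)) add(exec, prov_generated, r$outputs)
    if (nrow(r$memberships)) {
      s <- c(s, r$memberships$container)
      p <- c(p, rep_len(prov_had_member, nrow(r$memberships)))
      o <- c(o, r$memberships$member)
      kind <- c(kind, rep_len("iri", nrow(r$memberships)))
      dtype <- c(dtype, rep_len(NA_character_, nrow(r$memberships)))
    }
    for (nm in names(r$params)) {
      v <- r$params[[nm]]
      node <- paste0(exec, "/parameter/", nm)
      add(exec, cap("hasParameter"), node)
      add(node, cap("pairName"), nm, "literal", "string")
      raw <- qty_value(v)
      add(node, cap("pairValue"), literal_lexical(raw), "literal",
          literal_dtype(raw))
      if (inherits(v, "quantity")) {
        add(node, cap("pairUnit"), v$unit, "literal", "string")
      }
      add(node, cap("pairValueText"), format_param_text(v), "literal", "string")
      cls <- r$param_classes[[nm]]
      if (!is.null(cls)) add(node, rdf_type, cls)
    }
    fnode <- paste0(cap("function/"),
                    gsub("[^A-Za-z0-9_.-]", "_", r$routine_id), "@",
                    r$package_name, "-", r$package_version)
    pkgnode <- paste0(cap("package/"),
                      gsub("[^A-Za-z0-9_.-]", "_", r$package_name), "-",
                      r$package_version)
    add(exec, cap("usedFunction"), fnode)
    add(fnode, rdf_type, cap("Function"))
    add(fnode, cap("functionName"), r$routine_name, "literal", "string")
    add(fnode, cap("inPackage"), pkgnode)
    add(pkgnode, cap("packageName"), r$package_name, "literal", "string")
    add(pkgnode, cap("packageVersion"), r$package_version, "literal", "string")
    if (identical(r$kind, "file_event")) {
      add(r$file_node, rdf_type, cap("File"))
      add(r$file_node, cap("filePath"), r$file_path, "literal", "string")
      add(r$file_node, cap("contentDigest"), r$content_digest, "literal",
          "string")
      add(r$file_node, cap("fileEventKind"), r$file_kind, "literal", "string")
    }
    parts[[k]] <- tibble::tibble(s = s, p = p, o = o, o_kind = kind,
                                 o_dtype = dtype)
  }

  # semantic types of entities
  ids <- ls(ctx$entity_types)
  if (length(ids)) {
    types <- lapply(ids, function(id) get(id, envir = ctx$entity_types))
    n <- lengths(types)
    parts[[length(ctx$records) + 1L]] <- tibble::tibble(
      s = rep(ids, n), p = rdf_type, o = unlist(types),
      o_kind = "iri", o_dtype = NA_character_
    )
  }
  run_node <- paste0(cap("run/"), ctx$run_id)
  parts[[length(ctx$records) + 2L]] <- tibble::tibble(
    s = run_node, p = c(rdf_type, cap("runId")),
    o = c(cap("ScriptRun"), ctx$run_id),
    o_kind = c("iri", "literal"), o_dtype = c(NA_character_, "string")
  )

  rdf_graph(dplyr::distinct(dplyr::bind_rows(parts)))
}

#' Serialize a provenance graph to Turtle
#' @param graph An `rdf_graph` (e.g. from [provenance_to_rdf()]).
#' @param path Optional sidecar file path (conventionally `provenance.ttl`
#'   beside the run outputs).
#' @return Character vector of Turtle lines.
#' @export
serialize_provenance <- function(graph, path = NULL) {
  write_turtle(graph, path = path)
}

#' @export
print.run_context <- function(x, ...) {
  cat(sprintf("<run_context '%s'> %d records\n", x$run_id, length(x$records)))
  invisible(x)
}

#' @export
glance.run_context <- function(x, ...) {
  recs <- x$records
  tibble::tibble(
    run_id = x$run_id,
    n_records = length(recs),
    n_failed = sum(vapply(recs, function(r) isTRUE(r$failed), logical(1))),
    n_files_written = sum(vapply(recs, function(r)
      identical(r$kind, "file_event") && identical(r$file_kind, "write"),
      logical(1)))
  )
}
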