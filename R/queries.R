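# Competency-question queries over the mapped knowledge graph.
#
# All queries are native traversals over the triple tibble (with igraph
# providing reachability on the derivation relation); equivalent SPARQL texts
# for representative queries ship under inst/sparql. Every query is read-only
# and returns a tibble with deterministic (lexicographic) row order.
#
# The derivation relation is the directed union of
#   entity -> execution   (prov:used, reversed)
#   execution -> entity   (prov:generated)
#   container -> member   (prov:hadMember)
# so a BFS forward from the session file reaches every derived output file,
# and a BFS backward from an output file yields its derivation chain.

kg_index <- function(kg) {
  idx <- attr(kg, "kg_index")
  if (!is.null(idx)) return(kg)
  tr <- tibble::as_tibble(kg)
  cap <- function(x) ns_iri("cap", x)

  used <- tr[tr$p == ns_iri("prov", "used"), c("s", "o")]
  gen <- tr[tr$p == ns_iri("prov", "generated"), c("s", "o")]
  mem <- tr[tr$p == ns_iri("prov", "hadMember"), c("s", "o")]
  edges <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(from = used$o, to = used$s),
    tibble::tibble(from = gen$s, to = gen$o),
    tibble::tibble(from = mem$s, to = mem$o)
  ))
  verts <- unique(c(edges$from, edges$to))
  ig <- igraph::graph_from_data_frame(edges, vertices = verts)

  paths <- tr[tr$p == cap("filePath") & tr$o_kind == "literal", c("s", "o")]
  kinds <- tr[tr$p == cap("fileEventKind"), c("s", "o")]
  files <- dplyr::distinct(dplyr::inner_join(
    dplyr::rename(paths, path = "o"),
    dplyr::rename(kinds, kind = "o"), by = "s",
    relationship = "many-to-many"))

  types <- tr[tr$p == ns_iri("rdf", "type") & tr$o_kind == "iri",
              c("s", "o")]

  idx <- list(ig = ig, verts = verts, files = files, types = types)
  attr(kg, "kg_index") <- idx
  kg
}

kg_idx <- function(kg) {
  kg <- kg_index(kg)
  attr(kg, "kg_index")
}

kg_written_files <- function(idx) {
  dplyr::distinct(idx$files[idx$files$kind == "write", c("s", "path")])
}

reach_nodes <- function(idx, node, mode) {
  if (!node %in% idx$verts) return(character(0))
  names(igraph::subcomponent(idx$ig, node, mode = mode))
}

# chain nodes (the node itself excluded) for each written file
kg_file_chains <- function(idx) {
  wf <- kg_written_files(idx)
  chains <- lapply(wf$s, function(f) setdiff(reach_nodes(idx, f, "in"), f))
  names(chains) <- wf$path
  chains[order(names(chains))]
}

resolve_class <- function(onto, class) {
  iri <- expand_curie(class, neao_namespaces())
  if (!iri %in% onto$classes$uri) {
    stop(sprintf("class not in ontology: %s", iri), call. = FALSE)
  }
  iri
}

step_universe <- function(onto) {
  setdiff(subclasses_of(onto, ns_iri("neao_base", "AnalysisStep")),
          ns_iri("neao_base", "AnalysisStep"))
}

minimal_classes <- function(onto, classes) {
  if (length(classes) <= 1) return(classes)
  rel <- onto_inferred(onto)
  proper <- rel[rel$sub != rel$super & rel$sub %in% classes &
                  rel$super %in% classes, ]
  setdiff(classes, unique(proper$super))
}

class_filter <- function(onto, class, include_inferred) {
  if (include_inferred) subclasses_of(onto, class) else
    expand_curie(class, neao_namespaces())
}

#' Files derived from a source file
#'
#' Lists every output file whose saved content is connected to the given
#' source file by a directed chain of usage/generation (and container
#' membership) edges.
#'
#' @param kg Mapped knowledge graph.
#' @param source_path Path of the source file as recorded (run-relative).
#' @return Tibble with columns `input` and `output` (one row per derived
#'   file), in lexicographic order. Unknown paths yield an empty table.
#' @export
files_derived_from <- function(kg, source_path) {
  idx <- kg_idx(kg)
  src <- dplyr::distinct(
    idx$files[idx$files$kind == "read" & idx$files$path == source_path,
              c("s", "path")])
  wf <- kg_written_files(idx)
  out <- lapply(seq_len(nrow(src)), function(i) {
    reached <- reach_nodes(idx, src$s[i], "out")
    hits <- wf[wf$s %in% setdiff(reached, src$s[i]), ]
    tibble::tibble(input = src$path[i], output = hits$path)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(input = character(0), output = character(0))
  }
  dplyr::arrange(dplyr::distinct(res), .data$input, .data$output)
}

#' All files saved in any run
#' @param kg Mapped knowledge graph.
#' @return Tibble with column `output`, sorted.
#' @export
all_saved_files <- function(kg) {
  idx <- kg_idx(kg)
  dplyr::arrange(
    dplyr::distinct(tibble::tibble(output = kg_written_files(idx)$path)),
    .data$output)
}

chain_step_rows <- function(idx, onto, chains, class_set, minimal = TRUE) {
  types <- idx$types
  step_typed <- types[types$o %in% class_set, ]
  out <- lapply(names(chains), function(path) {
    execs <- intersect(chains[[path]], unique(step_typed$s))
    if (!length(execs)) return(NULL)
    rows <- step_typed[step_typed$s %in% execs, ]
    if (minimal) {
      parts <- split(rows$o, rows$s)
      cls <- unlist(lapply(parts, function(cl) minimal_classes(onto, cl)),
                    use.names = FALSE)
      rows <- tibble::tibble(s = rep(names(parts),
                                     vapply(parts, function(cl)
                                       length(minimal_classes(onto, cl)),
                                       integer(1))),
                             o = cls)
    }
    tibble::tibble(file = path, exec = rows$s, step_class = rows$o)
  })
  dplyr::bind_rows(out)
}

#' Analysis steps on the derivation chain of each saved file
#'
#' One row per (file, step class) where an execution typed by that class lies
#' on the file's derivation chain; duplicates collapsed. By default only the
#' most specific captured classes are reported (as annotated); with
#' `minimal = FALSE` all entailed step classes are listed.
#'
#' @param kg Mapped knowledge graph.
#' @param onto Materialized ontology.
#' @param minimal Report only minimal (most specific) classes per execution.
#' @return Tibble with columns `file`, `step_class`, sorted.
#' @export
steps_for_files <- function(kg, onto, minimal = TRUE) {
  idx <- kg_idx(kg)
  chains <- kg_file_chains(idx)
  rows <- chain_step_rows(idx, onto, chains, step_universe(onto),
                          minimal = minimal)
  if (nrow(rows) == 0) {
    return(tibble::tibble(file = character(0), step_class = character(0)))
  }
  dplyr::arrange(dplyr::distinct(rows[, c("file", "step_class")]),
                 .data$file, .data$step_class)
}

#' Files whose derivation involves a given step and/or data class
#'
#' Lists saved files whose derivation chain contains an execution typed under
#' `step_class` and/or an entity typed under `data_class`; when both are given
#' both conditions must hold. `include_inferred` resolves grouping classes via
#' the materialized subclass closure.
#'
#' @param kg Mapped knowledge graph.
#' @param onto Materialized ontology.
#' @param step_class,data_class Class IRI/CURIE or `NULL`.
#' @param include_inferred Match subclasses of the given classes.
#' @return Tibble with column `file`, sorted.
#' @export
files_with_step_or_data <- function(kg, onto, step_class = NULL,
                                    data_class = NULL,
                                    include_inferred = TRUE) {
  if (is.null(step_class) && is.null(data_class)) {
    stop("at least one of step_class or data_class must be given",
         call. = FALSE)
  }
  idx <- kg_idx(kg)
  chains <- kg_file_chains(idx)
  types <- idx$types
  step_nodes <- data_nodes <- NULL
  if (!is.null(step_class)) {
    cls <- class_filter(onto, resolve_class(onto, step_class),
                        include_inferred)
    step_nodes <- unique(types$s[types$o %in% cls])
  }
  if (!is.null(data_class)) {
    cls <- class_filter(onto, resolve_class(onto, data_class),
                        include_inferred)
    data_nodes <- unique(types$s[types$o %in% cls])
  }
  hit <- vapply(chains, function(nodes) {
    ok <- TRUE
    if (!is.null(step_nodes)) ok <- ok && any(nodes %in% step_nodes)
    if (!is.null(data_nodes)) ok <- ok && any(nodes %in% data_nodes)
    ok
  }, logical(1))
  tibble::tibble(file = sort(names(chains)[hit]))
}

#' Parameters used by executions of a step class, per file
#'
#' One row per annotated parameter of each matching execution on each file's
#' derivation chain, with its `AnalysisParameter` class and (formatted)
#' value. `scope_data_class` restricts to executions whose inputs derive from
#' entities of that data class (e.g. bin sizes of histograms computed from
#' surrogate spike trains).
#'
#' @param kg Mapped knowledge graph.
#' @param onto Materialized ontology.
#' @param step_class Step class IRI/CURIE (inferred subclasses included).
#' @param scope_data_class Optional data class IRI/CURIE.
#' @return Tibble with columns `file`, `parameter_class`, `value`, sorted.
#' @export
parameters_for_step <- function(kg, onto, step_class,
                                scope_data_class = NULL) {
  idx <- kg_idx(kg)
  tr <- tibble::as_tibble(kg)
  cap <- function(x) ns_iri("cap", x)
  chains <- kg_file_chains(idx)
  cls <- class_filter(onto, resolve_class(onto, step_class), TRUE)
  rows <- chain_step_rows(idx, onto, chains, cls, minimal = FALSE)
  if (nrow(rows) == 0) {
    return(tibble::tibble(file = character(0), parameter_class = character(0),
                          value = character(0)))
  }
  execs <- unique(rows$exec)

  if (!is.null(scope_data_class)) {
    scls <- class_filter(onto, resolve_class(onto, scope_data_class), TRUE)
    scope_nodes <- unique(idx$types$s[idx$types$o %in% scls])
    in_scope <- vapply(execs, function(e) {
      up <- setdiff(reach_nodes(idx, e, "in"), e)
      any(up %in% scope_nodes)
    }, logical(1))
    execs <- execs[in_scope]
    rows <- rows[rows$exec %in% execs, ]
  }

  param_cls <- setdiff(
    subclasses_of(onto, ns_iri("neao_base", "AnalysisParameter")),
    ns_iri("neao_base", "AnalysisParameter"))
  haspar <- tr[tr$p == cap("hasParameter") & tr$s %in% execs, c("s", "o")]
  ptypes <- idx$types[idx$types$s %in% haspar$o & idx$types$o %in% param_cls, ]
  pvals <- tr[tr$p == cap("pairValueText") & tr$s %in% haspar$o, c("s", "o")]
  params <- dplyr::inner_join(
    dplyr::rename(haspar, exec = "s", node = "o"),
    dplyr::rename(ptypes, node = "s", parameter_class = "o"), by = "node",
    relationship = "many-to-many")
  params$value <- pvals$o[match(params$node, pvals$s)]
  out <- dplyr::inner_join(rows[, c("file", "exec")], params, by = "exec",
                           relationship = "many-to-many")
  out <- dplyr::distinct(out[, c("file", "parameter_class", "value")])
  dplyr::arrange(out, .data$file, .data$parameter_class, .data$value)
}

#' Software package implementing a step class, per file
#'
#' Package name/version reached via `isImplementedIn`/`isImplementedInPackage`
#' for executions of the step class on each file's derivation chain. Functions
#' without a package link yield empty package fields.
#'
#' @param kg Mapped knowledge graph.
#' @param onto Materialized ontology.
#' @param step_class Step class IRI/CURIE (inferred subclasses included).
#' @return Tibble with columns `file`, `package_name`, `package_version`.
#' @export
software_for_step <- function(kg, onto, step_class) {
  idx <- kg_idx(kg)
  tr <- tibble::as_tibble(kg)
  base <- function(x) ns_iri("neao_base", x)
  chains <- kg_file_chains(idx)
  cls <- class_filter(onto, resolve_class(onto, step_class), TRUE)
  rows <- chain_step_rows(idx, onto, chains, cls, minimal = FALSE)
  if (nrow(rows) == 0) {
    return(tibble::tibble(file = character(0), package_name = character(0),
                          package_version = character(0)))
  }
  impl <- tr[tr$p == base("isImplementedIn"), c("s", "o")]
  inpkg <- tr[tr$p == base("isImplementedInPackage"), c("s", "o")]
  pname <- tr[tr$p == base("packageName"), c("s", "o")]
  pver <- tr[tr$p == base("packageVersion"), c("s", "o")]
  fn <- impl$o[match(rows$exec, impl$s)]
  pkg <- inpkg$o[match(fn, inpkg$s)]
  out <- tibble::tibble(
    file = rows$file,
    package_name = dplyr::coalesce(pname$o[match(pkg, pname$s)], ""),
    package_version = dplyr::coalesce(pver$o[match(pkg, pver$s)], "")
  )
  out <- out[!is.na(fn), , drop = FALSE]
  dplyr::arrange(dplyr::distinct(out), .data$file, .data$package_name)
}

#' Files where one step class was executed upstream of another
#'
#' Reports files on whose derivation chain an execution under `earlier_class`
#' occurs upstream (by the derivation relation) of an execution under
#' `later_class`, together with the specific earlier subclass.
#'
#' @param kg Mapped knowledge graph.
#' @param onto Materialized ontology.
#' @param earlier_class,later_class Step class IRIs/CURIEs (inferred
#'   subclasses included).
#' @return Tibble with columns `file`, `earlier_step_class`, sorted.
#' @export
step_preceding <- function(kg, onto, earlier_class, later_class) {
  idx <- kg_idx(kg)
  chains <- kg_file_chains(idx)
  e_cls <- class_filter(onto, resolve_class(onto, earlier_class), TRUE)
  l_cls <- class_filter(onto, resolve_class(onto, later_class), TRUE)
  e_rows <- chain_step_rows(idx, onto, chains, e_cls, minimal = TRUE)
  l_rows <- chain_step_rows(idx, onto, chains, l_cls, minimal = FALSE)
  if (nrow(e_rows) == 0 || nrow(l_rows) == 0) {
    return(tibble::tibble(file = character(0),
                          earlier_step_class = character(0)))
  }
  out <- list()
  for (path in intersect(unique(e_rows$file), unique(l_rows$file))) {
    ef <- e_rows[e_rows$file == path, ]
    lf <- unique(l_rows$exec[l_rows$file == path])
    ancestors <- unique(unlist(lapply(lf, function(e)
      setdiff(reach_nodes(idx, e, "in"), e))))
    hit <- ef[ef$exec %in% ancestors, ]
    if (nrow(hit)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        file = path, earlier_step_class = unique(hit$step_class))
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(file = character(0),
                          earlier_step_class = character(0)))
  }
  dplyr::arrange(dplyr::distinct(res), .data$file, .data$earlier_step_class)
}

#' Number of container outputs per step-class execution, per file
#'
#' For executions of the step class on each file's derivation chain that
#' generated a container, counts the distinct members (e.g. the number of
#' surrogates generated per spike train).
#'
#' @param kg Mapped knowledge graph.
#' @param onto Materialized ontology.
#' @param step_class Step class IRI/CURIE (inferred subclasses included).
#' @return Tibble with columns `file`, `step_class`, `n_outputs`, sorted.
#' @export
outputs_per_step <- function(kg, onto, step_class) {
  idx <- kg_idx(kg)
  tr <- tibble::as_tibble(kg)
  chains <- kg_file_chains(idx)
  cls <- class_filter(onto, resolve_class(onto, step_class), TRUE)
  rows <- chain_step_rows(idx, onto, chains, cls, minimal = TRUE)
  if (nrow(rows) == 0) {
    return(tibble::tibble(file = character(0), step_class = character(0),
                          n_outputs = integer(0)))
  }
  gen <- tr[tr$p == ns_iri("prov", "generated"), c("s", "o")]
  mem <- tr[tr$p == ns_iri("prov", "hadMember"), c("s", "o")]
  members <- dplyr::inner_join(gen, mem, by = c(o = "s"),
                               relationship = "many-to-many")
  counts <- dplyr::summarise(
    dplyr::group_by(members, exec = .data$s),
    n_outputs = dplyr::n_distinct(.data$o.y), .groups = "drop")
  out <- dplyr::inner_join(rows, counts, by = "exec")
  out <- dplyr::distinct(out[, c("file", "step_class", "n_outputs")])
  dplyr::arrange(out, .data$file, .data$step_class)
}

#' Aggregate a query table by output folder
#'
#' Groups rows by the leading `depth` directory components of a path column
#' (fewer when the path is shallower), counting distinct paths; optionally
#' pivots a second column into a wide incidence matrix of counts.
#'
#' @param table A query result tibble.
#' @param path_column Name of the path column.
#' @param depth Number of leading directory components forming the folder key.
#' @param pivot Optional column name to spread into wide count columns.
#' @return Tibble keyed by `folder`, sorted.
#' @export
aggregate_by_folder <- function(table, path_column = "output", depth = 2L,
                                pivot = NULL) {
  stopifnot(path_column %in% names(table))
  if (nrow(table) == 0) {
    return(tibble::tibble(folder = character(0), n = integer(0)))
  }
  folder_of <- function(path) {
    parts <- strsplit(path, "/", fixed = TRUE)
    vapply(parts, function(p) {
      dirs <- p[-length(p)]
      paste(utils::head(dirs, depth), collapse = "/")
    }, character(1))
  }
  tb <- dplyr::mutate(table, folder = folder_of(.data[[path_column]]))
  if (is.null(pivot)) {
    out <- dplyr::summarise(dplyr::group_by(tb, .data$folder),
                            n = dplyr::n_distinct(.data[[path_column]]),
                            .groups = "drop")
    return(dplyr::arrange(out, .data$folder))
  }
  out <- dplyr::summarise(
    dplyr::group_by(tb, .data$folder, .data[[pivot]]),
    n = dplyr::n_distinct(.data[[path_column]]), .groups = "drop")
  out <- tidyr::pivot_wider(out, names_from = dplyr::all_of(pivot),
                            values_from = "n", values_fill = 0L)
  out <- out[, c("folder", sort(setdiff(names(out), "folder")))]
  dplyr::arrange(out, .data$folder)
}

#' Write a query table as CSV
#'
#' Rows are written in the table's (deterministic) order so repeated runs with
#' fixed seeds produce byte-identical files.
#'
#' @param table A query result tibble.
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
write_query_csv <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(table)
}
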