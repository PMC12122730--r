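# A small SPARQL engine over the tibble-backed triple store.
#
# Supported: PREFIX declarations; SELECT [DISTINCT] ?vars WHERE { BGP };
# INSERT { template } WHERE { BGP }. Basic graph patterns are triple patterns
# with property paths built from IRIs, `a`, inverse (^), sequence (/),
# alternation (|, in parentheses) and one-or-more (+). Literals may appear as
# objects. This covers the competency-question queries and the NEAO mapping
# updates; it is not a general SPARQL implementation.

sparql_tokenize <- function(text) {
  text <- paste(text, collapse = "\n")
  # strip comment lines (no '#' inside our IRIs appears at line starts only)
  text <- gsub("(?m)^\\s*#.*$", "", text, perl = TRUE)
  pattern <- paste0(
    "(PREFIX|SELECT|DISTINCT|WHERE|INSERT|DATA)|",   # keywords
    "(<[^>]*>)|",                                     # IRI
    "(\\?[A-Za-z_][A-Za-z0-9_]*)|",                   # variable
    "(\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*)?)|", # literal
    "([A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*)|",    # pname
    "([A-Za-z_][A-Za-z0-9_.-]*:)|",                   # prefix decl name
    "(\\{|\\}|\\(|\\)|\\.|;|,|\\||/|\\^|\\+|\\*|a)|", # punctuation / 'a'
    "(-?[0-9]+\\.[0-9]+)|(-?[0-9]+)|(true|false)"     # numbers / booleans
  )
  m <- gregexpr(pattern, text, perl = TRUE)
  tokens <- regmatches(text, m)[[1]]
  tokens[nzchar(tokens)]
}

sparql_term <- function(tok, prefixes) {
  if (startsWith(tok, "?")) {
    return(list(type = "var", name = substring(tok, 2)))
  }
  if (startsWith(tok, "<")) {
    return(list(type = "const", key = substr(tok, 2, nchar(tok) - 1L)))
  }
  if (startsWith(tok, "\"")) {
    dt <- "string"
    lex_part <- tok
    if (grepl("\\^\\^", tok)) {
      parts <- strsplit(tok, "\\^\\^")[[1]]
      lex_part <- parts[1]
      dt_iri <- expand_curie(parts[2], prefixes)
      dt <- switch(sub(".*#", "", dt_iri),
                   integer = "integer", double = "double", decimal = "double",
                   boolean = "boolean", "string")
    }
    lex <- sub("^\"(.*)\"$", "\\1", lex_part)
    lex <- gsub("\\\\\"", "\"", lex)
    lex <- gsub("\\\\\\\\", "\\\\", lex)
    return(list(type = "const", key = paste0("\"", lex, "\"^^", dt)))
  }
  if (tok == "a") {
    return(list(type = "const", key = ns_iri("rdf", "type")))
  }
  if (tok %in% c("true", "false")) {
    return(list(type = "const", key = paste0("\"", tok, "\"^^boolean")))
  }
  if (grepl("^-?[0-9]+$", tok)) {
    return(list(type = "const", key = paste0("\"", tok, "\"^^integer")))
  }
  if (grepl("^-?[0-9]+\\.[0-9]+$", tok)) {
    return(list(type = "const", key = paste0("\"", tok, "\"^^double")))
  }
  list(type = "const", key = expand_curie(tok, prefixes))
}

# Property path parsing (recursive descent over the token stream) ------------

parse_path <- function(tokens, i, prefixes) {
  res <- parse_path_seq(tokens, i, prefixes)
  parts <- list(res$node)
  i <- res$i
  while (i <= length(tokens) && tokens[i] == "|") {
    res <- parse_path_seq(tokens, i + 1L, prefixes)
    parts <- c(parts, list(res$node))
    i <- res$i
  }
  node <- if (length(parts) == 1) parts[[1]] else list(op = "alt", parts = parts)
  list(node = node, i = i)
}

parse_path_seq <- function(tokens, i, prefixes) {
  res <- parse_path_unary(tokens, i, prefixes)
  parts <- list(res$node)
  i <- res$i
  while (i <= length(tokens) && tokens[i] == "/") {
    res <- parse_path_unary(tokens, i + 1L, prefixes)
    parts <- c(parts, list(res$node))
    i <- res$i
  }
  node <- if (length(parts) == 1) parts[[1]] else list(op = "seq", parts = parts)
  list(node = node, i = i)
}

parse_path_unary <- function(tokens, i, prefixes) {
  inverse <- FALSE
  if (tokens[i] == "^") { inverse <- TRUE; i <- i + 1L }
  if (tokens[i] == "(") {
    res <- parse_path(tokens, i + 1L, prefixes)
    stopifnot(tokens[res$i] == ")")
    node <- res$node
    i <- res$i + 1L
  } else {
    term <- sparql_term(tokens[i], prefixes)
    stopifnot(term$type == "const")
    node <- list(op = "iri", iri = term$key)
    i <- i + 1L
  }
  if (i <= length(tokens) && tokens[i] %in% c("+", "*")) {
    node <- list(op = if (tokens[i] == "+") "plus" else "star", part = node)
    i <- i + 1L
  }
  if (inverse) node <- list(op = "inv", part = node)
  list(node = node, i = i)
}

# Path evaluation -------------------------------------------------------------

graph_pairs <- function(tr, iri) {
  rows <- tr$p == iri
  tibble::tibble(from = tr$s[rows],
                 to = term_key(tr$o[rows], tr$o_kind[rows], tr$o_dtype[rows]))
}

path_step_pairs <- function(tr, node) {
  switch(node$op,
    iri = graph_pairs(tr, node$iri),
    inv = {
      p <- path_step_pairs(tr, node$part)
      tibble::tibble(from = p$to, to = p$from)
    },
    alt = dplyr::distinct(dplyr::bind_rows(
      lapply(node$parts, path_step_pairs, tr = tr))),
    seq = {
      parts <- lapply(node$parts, path_step_pairs, tr = tr)
      out <- parts[[1]]
      for (k in seq_along(parts)[-1]) {
        out <- dplyr::inner_join(out, parts[[k]], by = c(to = "from"),
                                 relationship = "many-to-many")
        out <- dplyr::distinct(tibble::tibble(from = out$from, to = out$to.y))
      }
      out
    },
    plus = transitive_pairs(path_step_pairs(tr, node$part), reflexive = FALSE),
    star = transitive_pairs(path_step_pairs(tr, node$part), reflexive = TRUE),
    stop("unknown path operator")
  )
}

transitive_pairs <- function(pairs, reflexive = FALSE) {
  verts <- unique(c(pairs$from, pairs$to))
  if (!length(verts)) return(pairs)
  g <- igraph::graph_from_data_frame(pairs, vertices = verts)
  reach <- lapply(seq_along(verts), function(v) {
    r <- igraph::subcomponent(g, v, mode = "out")
    as.integer(r)
  })
  n <- lengths(reach)
  out <- tibble::tibble(from = rep(verts, n), to = verts[unlist(reach)])
  if (!reflexive) out <- out[out$from != out$to | out$from %in%
                               pairs$from[pairs$from == pairs$to], ]
  dplyr::distinct(out)
}

bfs_reach <- function(pairs, seeds, forward = TRUE, reflexive = FALSE) {
  # pairs of (seed, reachable) restricted to the given seed nodes
  adj <- if (forward) split(pairs$to, pairs$from) else split(pairs$from, pairs$to)
  out_from <- character(0); out_to <- character(0)
  for (seed in unique(seeds)) {
    seen <- character(0)
    frontier <- seed
    repeat {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, seen)
      if (!length(nxt)) break
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (reflexive) seen <- unique(c(seed, seen))
    if (length(seen)) {
      out_from <- c(out_from, rep(seed, length(seen)))
      out_to <- c(out_to, seen)
    }
  }
  if (forward) tibble::tibble(from = out_from, to = out_to)
  else tibble::tibble(from = out_to, to = out_from)
}

pattern_pairs <- function(tr, bindings, pat) {
  # Evaluate the path, constraining closure operators by already-known
  # endpoint values so `p+` never requires a full transitive closure.
  known <- function(term) {
    if (term$type == "const") return(term$key)
    if (!is.null(bindings) && term$name %in% names(bindings)) {
      return(unique(bindings[[term$name]]))
    }
    NULL
  }
  if (pat$path$op %in% c("plus", "star")) {
    base <- path_step_pairs(tr, pat$path$part)
    refl <- pat$path$op == "star"
    s_known <- known(pat$s)
    o_known <- known(pat$o)
    if (!is.null(s_known)) {
      return(bfs_reach(base, s_known, forward = TRUE, reflexive = refl))
    }
    if (!is.null(o_known)) {
      return(bfs_reach(base, o_known, forward = FALSE, reflexive = refl))
    }
  }
  path_step_pairs(tr, pat$path)
}

eval_pattern <- function(tr, bindings, pat) {
  pairs <- pattern_pairs(tr, bindings, pat)
  if (pat$s$type == "const") {
    pairs <- pairs[pairs$from == pat$s$key, , drop = FALSE]
  }
  if (pat$o$type == "const") {
    pairs <- pairs[pairs$to == pat$o$key, , drop = FALSE]
  }
  same_var <- pat$s$type == "var" && pat$o$type == "var" &&
    pat$s$name == pat$o$name
  if (same_var) pairs <- pairs[pairs$from == pairs$to, , drop = FALSE]
  cand <- tibble::tibble(.rows = nrow(pairs))
  if (pat$s$type == "var") cand[[pat$s$name]] <- pairs$from
  if (pat$o$type == "var" && !same_var) cand[[pat$o$name]] <- pairs$to
  cand <- dplyr::distinct(cand)
  if (ncol(cand) == 0) {
    # both endpoints constant: existence test
    if (nrow(pairs) == 0) {
      return(if (is.null(bindings)) tibble::tibble(.rows = 0) else
        bindings[0, , drop = FALSE])
    }
    return(if (is.null(bindings)) tibble::tibble(.rows = 1) else bindings)
  }
  if (is.null(bindings)) return(cand)
  shared <- intersect(names(bindings), names(cand))
  if (length(shared)) {
    dplyr::inner_join(bindings, cand, by = shared,
                      relationship = "many-to-many")
  } else {
    dplyr::cross_join(bindings, cand)
  }
}

parse_bgp <- function(tokens, i, prefixes) {
  stopifnot(tokens[i] == "{")
  i <- i + 1L
  patterns <- list()
  subj <- NULL
  pred <- NULL
  while (tokens[i] != "}") {
    if (tokens[i] == ".") { subj <- NULL; pred <- NULL; i <- i + 1L; next }
    if (tokens[i] == ";") { pred <- NULL; i <- i + 1L; next }
    if (tokens[i] == ",") { i <- i + 1L; next }
    if (is.null(subj)) {
      subj <- sparql_term(tokens[i], prefixes)
      if (subj$type == "const" && !startsWith(tokens[i], "\"")) {
        subj$key <- expand_curie(subj$key, prefixes)
      }
      i <- i + 1L
      next
    }
    if (is.null(pred)) {
      res <- parse_path(tokens, i, prefixes)
      pred <- res$node
      i <- res$i
      next
    }
    obj <- sparql_term(tokens[i], prefixes)
    patterns[[length(patterns) + 1L]] <- list(s = subj, path = pred, o = obj)
    i <- i + 1L
  }
  list(patterns = patterns, i = i + 1L)
}

parse_sparql <- function(text) {
  tokens <- sparql_tokenize(text)
  prefixes <- neao_namespaces()
  i <- 1L
  while (i <= length(tokens) && tokens[i] == "PREFIX") {
    pfx <- sub(":$", "", tokens[i + 1L])
    iri <- sub("^<(.*)>$", "\\1", tokens[i + 2L])
    prefixes[pfx] <- iri
    i <- i + 3L
  }
  form <- tokens[i]
  if (form == "SELECT") {
    i <- i + 1L
    distinct <- FALSE
    if (tokens[i] == "DISTINCT") { distinct <- TRUE; i <- i + 1L }
    vars <- character(0)
    while (tokens[i] != "WHERE") {
      if (tokens[i] == "*") { vars <- "*" } else {
        vars <- c(vars, substring(tokens[i], 2))
      }
      i <- i + 1L
    }
    body <- parse_bgp(tokens, i + 1L, prefixes)
    list(form = "select", vars = vars, distinct = distinct,
         patterns = body$patterns, prefixes = prefixes)
  } else if (form == "INSERT") {
    tmpl <- parse_bgp(tokens, i + 1L, prefixes)
    stopifnot(tokens[tmpl$i] == "WHERE")
    body <- parse_bgp(tokens, tmpl$i + 1L, prefixes)
    list(form = "insert", template = tmpl$patterns, patterns = body$patterns,
         prefixes = prefixes)
  } else {
    stop(sprintf("unsupported SPARQL form: %s", form), call. = FALSE)
  }
}

eval_bgp <- function(graph, patterns) {
  tr <- tibble::as_tibble(graph)
  bindings <- NULL
  for (pat in patterns) {
    bindings <- eval_pattern(tr, bindings, pat)
    if (!is.null(bindings) && nrow(bindings) == 0) break
  }
  if (is.null(bindings)) bindings <- tibble::tibble()
  bindings
}

#' Run a SPARQL SELECT query over an RDF graph
#'
#' @param graph An `rdf_graph`.
#' @param query SPARQL text (character vector or single string).
#' @return A tibble with one column per selected variable; literal values are
#'   decoded to their lexical form. Rows are distinct and sorted.
#' @export
sparql_select <- function(graph, query) {
  q <- parse_sparql(query)
  stopifnot(q$form == "select")
  bindings <- eval_bgp(graph, q$patterns)
  vars <- if (identical(q$vars, "*")) names(bindings) else q$vars
  out <- bindings[, vars, drop = FALSE]
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), term_decode))
  out <- dplyr::distinct(tibble::as_tibble(out))
  dplyr::arrange(out, dplyr::across(dplyr::everything()))
}

#' Apply a SPARQL INSERT-WHERE update to an RDF graph
#'
#' @param graph An `rdf_graph`.
#' @param query SPARQL update text (`INSERT { ... } WHERE { ... }`).
#' @return The graph with the instantiated template triples added.
#' @export
sparql_update <- function(graph, query) {
  q <- parse_sparql(query)
  stopifnot(q$form == "insert")
  bindings <- eval_bgp(graph, q$patterns)
  if (nrow(bindings) == 0) return(graph)
  new <- list()
  for (pat in q$template) {
    stopifnot(pat$path$op == "iri")
    s_keys <- if (pat$s$type == "var") bindings[[pat$s$name]] else
      rep(pat$s$key, nrow(bindings))
    o_keys <- if (pat$o$type == "var") bindings[[pat$o$name]] else
      rep(pat$o$key, nrow(bindings))
    dec <- term_unkey(o_keys)
    new[[length(new) + 1L]] <- tibble::tibble(
      s = s_keys, p = pat$path$iri, o = dec$o, o_kind = dec$o_kind,
      o_dtype = dec$o_dtype
    )
  }
  out <- dplyr::distinct(dplyr::bind_rows(tibble::as_tibble(graph),
                                          dplyr::bind_rows(new)))
  rdf_graph(out, prefixes = rdf_prefixes(graph))
}

#' Read a SPARQL query/update shipped with the package
#' @param name File name under `inst/sparql` (e.g. "map_has_input.ru").
#' @return The query text as a single string.
#' @export
sparql_resource <- function(name) {
  path <- system.file("sparql", name, package = "neaokg")
  if (!nzchar(path)) stop(sprintf("no such SPARQL resource: %s", name),
                          call. = FALSE)
  paste(readLines(path, warn = FALSE), collapse = "\n")
}
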