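# In-memory RDF triple store backed by a tibble, with Turtle I/O.
#
# Triples are rows of (s, p, o, o_kind, o_dtype):
#   s, p    subject / predicate IRIs (or "_:" blank-node labels for subjects)
#   o       object IRI, blank label, or the lexical form of a literal
#   o_kind  "iri" or "literal"
#   o_dtype literal datatype: "string", "integer", "double", "boolean" (NA for IRIs)
# The prefix map used for CURIE abbreviation travels as an attribute.

#' Well-known namespaces used throughout the package
#'
#' Includes the six NEAO module namespaces (root, base, data, steps, parameters,
#' bibliography) plus the standard vocabularies (RDF, RDFS, OWL, SKOS, DCTERMS,
#' BiRO, XSD, PROV-O) and the internal provenance-capture namespace.
#'
#' @return Named character vector mapping prefix to namespace IRI.
#' @export
neao_namespaces <- function() {
  c(
    neao        = "http://purl.org/neao#",
    neao_base   = "http://purl.org/neao/base#",
    neao_data   = "http://purl.org/neao/data#",
    neao_steps  = "http://purl.org/neao/steps#",
    neao_params = "http://purl.org/neao/parameters#",
    neao_bib    = "http://purl.org/neao/bibliography#",
    rdf     = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs    = "http://www.w3.org/2000/01/rdf-schema#",
    owl     = "http://www.w3.org/2002/07/owl#",
    skos    = "http://www.w3.org/2004/02/skos/core#",
    dcterms = "http://purl.org/dc/terms/",
    biro    = "http://purl.org/spar/biro/",
    xsd     = "http://www.w3.org/2001/XMLSchema#",
    prov    = "http://www.w3.org/ns/prov#",
    cap     = "http://example.org/capture#"
  )
}

ns_iri <- function(prefix, local = "") {
  paste0(neao_namespaces()[[prefix]], local)
}

#' Create an empty (or pre-filled) RDF graph
#'
#' @param triples Optional tibble with columns `s`, `p`, `o`, `o_kind`,
#'   `o_dtype`.
#' @param prefixes Named character vector of prefix -> namespace IRI.
#' @return An `rdf_graph` object (a tibble of triples).
#' @export
rdf_graph <- function(triples = NULL, prefixes = neao_namespaces()) {
  if (is.null(triples)) {
    triples <- tibble::tibble(
      s = character(), p = character(), o = character(),
      o_kind = character(), o_dtype = character()
    )
  }
  structure(triples, class = c("rdf_graph", class(tibble::tibble())),
            prefixes = prefixes)
}

rdf_prefixes <- function(graph) attr(graph, "prefixes")

#' Add triples to an RDF graph
#'
#' Vectorized over all arguments. Objects are IRIs unless a literal is passed
#' through [rdf_literal()] encoding via `o_kind`/`o_dtype`.
#'
#' @param graph An `rdf_graph`.
#' @param s,p,o Subject, predicate, object vectors.
#' @param o_kind "iri" or "literal" (recycled).
#' @param o_dtype Literal datatype (recycled; NA for IRIs).
#' @return The graph with rows appended (deduplicated).
#' @export
rdf_add <- function(graph, s, p, o, o_kind = "iri", o_dtype = NA_character_) {
  n <- max(length(s), length(p), length(o))
  new <- tibble::tibble(
    s = rep_len(as.character(s), n),
    p = rep_len(as.character(p), n),
    o = rep_len(as.character(o), n),
    o_kind = rep_len(o_kind, n),
    o_dtype = rep_len(o_dtype, n)
  )
  out <- dplyr::distinct(dplyr::bind_rows(tibble::as_tibble(graph), new))
  rdf_graph(out, prefixes = rdf_prefixes(graph))
}

rdf_bind <- function(..., prefixes = neao_namespaces()) {
  parts <- lapply(list(...), tibble::as_tibble)
  rdf_graph(dplyr::distinct(dplyr::bind_rows(parts)), prefixes = prefixes)
}

# Literal helpers -------------------------------------------------------------

literal_dtype <- function(x) {
  if (is.logical(x)) "boolean"
  else if (is.integer(x)) "integer"
  else if (is.numeric(x)) "double"
  else "string"
}

literal_lexical <- function(x) {
  if (is.logical(x)) ifelse(x, "true", "false")
  else if (is.integer(x)) sprintf("%d", x)
  else if (is.numeric(x)) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  else as.character(x)
}

#' Encode an R value as an RDF literal row
#' @param x A scalar logical, integer, double, or character value.
#' @return A list with `o`, `o_kind`, `o_dtype` suitable for [rdf_add()].
#' @export
rdf_literal <- function(x) {
  list(o = literal_lexical(x), o_kind = "literal", o_dtype = literal_dtype(x))
}

# Internal "term key" encoding: a single string that distinguishes IRIs from
# literals so join-based pattern matching can treat objects uniformly.
term_key <- function(o, o_kind, o_dtype) {
  out <- as.character(o)
  lit <- o_kind == "literal"
  out[lit] <- paste0("\"", o[lit], "\"^^", o_dtype[lit])
  out
}

term_decode <- function(key) {
  lit <- grepl("^\".*\"\\^\\^", key)
  out <- key
  out[lit] <- sub("^\"(.*)\"\\^\\^[a-z]+$", "\\1", key[lit])
  out
}

term_is_literal <- function(key) grepl("^\".*\"\\^\\^", key)

term_unkey <- function(key) {
  lit <- term_is_literal(key)
  tibble::tibble(
    o = ifelse(lit, sub("^\"(.*)\"\\^\\^[a-z]+$", "\\1", key), key),
    o_kind = ifelse(lit, "literal", "iri"),
    o_dtype = ifelse(lit, sub("^\".*\"\\^\\^([a-z]+)$", "\\1", key),
                     NA_character_)
  )
}

# Turtle serialization --------------------------------------------------------

abbreviate_iri <- function(iri, prefixes) {
  out <- paste0("<", iri, ">")
  for (pfx in names(prefixes)) {
    base <- prefixes[[pfx]]
    hit <- startsWith(iri, base)
    if (any(hit)) {
      local <- substring(iri[hit], nchar(base) + 1L)
      ok <- grepl("^[A-Za-z0-9_.-]*$", local) & local != ""
      out[hit][ok] <- paste0(pfx, ":", local[ok])
    }
  }
  blank <- startsWith(iri, "_:")
  out[blank] <- iri[blank]
  out
}

escape_turtle_string <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  x <- gsub("\n", "\\\\n", x)
  gsub("\t", "\\\\t", x)
}

format_turtle_object <- function(o, o_kind, o_dtype, prefixes) {
  out <- character(length(o))
  iri <- o_kind == "iri"
  out[iri] <- abbreviate_iri(o[iri], prefixes)
  lit <- !iri
  if (any(lit)) {
    dt <- o_dtype[lit]
    v <- o[lit]
    res <- paste0("\"", escape_turtle_string(v), "\"")
    res[dt == "integer"] <- paste0("\"", v[dt == "integer"], "\"^^xsd:integer")
    res[dt == "double"]  <- paste0("\"", v[dt == "double"], "\"^^xsd:double")
    res[dt == "boolean"] <- v[dt == "boolean"]
    out[lit] <- res
  }
  out
}

#' Serialize an RDF graph to Turtle
#'
#' Emits a prefix header followed by one statement per line. The output parses
#' back with [read_turtle()] to the identical triple set.
#'
#' @param graph An `rdf_graph`.
#' @param path Optional file path; when given the document is written there.
#' @return The Turtle document as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
write_turtle <- function(graph, path = NULL) {
  prefixes <- rdf_prefixes(graph)
  header <- sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes))
  tr <- tibble::as_tibble(graph)
  body <- character(0)
  if (nrow(tr) > 0) {
    tr <- dplyr::arrange(tr, .data$s, .data$p, .data$o)
    body <- paste(
      abbreviate_iri(tr$s, prefixes),
      abbreviate_iri(tr$p, prefixes),
      format_turtle_object(tr$o, tr$o_kind, tr$o_dtype, prefixes),
      "."
    )
  }
  doc <- c(header, "", body)
  if (!is.null(path)) {
    writeLines(doc, path, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

# Turtle parsing (subset: @prefix declarations; statements built from IRIs,
# prefixed names, blank-node labels, literals with optional ^^datatype,
# booleans, 'a', and the ';' / ',' abbreviations).

tokenize_turtle <- function(text) {
  text <- paste(text, collapse = "\n")
  tokens <- character(0)
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch %in% c(" ", "\t", "\n", "\r")) { i <- i + 1L; next }
    if (ch == "#") {
      j <- regexpr("\n", substr(text, i, n))
      if (j < 0) break
      i <- i + j
      next
    }
    if (ch == "<") {
      j <- regexpr(">", substr(text, i, n))
      if (j < 0) stop("unterminated IRI in Turtle input", call. = FALSE)
      tokens <- c(tokens, substr(text, i, i + j - 1L))
      i <- i + j
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      val <- character(0)
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") {
          nxt <- substr(text, j + 1L, j + 1L)
          val <- c(val, switch(nxt, n = "\n", t = "\t", "\"" = "\"",
                               "\\" = "\\", nxt))
          j <- j + 2L
        } else if (cj == "\"") {
          break
        } else {
          val <- c(val, cj)
          j <- j + 1L
        }
      }
      if (j > n) stop("unterminated string in Turtle input", call. = FALSE)
      lex <- paste(val, collapse = "")
      i <- j + 1L
      if (substr(text, i, i + 1L) == "^^") {
        i <- i + 2L
        rest <- substr(text, i, n)
        m <- regexpr("^(<[^>]*>|[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*)", rest)
        dt <- regmatches(rest, m)
        i <- i + attr(m, "match.length")
        tokens <- c(tokens, paste0("\x01LIT\x01", lex, "\x01", dt))
      } else {
        tokens <- c(tokens, paste0("\x01LIT\x01", lex, "\x01"))
      }
      next
    }
    rest <- substr(text, i, n)
    m <- regexpr("^(@prefix|\\.|;|,|[^\\s<>\"#;,]+)", rest, perl = TRUE)
    tok <- regmatches(rest, m)
    tokens <- c(tokens, tok)
    i <- i + attr(m, "match.length")
  }
  tokens
}

resolve_turtle_term <- function(tok, prefixes) {
  if (startsWith(tok, "\x01LIT\x01")) {
    parts <- strsplit(substring(tok, 6L), "\x01", fixed = TRUE)[[1]]
    lex <- parts[1]
    dt_tok <- if (length(parts) >= 2) parts[2] else ""
    dtype <- "string"
    if (nzchar(dt_tok)) {
      dt_iri <- resolve_turtle_term(dt_tok, prefixes)$o
      dtype <- switch(sub(".*#", "", dt_iri),
                      integer = "integer", double = "double", decimal = "double",
                      boolean = "boolean", "string")
    }
    return(list(o = lex, o_kind = "literal", o_dtype = dtype))
  }
  if (startsWith(tok, "<")) {
    return(list(o = substr(tok, 2L, nchar(tok) - 1L), o_kind = "iri",
                o_dtype = NA_character_))
  }
  if (startsWith(tok, "_:")) {
    return(list(o = tok, o_kind = "iri", o_dtype = NA_character_))
  }
  if (tok %in% c("true", "false")) {
    return(list(o = tok, o_kind = "literal", o_dtype = "boolean"))
  }
  if (tok == "a") {
    return(list(o = ns_iri("rdf", "type"), o_kind = "iri",
                o_dtype = NA_character_))
  }
  if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*:", tok)) {
    pfx <- sub(":.*$", "", tok)
    local <- sub("^[^:]*:", "", tok)
    if (!pfx %in% names(prefixes)) {
      stop(sprintf("unknown prefix '%s' in Turtle input", pfx), call. = FALSE)
    }
    return(list(o = paste0(prefixes[[pfx]], local), o_kind = "iri",
                o_dtype = NA_character_))
  }
  if (grepl("^[-+]?[0-9]+$", tok)) {
    return(list(o = tok, o_kind = "literal", o_dtype = "integer"))
  }
  if (grepl("^[-+]?[0-9.eE+-]+$", tok)) {
    return(list(o = tok, o_kind = "literal", o_dtype = "double"))
  }
  stop(sprintf("cannot parse Turtle token '%s'", tok), call. = FALSE)
}

#' Parse a Turtle document
#'
#' Understands the subset emitted by [write_turtle()] (plus `;`/`,`
#' abbreviations and numeric/boolean shorthand literals).
#'
#' @param text Character vector of lines, or a single string.
#' @param path Optional path to read from instead of `text`.
#' @return An `rdf_graph`.
#' @export
read_turtle <- function(text = NULL, path = NULL) {
  if (!is.null(path)) text <- readLines(path, warn = FALSE, encoding = "UTF-8")
  tokens <- tokenize_turtle(text)
  prefixes <- character(0)
  s <- character(0); p <- character(0); o <- character(0)
  o_kind <- character(0); o_dtype <- character(0)
  i <- 1L
  subj <- NULL; pred <- NULL
  state <- "subject"
  while (i <= length(tokens)) {
    tok <- tokens[i]
    if (tok == "@prefix") {
      pfx <- sub(":$", "", tokens[i + 1L])
      iri <- resolve_turtle_term(tokens[i + 2L], prefixes)$o
      prefixes[pfx] <- iri
      stopifnot(tokens[i + 3L] == ".")
      i <- i + 4L
      next
    }
    if (tok == ".") { state <- "subject"; i <- i + 1L; next }
    if (tok == ";") { state <- "predicate"; i <- i + 1L; next }
    if (tok == ",") { state <- "object"; i <- i + 1L; next }
    term <- resolve_turtle_term(tok, prefixes)
    if (state == "subject") {
      subj <- term$o; state <- "predicate"
    } else if (state == "predicate") {
      pred <- term$o; state <- "object"
    } else {
      s <- c(s, subj); p <- c(p, pred); o <- c(o, term$o)
      o_kind <- c(o_kind, term$o_kind); o_dtype <- c(o_dtype, term$o_dtype)
    }
    i <- i + 1L
  }
  triples <- dplyr::distinct(tibble::tibble(
    s = s, p = p, o = o, o_kind = o_kind, o_dtype = o_dtype
  ))
  rdf_graph(triples, prefixes = if (length(prefixes)) prefixes else neao_namespaces())
}

#' @export
tidy.rdf_graph <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.rdf_graph <- function(x, ...) {
  tr <- tibble::as_tibble(x)
  tibble::tibble(
    n_triples = nrow(tr),
    n_subjects = dplyr::n_distinct(tr$s),
    n_predicates = dplyr::n_distinct(tr$p)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
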