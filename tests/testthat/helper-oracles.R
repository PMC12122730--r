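# Independent oracles and shared fixtures for the test suite.

# Naive fixpoint inference oracle: boolean-matrix closure, looping until
# stable. Deliberately shares no code with materialize_inferences().
brute_force_inference <- function(onto) {
  classes <- onto$classes$uri
  n <- length(classes)
  idx <- stats::setNames(seq_len(n), classes)
  M <- diag(TRUE, n)
  for (i in seq_len(nrow(onto$subclass))) {
    M[idx[[onto$subclass$sub[i]]], idx[[onto$subclass$super[i]]]] <- TRUE
  }
  restr <- onto$restrictions
  key <- paste(restr$property, restr$value, restr$value_kind)
  repeat {
    changed <- FALSE
    # transitivity
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (M[i, j]) {
        for (k in seq_len(n)) {
          if (M[j, k] && !M[i, k]) { M[i, k] <- TRUE; changed <- TRUE }
        }
      }
    }
    # restriction matching: C under restriction r, G equivalent to r
    for (a in seq_len(nrow(restr))) {
      if (restr$kind[a] == "has_substep_some") next
      for (b in seq_len(nrow(restr))) {
        if (restr$kind[b] != "equivalent_to_restriction") next
        if (key[a] == key[b] && restr$class[a] != restr$class[b]) {
          i <- idx[[restr$class[a]]]; j <- idx[[restr$class[b]]]
          if (!M[i, j]) { M[i, j] <- TRUE; changed <- TRUE }
        }
      }
    }
    if (!changed) break
  }
  pairs <- which(M, arr.ind = TRUE)
  tibble::tibble(sub = classes[pairs[, 1]], super = classes[pairs[, 2]]) |>
    dplyr::arrange(sub, super)
}

# Random small ontology (named-class DAG plus optional restriction groupings)
# for property-style inference tests.
random_small_ontology <- function(n_classes, n_edges, n_groups = 0,
                                  seed = 1) {
  set.seed(seed)
  o <- neaokg:::new_ontology()
  steps_ns <- neao_namespaces()[["neao_steps"]]
  uris <- paste0(steps_ns, "C", seq_len(n_classes))
  for (u in uris) o <- neaokg:::onto_add_class(o, u, basename(u), "test class")
  for (k in seq_len(n_edges)) {
    ij <- sort(sample.int(n_classes, 2))  # edge low -> high keeps it acyclic
    o$subclass <- dplyr::bind_rows(
      o$subclass, tibble::tibble(sub = uris[ij[1]], super = uris[ij[2]]))
  }
  o$subclass <- dplyr::distinct(o$subclass)
  if (n_groups > 0) {
    prop <- paste0(neao_namespaces()[["neao_base"]], "hasPurpose")
    for (g in seq_len(n_groups)) {
      members <- sample(uris, sample(1:3, 1))
      group <- sample(setdiff(uris, members), 1)
      val <- paste0(steps_ns, "Purpose", g)
      o <- neaokg:::onto_add_restriction(o, group,
                                         "equivalent_to_restriction",
                                         prop, val)
      for (m in members) {
        o <- neaokg:::onto_add_restriction(o, m, "subclass_of_restriction",
                                           prop, val)
      }
    }
  }
  o
}

# Independent BFS over the raw triples (no igraph): set of written-file paths
# reachable from a read file along ^used / generated / hadMember edges.
bfs_derived_paths <- function(kg, source_path) {
  tr <- tibble::as_tibble(kg)
  cap <- "http://example.org/capture#"
  prov <- "http://www.w3.org/ns/prov#"
  paths <- tr[tr$p == paste0(cap, "filePath"), c("s", "o")]
  kinds <- tr[tr$p == paste0(cap, "fileEventKind"), c("s", "o")]
  src <- intersect(paths$s[paths$o == source_path],
                   kinds$s[kinds$o == "read"])
  edges_from <- c(tr$o[tr$p == paste0(prov, "used")],
                  tr$s[tr$p == paste0(prov, "generated")],
                  tr$s[tr$p == paste0(prov, "hadMember")])
  edges_to <- c(tr$s[tr$p == paste0(prov, "used")],
                tr$o[tr$p == paste0(prov, "generated")],
                tr$o[tr$p == paste0(prov, "hadMember")])
  seen <- character(0)
  frontier <- src
  while (length(frontier)) {
    nxt <- setdiff(unique(edges_to[edges_from %in% frontier]), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  written <- kinds$s[kinds$o == "write"]
  sort(unique(paths$o[paths$s %in% intersect(seen, written)]))
}

# Scaled-down end-to-end demo shared across tests (built once per session).
.mini_cache <- new.env(parent = emptyenv())

mini_demo <- function() {
  if (!is.null(.mini_cache$res)) return(.mini_cache$res)
  out <- file.path(tempdir(), "neaokg-mini-demo")
  unlink(out, recursive = TRUE)
  cfg <- session_config(
    n_trials = 6L, n_channels = 2L, trial_duration = 2,
    short_trial_id = 3L, short_trial_duration = 0.3,
    unit_snr = c(6, 2, 5.5), unit_rate = c(20, 3, 16),
    incorrect_trials = c(3L, 5L)
  )
  res <- run_demo_analyses(out, seed = 7, variants = c("1.1", "1.3"),
                           config = cfg, renderer = "raster")
  reg <- demo_registry()
  res$runs[["2.1"]] <- run_analysis_2("2.1", res$fixture, out, 71, reg,
                                      "raster", n_surrogates = 3L)
  res$runs[["2.2"]] <- run_analysis_2("2.2", res$fixture, out, 72, reg,
                                      "raster", n_surrogates = 3L)
  res$runs[["3"]] <- run_analysis_3(out, 73, reg, "raster",
                                    n_per_process = 3L, duration = 5)
  onto <- materialize_inferences(build_neao_subset())
  kg <- demo_knowledge_graph(res$runs, onto)
  .mini_cache$res <- list(res = res, onto = onto, kg = kg, out = out)
  .mini_cache$res
}

arrange_all_cols <- function(df) {
  dplyr::arrange(tibble::as_tibble(df), dplyr::across(dplyr::everything()))
}
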