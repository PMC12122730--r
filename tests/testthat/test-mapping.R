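# Brute-force pattern-rewrite oracle for the NEAO mapping: loops over every
# triple and applies the Table-11-style rules one by one, independent of the
# vectorized implementation.
brute_force_mapping <- function(kg) {
  tr <- tibble::as_tibble(kg)
  rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  base <- function(x) paste0("http://purl.org/neao/base#", x)
  cap <- function(x) paste0("http://example.org/capture#", x)
  prov <- function(x) paste0("http://www.w3.org/ns/prov#", x)
  typed <- function(node, cls)
    any(tr$s == node & tr$p == rdf_type & tr$o == cls)

  add <- list()
  push <- function(s, p, o, kind = "iri", dt = NA_character_) {
    add[[length(add) + 1L]] <<- tibble::tibble(s = s, p = p, o = o,
                                               o_kind = kind, o_dtype = dt)
  }
  for (i in seq_len(nrow(tr))) {
    s <- tr$s[i]; p <- tr$p[i]; o <- tr$o[i]
    if (p == prov("used") && typed(s, base("AnalysisStep")) &&
        typed(o, base("Data"))) push(s, base("hasInput"), o)
    if (p == prov("generated") && typed(s, base("AnalysisStep")) &&
        typed(o, base("Data"))) push(s, base("hasOutput"), o)
    if (p == cap("hasParameter") && typed(s, base("AnalysisStep")) &&
        typed(o, base("AnalysisParameter"))) {
      push(s, base("usesParameter"), o)
      vals <- tr[tr$s == o & tr$p == cap("pairValueText"), ]
      for (j in seq_len(nrow(vals))) {
        push(o, "http://www.w3.org/1999/02/22-rdf-syntax-ns#value",
             vals$o[j], "literal", "string")
      }
    }
    if (p == cap("usedFunction") && typed(s, base("AnalysisStep"))) {
      push(s, base("isImplementedIn"), o)
      push(o, rdf_type, base("Function"))
      nm <- tr[tr$s == o & tr$p == cap("functionName"), ]
      for (j in seq_len(nrow(nm))) {
        push(o, base("nameInDefinition"), nm$o[j], "literal", "string")
      }
      pk <- tr[tr$s == o & tr$p == cap("inPackage"), ]
      for (j in seq_len(nrow(pk))) {
        pkg <- pk$o[j]
        push(o, base("isImplementedInPackage"), pkg)
        push(pkg, rdf_type, base("SoftwarePackage"))
        pn <- tr[tr$s == pkg & tr$p == cap("packageName"), ]
        for (k in seq_len(nrow(pn))) {
          push(pkg, base("packageName"), pn$o[k], "literal", "string")
        }
        pv <- tr[tr$s == pkg & tr$p == cap("packageVersion"), ]
        for (k in seq_len(nrow(pv))) {
          push(pkg, base("packageVersion"), pv$o[k], "literal", "string")
        }
      }
    }
    if (p == prov("generated") && typed(s, base("AnalysisStep"))) {
      mem <- tr[tr$s == o & tr$p == prov("hadMember"), ]
      for (j in seq_len(nrow(mem))) {
        if (typed(mem$o[j], base("Data"))) {
          push(s, base("hasOutput"), mem$o[j])
        }
      }
    }
  }
  dplyr::distinct(dplyr::bind_rows(c(list(tr), add)))
}

small_kg <- function() {
  onto <- materialize_inferences(build_neao_subset())
  ctx <- run_context("map-test", tempdir(), demo_registry())
  st <- poisson_spiketrain(20, 2, seed = 8)
  iv <- track_execution(ctx, "neurospike.statistics.isi",
                        function(spiketrain) isi(spiketrain),
                        inputs = list(spiketrain = st))
  track_execution(ctx, "neurospike.statistics.isih",
    function(intervals, bin_size, t_max) isih(intervals, bin_size, t_max),
    inputs = list(intervals = entity_ref(iv$record$outputs[1], iv$value)),
    params = list(bin_size = qty(5, "ms"), t_max = 0.25))
  track_execution(ctx, "neurospike.surrogates.trial_shift_surrogates",
    function(spiketrain, dither, n, seed) {
      set.seed(seed)
      lapply(seq_len(n), function(i) surrogate_trial_shift(spiketrain, dither))
    },
    inputs = list(spiketrain = st),
    params = list(dither = qty(30, "ms"), n = 3L, seed = 2L))
  list(kg = build_knowledge_graph(provenance_to_rdf(ctx), onto), onto = onto)
}

test_that("mapping equals the brute-force pattern rewrite on small graphs", {
  x <- small_kg()
  got <- map_container_outputs(apply_mappings(x$kg, x$onto), x$onto)
  expect_identical(arrange_all_cols(got),
                   arrange_all_cols(brute_force_mapping(x$kg)))
})

test_that("mapping is monotone and idempotent", {
  x <- small_kg()
  m1 <- map_container_outputs(apply_mappings(x$kg, x$onto), x$onto)
  expect_equal(nrow(dplyr::anti_join(tibble::as_tibble(x$kg),
                                     tibble::as_tibble(m1),
                                     by = c("s", "p", "o"))), 0)
  m2 <- map_container_outputs(apply_mappings(m1, x$onto), x$onto)
  expect_identical(arrange_all_cols(m1), arrange_all_cols(m2))
})

test_that("graphs without NEAO-typed executions pass through unchanged", {
  onto <- materialize_inferences(build_neao_subset())
  ctx <- run_context("untyped", tempdir())   # no registry: nothing annotated
  track_execution(ctx, "m.f", function(x) x + 1, inputs = list(x = 1))
  kg <- build_knowledge_graph(provenance_to_rdf(ctx), onto)
  mapped <- map_container_outputs(apply_mappings(kg, onto), onto)
  expect_identical(arrange_all_cols(kg), arrange_all_cols(mapped))
})

test_that("after mapping, hasInput/hasOutput objects are Data and usesParameter objects are AnalysisParameter", {
  x <- small_kg()
  m <- map_container_outputs(apply_mappings(x$kg, x$onto), x$onto)
  tr <- tibble::as_tibble(m)
  rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  base <- function(s) paste0("http://purl.org/neao/base#", s)
  data_nodes <- tr$s[tr$p == rdf_type & tr$o == base("Data")]
  param_nodes <- tr$s[tr$p == rdf_type & tr$o == base("AnalysisParameter")]
  expect_true(all(tr$o[tr$p == base("hasInput")] %in% data_nodes))
  expect_true(all(tr$o[tr$p == base("hasOutput")] %in% data_nodes))
  expect_true(all(tr$o[tr$p == base("usesParameter")] %in% param_nodes))
})

test_that("container outputs map hasOutput to each typed member, idempotently", {
  x <- small_kg()
  m1 <- apply_mappings(x$kg, x$onto)
  m2 <- map_container_outputs(m1, x$onto)
  base_out <- "http://purl.org/neao/base#hasOutput"
  tr1 <- tibble::as_tibble(m1); tr2 <- tibble::as_tibble(m2)
  expect_equal(sum(tr2$p == base_out) - sum(tr1$p == base_out), 3)
  m3 <- map_container_outputs(m2, x$onto)
  expect_identical(arrange_all_cols(m2), arrange_all_cols(m3))
})

test_that("SPARQL UPDATE texts and native traversals build identical graphs", {
  x <- small_kg()
  native <- map_container_outputs(apply_mappings(x$kg, x$onto), x$onto)
  via_sparql <- apply_mappings_sparql(x$kg)
  expect_identical(arrange_all_cols(native), arrange_all_cols(via_sparql))
})
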