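prov_ns <- function(x) paste0("http://www.w3.org/ns/prov#", x)
cap_ns <- function(x) paste0("http://example.org/capture#", x)

test_that("a PSD-style execution records one input, two outputs and parameters", {
  reg <- demo_registry()
  ctx <- run_context("test-run", tempdir(), reg)
  seg <- analog_segment(matrix(rnorm(500), nrow = 1), 500)
  res <- track_execution(ctx, "neurospec.spectral.welch_psd",
    function(signal, frequency_resolution, overlap_factor, window) {
      r <- welch_psd_by_resolution(signal, frequency_resolution,
                                   overlap_factor, window)
      list(r$frequencies, r)
    },
    inputs = list(signal = seg),
    params = list(frequency_resolution = qty(2, "Hz"), overlap_factor = 0.5,
                  window = "hann"))
  expect_length(res$record$inputs, 1)
  expect_length(res$record$outputs, 2)
  expect_named(res$record$params,
               c("frequency_resolution", "overlap_factor", "window"))
  g <- tibble::as_tibble(provenance_to_rdf(ctx))
  exec <- paste0(cap_ns("execution/test-run/"), res$record$sequence_index)
  types <- g$o[g$s == exec & g$p == "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"]
  expect_true("http://purl.org/neao/steps#ComputePowerSpectralDensityWelch"
              %in% types)
  # the second return (0-based index 1) is typed as PSD data
  psd_out <- res$record$outputs[2]
  expect_true(any(g$s == psd_out &
                    g$o == "http://purl.org/neao/data#PowerSpectralDensity"))
  expect_false(any(g$s == res$record$outputs[1] &
                     g$o == "http://purl.org/neao/data#PowerSpectralDensity"))
})

test_that("container returns yield one output plus membership pairs", {
  reg <- demo_registry()
  ctx <- run_context("test-run", tempdir(), reg)
  st <- poisson_spiketrain(20, 2, seed = 5)
  res <- track_execution(ctx, "neurospike.surrogates.trial_shift_surrogates",
    function(spiketrain, dither, n, seed) {
      set.seed(seed)
      lapply(seq_len(n), function(i) surrogate_trial_shift(spiketrain, dither))
    },
    inputs = list(spiketrain = st),
    params = list(dither = qty(30, "ms"), n = 30L, seed = 99L))
  expect_length(res$record$outputs, 1)
  expect_equal(nrow(res$record$memberships), 30)
  g <- tibble::as_tibble(provenance_to_rdf(ctx))
  members <- g$o[g$p == prov_ns("hadMember")]
  expect_length(unique(members), 30)
  surrogate_typed <- g$s[g$o == "http://purl.org/neao/data#SpikeTrainSurrogate"]
  expect_setequal(unique(members), unique(surrogate_typed))
})

test_that("zero-argument generators record no inputs and one output", {
  ctx <- run_context("test-run", tempdir(), demo_registry())
  res <- track_execution(ctx, "neurospike.generate.poisson_spiketrain",
    function(rate, duration, seed) poisson_spiketrain(rate, duration, seed),
    params = list(rate = qty(10, "Hz"), duration = 10, seed = 1L))
  expect_length(res$record$inputs, 0)
  expect_gte(length(res$record$outputs), 1)
})

test_that("content addressing gives identical ids for identical values within a run", {
  ctx <- run_context("test-run", tempdir())
  v <- list(a = 1:10, b = "x")
  r1 <- track_execution(ctx, "m.f", function(x) x, inputs = list(x = v))
  r2 <- track_execution(ctx, "m.g", function(x) x, inputs = list(x = v))
  expect_identical(r1$record$inputs, r2$record$inputs)
  expect_identical(r1$record$outputs, r2$record$outputs)
})

test_that("sequence indices increase along the data flow", {
  ctx <- run_context("test-run", tempdir())
  a <- track_execution(ctx, "m.make", function() rnorm(5))
  b <- track_execution(ctx, "m.use", function(x) sum(x),
                       inputs = list(x = entity_ref(a$record$outputs[1],
                                                    a$value)))
  expect_lt(a$record$sequence_index, b$record$sequence_index)
})

test_that("routine failure leaves a flagged partial record and propagates", {
  ctx <- run_context("test-run", tempdir())
  expect_error(
    track_execution(ctx, "m.bad", function(x) stop("boom"),
                    inputs = list(x = 1)),
    "boom")
  rec <- ctx$records[[length(ctx$records)]]
  expect_true(rec$failed)
  expect_length(rec$outputs, 0)
  g <- tibble::as_tibble(provenance_to_rdf(ctx))
  expect_true(any(g$p == cap_ns("failed") & g$o == "true"))
})

test_that("identical content written to two paths gives two file nodes, one digest", {
  ctx <- run_context("test-run", tempdir())
  value <- list(payload = 1:5)
  r1 <- record_file_event(ctx, file.path(tempdir(), "out/a.png"), value,
                          "write")
  r2 <- record_file_event(ctx, file.path(tempdir(), "out/b.png"), value,
                          "write")
  expect_false(identical(r1$file_node, r2$file_node))
  expect_identical(r1$content_digest, r2$content_digest)
})

test_that("parameter names disjoint from input names is enforced", {
  ctx <- run_context("test-run", tempdir())
  expect_error(
    track_execution(ctx, "m.f", function(x) x, inputs = list(x = 1),
                    params = list(x = 2)),
    "disjoint")
})

test_that("provenance serialization round-trips and is deterministic", {
  make_graph <- function() {
    ctx <- run_context("det-run", tempdir(), demo_registry(), seed = 1)
    st <- poisson_spiketrain(10, 5, seed = 3)
    iv <- track_execution(ctx, "neurospike.statistics.isi",
                          function(spiketrain) isi(spiketrain),
                          inputs = list(spiketrain = st))
    track_execution(ctx, "neurospike.statistics.cv2",
                    function(intervals) cv2(intervals),
                    inputs = list(intervals = out_ref <- entity_ref(
                      iv$record$outputs[1], iv$value)))
    provenance_to_rdf(ctx)
  }
  g1 <- make_graph(); g2 <- make_graph()
  expect_identical(arrange_all_cols(g1), arrange_all_cols(g2))
  doc <- serialize_provenance(g1)
  expect_identical(arrange_all_cols(read_turtle(doc)), arrange_all_cols(g1))
})

test_that("parameter literals carry value, unit, and formatted text", {
  ctx <- run_context("test-run", tempdir(), demo_registry())
  st <- poisson_spiketrain(20, 2, seed = 1)
  track_execution(ctx, "neurospike.surrogates.uniform_dither_surrogates",
    function(spiketrain, dither, n, seed) {
      set.seed(seed)
      lapply(seq_len(n), function(i) surrogate_uniform_dither(spiketrain, dither))
    },
    inputs = list(spiketrain = st),
    params = list(dither = qty(25, "ms"), n = 30L, seed = 4L))
  g <- tibble::as_tibble(provenance_to_rdf(ctx))
  expect_true(any(g$p == cap_ns("pairValue") & g$o == "25"))
  expect_true(any(g$p == cap_ns("pairUnit") & g$o == "ms"))
  expect_true(any(g$p == cap_ns("pairValueText") & g$o == "25.0 ms"))
  node <- g$s[g$p == cap_ns("pairValueText") & g$o == "25.0 ms"][1]
  expect_true(any(g$s == node &
                    g$o == "http://purl.org/neao/parameters#DitheringTime"))
})

test_that("graph size grows linearly with inputs, outputs and memberships", {
  n_triples <- function(k) {
    ctx <- run_context("lin-run", tempdir())
    track_execution(ctx, "m.f", function(xs) as.list(seq_len(k)),
                    inputs = list(xs = multi_input(as.list(seq_len(k) + 100))))
    nrow(provenance_to_rdf(ctx))
  }
  n10 <- n_triples(10); n20 <- n_triples(20); n40 <- n_triples(40)
  expect_equal(n40 - n20, 2 * (n20 - n10))
})
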