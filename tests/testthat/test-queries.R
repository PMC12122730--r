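# Query-engine tests over the scaled-down end-to-end demo (see helper).

test_that("derived-file chains equal the independent BFS oracle", {
  d <- mini_demo()
  got <- files_derived_from(d$kg, "i140703-001_no_raw.rds")
  expect_identical(got$output, bfs_derived_paths(d$kg, "i140703-001_no_raw.rds"))
  expect_true(all(got$input == "i140703-001_no_raw.rds"))
})

test_that("artificial-data outputs are not derived from the session file", {
  d <- mini_demo()
  got <- files_derived_from(d$kg, "i140703-001_no_raw.rds")
  expect_false(any(grepl("isi_histograms", got$output)))
  # and an unknown file yields an empty table
  expect_equal(nrow(files_derived_from(d$kg, "no/such/file.nix")), 0)
})

test_that("all_saved_files lists exactly the written files per folder", {
  d <- mini_demo()
  counts <- aggregate_by_folder(all_saved_files(d$kg), "output", 2)
  expected <- tibble::tibble(
    folder = c("isi_histograms", "reach2grasp/psd_by_trial",
               "reach2grasp/psd_by_trial_3", "reach2grasp/surrogate_isih_1",
               "reach2grasp/surrogate_isih_2"),
    n = c(6L, 5L, 5L, 2L, 2L)
  )
  expect_identical(counts, expected)
})

test_that("queries leave the graph unchanged", {
  d <- mini_demo()
  before <- nrow(d$kg)
  invisible(files_derived_from(d$kg, "i140703-001_no_raw.rds"))
  invisible(steps_for_files(d$kg, d$onto))
  invisible(parameters_for_step(d$kg, d$onto, "neao_steps:DigitalFiltering"))
  expect_equal(nrow(d$kg), before)
})

test_that("steps_for_files reports the annotated step classes on each chain", {
  d <- mini_demo()
  s <- steps_for_files(d$kg, d$onto)
  isih_file <- "isi_histograms/1.png"
  classes <- sub(".*#", "", s$step_class[s$file == isih_file])
  expect_setequal(classes, c("ComputeCV2", "ComputeInterspikeIntervalHistogram",
                             "ComputeInterspikeIntervals",
                             "GenerateStationaryPoissonProcess"))
  psd_file <- s$file[grepl("psd_by_trial/", s$file)][1]
  psd_classes <- sub(".*#", "", s$step_class[s$file == psd_file])
  expect_true(all(c("ApplyButterworthFilter", "ApplyDownsampling",
                    "ComputePowerSpectralDensityWelch") %in% psd_classes))
})

test_that("include_inferred=FALSE on a leaf class equals include_inferred=TRUE", {
  d <- mini_demo()
  leaf <- "neao_steps:ComputePowerSpectralDensityWelch"   # no subclasses
  a <- files_with_step_or_data(d$kg, d$onto, leaf, include_inferred = TRUE)
  b <- files_with_step_or_data(d$kg, d$onto, leaf, include_inferred = FALSE)
  expect_identical(a, b)
})

test_that("grouping classes resolve through the subclass closure", {
  d <- mini_demo()
  grouped <- files_with_step_or_data(d$kg, d$onto,
                                     "neao_steps:PowerSpectralDensityAnalysis",
                                     "neao_data:PowerSpectralDensity")
  expect_equal(nrow(grouped), 10)   # 5 files in each of the two Welch variants
  art <- files_with_step_or_data(d$kg, d$onto,
                                 step_class = "neao_steps:ArtificialDataGeneration")
  expect_true(all(grepl("^isi_histograms/", art$file)))
  expect_equal(nrow(art), 6)
})

test_that("a class missing from the ontology is an error naming the IRI", {
  d <- mini_demo()
  expect_error(
    files_with_step_or_data(d$kg, d$onto, "neao_steps:NoSuchStep"),
    "NoSuchStep")
})

test_that("parameter scoping restricts to executions downstream of a data class", {
  d <- mini_demo()
  scoped <- parameters_for_step(d$kg, d$onto,
                                "neao_steps:ComputeInterspikeIntervalHistogram",
                                scope_data_class = "neao_data:SpikeTrainSurrogate")
  expect_true(all(grepl("surrogate_isih", scoped$file)))
  expect_true(all(scoped$value[grepl("BinSize", scoped$parameter_class)] ==
                    "5.0 ms"))
})

test_that("upstream-step queries are directional", {
  d <- mini_demo()
  fwd <- step_preceding(d$kg, d$onto, "neao_steps:DigitalFiltering",
                        "neao_steps:PowerSpectralDensityAnalysis")
  expect_equal(nrow(fwd), 10)
  expect_true(all(grepl("ApplyButterworthFilter", fwd$earlier_step_class)))
  rev <- step_preceding(d$kg, d$onto, "neao_steps:PowerSpectralDensityAnalysis",
                        "neao_steps:DigitalFiltering")
  expect_equal(nrow(rev), 0)
})

test_that("folder aggregation counts, pivots, and handles empty input", {
  tb <- tibble::tibble(output = c("a/b/s/1.png", "a/b/s/2.png", "c/3.png"),
                       cls = c("X", "X", "Y"))
  agg <- aggregate_by_folder(tb, "output", 2)
  expect_identical(agg$folder, c("a/b", "c"))
  expect_identical(agg$n, c(2L, 1L))
  piv <- aggregate_by_folder(tb, "output", 2, pivot = "cls")
  expect_identical(piv$X, c(2L, 0L))
  expect_identical(piv$Y, c(0L, 1L))
  empty <- aggregate_by_folder(tb[0, ], "output", 2)
  expect_equal(nrow(empty), 0)
})

test_that("CSV serialization of query tables is byte-stable", {
  d <- mini_demo()
  t1 <- files_derived_from(d$kg, "i140703-001_no_raw.rds")
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_query_csv(t1, f1)
  write_query_csv(files_derived_from(d$kg, "i140703-001_no_raw.rds"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("SPARQL query texts produce the same tables as the native traversals", {
  d <- mini_demo()
  q <- sparql_select(d$kg, sparql_resource("q_all_saved_files.rq"))
  expect_identical(dplyr::arrange(tibble::tibble(output = q$path), output),
                   all_saved_files(d$kg))
  qd <- sparql_select(d$kg, sparql_resource("q_files_derived_from.rq"))
  qd <- dplyr::arrange(tibble::tibble(input = qd$src, output = qd$out),
                       input, output)
  expect_identical(qd, files_derived_from(d$kg, "i140703-001_no_raw.rds"))
  qs <- sparql_select(d$kg, sparql_resource("q_steps_for_files.rq"))
  qs <- dplyr::arrange(tibble::tibble(file = qs$path, step_class = qs$class),
                       file, step_class)
  expect_identical(qs, steps_for_files(d$kg, d$onto, minimal = FALSE))
})
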