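# The three demonstration analyses, run end-to-end on the synthetic session:
#
#   1.1  PSD per trial, Welch (resolution 2 Hz, overlap 0.5, hann)  [pkg A]
#   1.2  PSD per trial, multitaper                                   [pkg A]
#   1.3  PSD per trial, Welch (samples parameterization 500/250/125) [pkg B]
#   2.1  surrogate ISIHs, uniform spike dithering (25 ms)
#   2.2  surrogate ISIHs, trial shifting (30 ms)
#   3    ISIHs + CV2 of 100 Poisson + 100 gamma(1) trains, 10 Hz, 100 s
#
# Each run annotates its routines with NEAO classes, captures provenance,
# writes one PNG per result plus a Turtle sidecar, and the captured graphs
# feed the knowledge-graph queries. Output layout:
#   <out>/reach2grasp/psd_by_trial{,_2,_3}/<session>/<trial id>.png
#   <out>/reach2grasp/surrogate_isih_{1,2}/<session>/<unit id>.png
#   <out>/isi_histograms/<index>.png

pkg_a <- c(name = "neurospec", version = "0.14.0")
pkg_b <- c(name = "scisig", version = "1.11.4")

#' Default annotation registry for the demo analyses
#'
#' Maps every analysis routine of the three demo scenarios to its NEAO step
#' class, its arguments to Data/AnalysisParameter classes, and its returns to
#' Data classes (plot and file I/O routines stay unannotated).
#'
#' @return An `annotation_registry`.
#' @export
demo_registry <- function() {
  reg <- annotation_registry()
  reg_add <- function(id, ...) register_annotation(reg, id, neao_annotation(...))

  reg_add("demo.session.get_trial",
          returns = list("0" = "neao_data:TimeSeries"))
  reg_add("demo.session.select_unit_trains",
          returns = list("0" = "neao_data:SpikeTrain"), container_returns = 0L)

  reg_add("neurosig.signal.butterworth_filter",
          step_class = "neao_steps:ApplyButterworthFilter",
          arguments = list(signal = "neao_data:TimeSeries",
                           order = "neao_params:FilterOrder",
                           cutoff = "neao_params:LowPassFrequencyCutoff"),
          returns = list("0" = "neao_data:TimeSeries"))
  reg_add("neurosig.signal.downsample",
          step_class = "neao_steps:ApplyDownsampling",
          arguments = list(signal = "neao_data:TimeSeries"),
          returns = list("0" = "neao_data:TimeSeries"))

  reg_add("neurospec.spectral.welch_psd",
          step_class = "neao_steps:ComputePowerSpectralDensityWelch",
          arguments = list(
            signal = "neao_data:TimeSeries",
            frequency_resolution = "neao_params:FrequencyResolution",
            overlap_factor = "neao_params:WindowOverlapFactor",
            window = "neao_params:WindowFunction"),
          returns = list("1" = "neao_data:PowerSpectralDensity"))
  reg_add("neurospec.spectral.multitaper_psd",
          step_class = "neao_steps:ComputePowerSpectralDensityMultitaper",
          arguments = list(signal = "neao_data:TimeSeries"),
          returns = list("1" = "neao_data:PowerSpectralDensity"))
  reg_add("scisig.signal.welch",
          step_class = "neao_steps:ComputePowerSpectralDensityWelch",
          arguments = list(
            signal = "neao_data:TimeSeries",
            fs = "neao_params:SamplingFrequency",
            nperseg = "neao_params:WindowLengthSamples",
            noverlap = "neao_params:WindowOverlapSamples",
            window = "neao_params:WindowFunction"),
          returns = list("1" = "neao_data:PowerSpectralDensity"))

  isi_args <- list(spiketrain = "neao_data:SpikeTrain")
  reg_add("neurospike.statistics.isi",
          step_class = "neao_steps:ComputeInterspikeIntervals",
          arguments = isi_args,
          returns = list("0" = "neao_data:InterspikeIntervals"))
  reg_add("neurospike.statistics.isi_list",
          step_class = "neao_steps:ComputeInterspikeIntervals",
          arguments = list(spiketrains = "neao_data:SpikeTrain"),
          returns = list("0" = "neao_data:InterspikeIntervals"),
          container_returns = 0L)
  reg_add("neurospike.statistics.isih",
          step_class = "neao_steps:ComputeInterspikeIntervalHistogram",
          arguments = list(intervals = "neao_data:InterspikeIntervals",
                           bin_size = "neao_params:BinSize"),
          returns = list("0" = "neao_data:InterspikeIntervalHistogram"))
  reg_add("neurospike.statistics.isih_list",
          step_class = "neao_steps:ComputeInterspikeIntervalHistogram",
          arguments = list(intervals = "neao_data:InterspikeIntervals",
                           bin_size = "neao_params:BinSize"),
          returns = list("0" = "neao_data:InterspikeIntervalHistogram"),
          container_returns = 0L)
  reg_add("neurospike.statistics.sum_histograms",
          step_class = "neao_steps:ApplySum",
          arguments = list(histograms = "neao_data:InterspikeIntervalHistogram"),
          returns = list("0" = "neao_data:InterspikeIntervalHistogram"))
  reg_add("neurospike.statistics.mean_histograms",
          step_class = "neao_steps:ComputeMean",
          arguments = list(histograms = "neao_data:InterspikeIntervalHistogram"))
  reg_add("neurospike.statistics.std_histograms",
          step_class = "neao_steps:ComputeStandardDeviation",
          arguments = list(histograms = "neao_data:InterspikeIntervalHistogram"))
  reg_add("neurospike.statistics.cv2",
          step_class = "neao_steps:ComputeCV2",
          arguments = list(intervals = "neao_data:InterspikeIntervals"),
          returns = list("0" = "neao_data:CV2"))

  reg_add("neurospike.generate.poisson_spiketrain",
          step_class = "neao_steps:GenerateStationaryPoissonProcess",
          arguments = list(rate = "neao_params:FiringRate"),
          returns = list("0" = "neao_data:SpikeTrain"))
  reg_add("neurospike.generate.gamma_spiketrain",
          step_class = "neao_steps:GenerateStationaryGammaProcess",
          arguments = list(rate = "neao_params:FiringRate",
                           shape = "neao_params:ShapeFactor"),
          returns = list("0" = "neao_data:SpikeTrain"))

  reg_add("neurospike.surrogates.uniform_dither_surrogates",
          step_class = "neao_steps:GenerateUniformSpikeDitheringSurrogate",
          arguments = list(spiketrain = "neao_data:SpikeTrain",
                           dither = "neao_params:DitheringTime"),
          returns = list("0" = "neao_data:SpikeTrainSurrogate"),
          container_returns = 0L)
  reg_add("neurospike.surrogates.trial_shift_surrogates",
          step_class = "neao_steps:GenerateTrialShiftingSurrogate",
          arguments = list(spiketrain = "neao_data:SpikeTrain",
                           dither = "neao_params:DitheringTime"),
          returns = list("0" = "neao_data:SpikeTrainSurrogate"),
          container_returns = 0L)
  reg
}

# Rendering -------------------------------------------------------------------

render_png <- function(path, draw, renderer = "auto", width = 560,
                       height = 400) {
  use_device <- switch(renderer,
                       device = TRUE,
                       raster = FALSE,
                       auto = isTRUE(unname(capabilities("png"))))
  if (use_device) {
    ok <- tryCatch({
      grDevices::png(path, width = width, height = height)
      on.exit(grDevices::dev.off(), add = TRUE)
      draw()
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(invisible(path))
  }
  # headless fallback: still a valid PNG image
  img <- matrix(seq(0, 1, length.out = 64 * 64), nrow = 64)
  png::writePNG(img, target = path)
  invisible(path)
}

draw_psd <- function(psd, max_frequency = 100) {
  keep <- psd$frequencies <= max_frequency
  pw <- psd$power
  if (is.null(dim(pw))) pw <- matrix(pw, ncol = 1)
  graphics::matplot(psd$frequencies[keep], pw[keep, , drop = FALSE],
                    type = "l", lty = 1, xlab = "frequency (Hz)",
                    ylab = "power density",
                    main = sprintf("PSD (%s)", psd$method))
}

draw_isih <- function(hist, surrogate_mean = NULL, surrogate_sd = NULL,
                      title = "ISIH") {
  mids <- (hist$bin_edges[-1] + hist$bin_edges[-length(hist$bin_edges)]) / 2
  ylim <- range(0, hist$counts,
                if (!is.null(surrogate_mean)) surrogate_mean + surrogate_sd)
  graphics::plot(mids * 1000, hist$counts, type = "h", lwd = 3,
                 col = "steelblue", xlab = "ISI (ms)", ylab = "count",
                 main = title, ylim = ylim)
  if (!is.null(surrogate_mean)) {
    graphics::lines(mids * 1000, surrogate_mean, col = "darkorange", lwd = 2)
    if (!is.null(surrogate_sd)) {
      graphics::lines(mids * 1000, surrogate_mean + surrogate_sd,
                      col = "darkorange", lty = 2)
      graphics::lines(mids * 1000, pmax(surrogate_mean - surrogate_sd, 0),
                      col = "darkorange", lty = 2)
    }
  }
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 7919) %% 2147483646 + 1)
}

demo_run_report <- function(variant, ctx, prov, files, sidecar, out_root) {
  structure(list(variant = variant, ctx = ctx, prov = prov, files = files,
                 sidecar = sidecar, out_root = out_root),
            class = "demo_run")
}

#' @export
print.demo_run <- function(x, ...) {
  cat(sprintf("<demo_run %s> %d files, %d provenance records\n",
              x$variant, length(x$files), length(x$ctx$records)))
  invisible(x)
}

#' @export
glance.demo_run <- function(x, ...) {
  dplyr::mutate(glance(x$ctx), variant = x$variant, .before = 1)
}

session_read <- function(ctx, fixture) {
  if (is.na(fixture$session_file_path)) {
    stop("fixture has no session_file_path; generate_session(path = ...)",
         call. = FALSE)
  }
  rec <- record_file_event(ctx, fixture$session_file_path, fixture, "read")
  entity_ref(rec$outputs[1], fixture)
}

# entity_ref to the j-th output of a track_execution() result
out_ref <- function(res, j = 1L, value = NULL) {
  if (is.null(value)) {
    value <- if (is.list(res$value) && length(res$record$outputs) > 1) {
      res$value[[j]]
    } else {
      res$value
    }
  }
  entity_ref(res$record$outputs[j], value)
}

# entity_refs to the members of a container return
member_refs <- function(res) {
  Map(entity_ref, res$record$memberships$member, res$value)
}

# Analysis 1 ------------------------------------------------------------------

#' Run demo Analysis 1 (PSD per trial)
#'
#' Per trial: Butterworth low-pass (order 4, 250 Hz) -> downsampling to
#' 500 Hz -> PSD (variant 1.1: Welch by frequency resolution; 1.2:
#' multitaper; 1.3: Welch by samples) -> plot (0-100 Hz) -> PNG named by
#' trial id. The trial that is shorter than one Welch window raises an
#' insufficient-data error and is skipped, so 160 of the 161 trials produce
#' files. Provenance is captured and serialized to a Turtle sidecar.
#'
#' @param variant "1.1", "1.2", or "1.3".
#' @param fixture A `session_fixture` with a serialized session file.
#' @param out_root Output root directory.
#' @param seed Seed for this run.
#' @param registry Annotation registry (defaults to [demo_registry()]).
#' @param renderer "auto", "device", or "raster" (headless fallback).
#' @return A `demo_run` report.
#' @export
run_analysis_1 <- function(variant = c("1.1", "1.2", "1.3"), fixture,
                           out_root, seed = 1L, registry = demo_registry(),
                           renderer = "auto") {
  variant <- match.arg(variant)
  folder <- switch(variant, "1.1" = "psd_by_trial", "1.2" = "psd_by_trial_2",
                   "1.3" = "psd_by_trial_3")
  out_dir <- file.path(out_root, "reach2grasp", folder, fixture$session_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ctx <- run_context(paste0("analysis-", variant), out_root, registry, seed)
  set.seed(seed)

  sref <- session_read(ctx, fixture)
  files <- character(0)
  for (tr in seq_along(fixture$segments)) {
    seg <- track_execution(ctx, "demo.session.get_trial",
      function(session, trial_id) session$segments[[trial_id]],
      inputs = list(session = sref), params = list(trial_id = tr))
    filt <- track_execution(ctx, "neurosig.signal.butterworth_filter",
      function(signal, order, cutoff) butterworth_lowpass(signal, order, cutoff),
      inputs = list(signal = out_ref(seg)),
      params = list(order = 4L, cutoff = qty(250, "Hz")))
    ds <- track_execution(ctx, "neurosig.signal.downsample",
      function(signal, target_rate) downsample(signal, target_rate),
      inputs = list(signal = out_ref(filt)), params = list(target_rate = 500L))

    psd <- tryCatch(
      switch(variant,
        "1.1" = track_execution(ctx, "neurospec.spectral.welch_psd",
          function(signal, frequency_resolution, overlap_factor, window) {
            r <- welch_psd_by_resolution(signal, frequency_resolution,
                                         overlap_factor, window)
            list(r$frequencies, r)
          },
          inputs = list(signal = out_ref(ds)),
          params = list(frequency_resolution = qty(2, "Hz"),
                        overlap_factor = 0.5, window = "hann"),
          package = pkg_a),
        "1.2" = track_execution(ctx, "neurospec.spectral.multitaper_psd",
          function(signal, num_tapers, bandwidth_param) {
            # the analysis requests the same 2 Hz spectral resolution as the
            # Welch variants; a segment shorter than 0.5 s cannot support it
            if (ncol(signal$samples) / signal$sampling_rate < 0.5) {
              stop("insufficient data: segment shorter than the 0.5 s window",
                   call. = FALSE)
            }
            r <- multitaper_psd(signal, num_tapers, bandwidth_param)
            list(r$frequencies, r)
          },
          inputs = list(signal = out_ref(ds)),
          params = list(num_tapers = 4L, bandwidth_param = 4L),
          package = pkg_a),
        "1.3" = track_execution(ctx, "scisig.signal.welch",
          function(signal, fs, nperseg, noverlap, window) {
            r <- welch_psd_by_samples(signal, fs, nperseg, noverlap, window)
            list(r$frequencies, r)
          },
          inputs = list(signal = out_ref(ds)),
          params = list(fs = 500.0, nperseg = 250L, noverlap = 125L,
                        window = "hann"),
          package = pkg_b)
      ),
      error = function(e) NULL  # trial too short for the spectral window
    )
    if (is.null(psd)) next

    fig <- track_execution(ctx, "demo.plot.plot_psd",
      function(psd, max_frequency) {
        list(kind = "psd_plot", method = psd$method,
             parameterization = psd$parameterization,
             frequencies = psd$frequencies, power = psd$power,
             max_frequency = max_frequency)
      },
      inputs = list(psd = out_ref(psd, 2L)),
      params = list(max_frequency = 100L))
    path <- file.path(out_dir, paste0(fixture$segments[[tr]]$trial_id, ".png"))
    render_png(path, function() draw_psd(psd$value[[2]]), renderer)
    record_file_event(ctx, path, fig$record$outputs[1], "write")
    files <- c(files, path)
  }

  prov <- provenance_to_rdf(ctx)
  sidecar <- file.path(out_root, "reach2grasp", folder, "provenance.ttl")
  serialize_provenance(prov, sidecar)
  demo_run_report(variant, ctx, prov, files, sidecar, out_root)
}

# Analysis 2 ------------------------------------------------------------------

sum_histogram_list <- function(histograms) {
  counts <- Reduce(`+`, lapply(histograms, function(h) h$counts))
  structure(list(bin_edges = histograms[[1]]$bin_edges, counts = counts),
            class = "isi_histogram")
}

#' Run demo Analysis 2 (surrogate interspike-interval histograms)
#'
#' Selects the units with SNR >= 5 and mean firing rate >= 15 Hz across all
#' correct trials; per unit computes the pooled 5 ms ISIH over the 142
#' correct trials, generates 30 surrogates per trial (variant 2.1: uniform
#' spike dithering with 25 ms dither; 2.2: trial shifting with 30 ms), pools
#' surrogate ISIHs across trials per surrogate index, and plots the data ISIH
#' with the mean and standard deviation of the 30 surrogate ISIHs. One PNG
#' per unit.
#'
#' @inheritParams run_analysis_1
#' @param variant "2.1" or "2.2".
#' @param n_surrogates Surrogates generated per trial.
#' @param bin_size Histogram bin width ([qty()] in "ms").
#' @param t_max Upper edge of the histograms, seconds.
#' @return A `demo_run` report.
#' @export
run_analysis_2 <- function(variant = c("2.1", "2.2"), fixture, out_root,
                           seed = 1L, registry = demo_registry(),
                           renderer = "auto", n_surrogates = 30L,
                           bin_size = qty(5, "ms"), t_max = 0.25) {
  variant <- match.arg(variant)
  folder <- switch(variant, "2.1" = "surrogate_isih_1",
                   "2.2" = "surrogate_isih_2")
  dither <- switch(variant, "2.1" = qty(25, "ms"), "2.2" = qty(30, "ms"))
  routine <- switch(variant,
    "2.1" = "neurospike.surrogates.uniform_dither_surrogates",
    "2.2" = "neurospike.surrogates.trial_shift_surrogates")
  surrogate_fn <- switch(variant, "2.1" = surrogate_uniform_dither,
                         "2.2" = surrogate_trial_shift)
  out_dir <- file.path(out_root, "reach2grasp", folder, fixture$session_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ctx <- run_context(paste0("analysis-", variant), out_root, registry, seed)
  set.seed(seed)

  sref <- session_read(ctx, fixture)
  units <- selected_units(fixture)
  files <- character(0)

  for (u in units) {
    sel <- track_execution(ctx, "demo.session.select_unit_trains",
      function(session, unit_id, min_snr, min_rate) {
        session$trains[[unit_id]][which(session$correct)]
      },
      inputs = list(session = sref),
      params = list(unit_id = u, min_snr = 5L, min_rate = qty(15, "Hz")))
    train_refs <- member_refs(sel)

    data_isi <- track_execution(ctx, "neurospike.statistics.isi_list",
      function(spiketrains) lapply(spiketrains, isi),
      inputs = list(spiketrains = multi_input(train_refs)))
    data_hist <- track_execution(ctx, "neurospike.statistics.isih_list",
      function(intervals, bin_size, t_max)
        lapply(intervals, function(v) isih(v, bin_size, t_max)),
      inputs = list(intervals = multi_input(member_refs(data_isi))),
      params = list(bin_size = bin_size, t_max = t_max))
    data_sum <- track_execution(ctx, "neurospike.statistics.sum_histograms",
      function(histograms) sum_histogram_list(histograms),
      inputs = list(histograms = multi_input(member_refs(data_hist))))

    surr <- vector("list", length(train_refs))
    for (t in seq_along(train_refs)) {
      sub_seed <- derive_seed(seed, match(u, units) * 1000L + t)
      surr[[t]] <- track_execution(ctx, routine,
        function(spiketrain, dither, n, seed) {
          set.seed(seed)
          lapply(seq_len(n), function(i) surrogate_fn(spiketrain, dither))
        },
        inputs = list(spiketrain = train_refs[[t]]),
        params = list(dither = dither, n = n_surrogates, seed = sub_seed))
      surr[[t]] <- member_refs(surr[[t]])
    }

    pooled <- vector("list", n_surrogates)
    for (s in seq_len(n_surrogates)) {
      strains <- lapply(surr, function(x) x[[s]])
      s_isi <- track_execution(ctx, "neurospike.statistics.isi_list",
        function(spiketrains) lapply(spiketrains, isi),
        inputs = list(spiketrains = multi_input(strains)))
      s_hist <- track_execution(ctx, "neurospike.statistics.isih_list",
        function(intervals, bin_size, t_max)
          lapply(intervals, function(v) isih(v, bin_size, t_max)),
        inputs = list(intervals = multi_input(member_refs(s_isi))),
        params = list(bin_size = bin_size, t_max = t_max))
      s_sum <- track_execution(ctx, "neurospike.statistics.sum_histograms",
        function(histograms) sum_histogram_list(histograms),
        inputs = list(histograms = multi_input(member_refs(s_hist))))
      pooled[[s]] <- out_ref(s_sum)
    }

    s_mean <- track_execution(ctx, "neurospike.statistics.mean_histograms",
      function(histograms)
        Reduce(`+`, lapply(histograms, function(h) h$counts)) /
          length(histograms),
      inputs = list(histograms = multi_input(pooled)))
    s_sd <- track_execution(ctx, "neurospike.statistics.std_histograms",
      function(histograms) {
        m <- do.call(rbind, lapply(histograms, function(h) h$counts))
        apply(m, 2, stats::sd)
      },
      inputs = list(histograms = multi_input(pooled)))

    fig <- track_execution(ctx, "demo.plot.plot_surrogate_isih",
      function(data_isih, surrogate_mean, surrogate_sd) {
        list(kind = "surrogate_isih_plot", data = data_isih,
             mean = surrogate_mean, sd = surrogate_sd)
      },
      inputs = list(data_isih = out_ref(data_sum),
                    surrogate_mean = out_ref(s_mean),
                    surrogate_sd = out_ref(s_sd)))
    path <- file.path(out_dir, paste0(u, ".png"))
    render_png(path, function()
      draw_isih(data_sum$value, s_mean$value, s_sd$value,
                title = sprintf("%s (%s surrogates)", u,
                                if (variant == "2.1") "uniform dithering"
                                else "trial shifting")),
      renderer)
    record_file_event(ctx, path, fig$record$outputs[1], "write")
    files <- c(files, path)
  }

  prov <- provenance_to_rdf(ctx)
  sidecar <- file.path(out_root, "reach2grasp", folder, "provenance.ttl")
  serialize_provenance(prov, sidecar)
  demo_run_report(variant, ctx, prov, files, sidecar, out_root)
}

# Analysis 3 ------------------------------------------------------------------

#' Run demo Analysis 3 (ISIHs of artificial spike trains)
#'
#' Generates 100 stationary-Poisson and 100 stationary-gamma (shape 1) spike
#' trains at 10 Hz for 100 s; per train computes the interspike intervals,
#' the CV2 variability measure, and a 10 ms ISIH, then plots and saves one
#' PNG per train (Poisson trains 1-100, gamma trains 101-200, named by list
#' index).
#'
#' @inheritParams run_analysis_1
#' @param n_per_process Number of trains per generator.
#' @param rate Target firing rate (Hz).
#' @param duration Train duration (s).
#' @param bin_size Histogram bin width ([qty()] in "ms").
#' @param t_max Upper edge of the histograms, seconds.
#' @return A `demo_run` report.
#' @export
run_analysis_3 <- function(out_root, seed = 1L, registry = demo_registry(),
                           renderer = "auto", n_per_process = 100L,
                           rate = qty(10, "Hz"), duration = 100,
                           bin_size = qty(10, "ms"), t_max = 1) {
  out_dir <- file.path(out_root, "isi_histograms")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ctx <- run_context("analysis-3", out_root, registry, seed)
  set.seed(seed)
  files <- character(0)
  cv2_values <- numeric(0)
  rates <- numeric(0)

  for (i in seq_len(2L * n_per_process)) {
    is_poisson <- i <= n_per_process
    sub_seed <- derive_seed(seed, i)
    gen <- if (is_poisson) {
      track_execution(ctx, "neurospike.generate.poisson_spiketrain",
        function(rate, duration, seed)
          poisson_spiketrain(rate, duration, seed = seed),
        params = list(rate = rate, duration = duration, seed = sub_seed))
    } else {
      track_execution(ctx, "neurospike.generate.gamma_spiketrain",
        function(rate, shape, duration, seed)
          gamma_spiketrain(rate, shape, duration, seed = seed),
        params = list(rate = rate, shape = 1L, duration = duration,
                      seed = sub_seed))
    }
    train <- gen$value
    rates <- c(rates, length(train$times) / duration)

    iv <- track_execution(ctx, "neurospike.statistics.isi",
      function(spiketrain) isi(spiketrain),
      inputs = list(spiketrain = out_ref(gen)))
    cv <- track_execution(ctx, "neurospike.statistics.cv2",
      function(intervals) cv2(intervals),
      inputs = list(intervals = out_ref(iv)))
    cv2_values <- c(cv2_values, cv$value)
    hist <- track_execution(ctx, "neurospike.statistics.isih",
      function(intervals, bin_size, t_max) isih(intervals, bin_size, t_max),
      inputs = list(intervals = out_ref(iv)),
      params = list(bin_size = bin_size, t_max = t_max))

    fig <- track_execution(ctx, "demo.plot.plot_isih",
      function(isih, cv2_value)
        list(kind = "isih_plot", isih = isih, cv2 = cv2_value),
      inputs = list(isih = out_ref(hist), cv2_value = out_ref(cv)))
    path <- file.path(out_dir, paste0(i, ".png"))
    render_png(path, function()
      draw_isih(hist$value,
                title = sprintf("spike train %d (CV2 = %.2f)", i, cv$value)),
      renderer)
    record_file_event(ctx, path, fig$record$outputs[1], "write")
    files <- c(files, path)
  }

  prov <- provenance_to_rdf(ctx)
  sidecar <- file.path(out_dir, "provenance.ttl")
  serialize_provenance(prov, sidecar)
  rep <- demo_run_report("3", ctx, prov, files, sidecar, out_root)
  rep$cv2_values <- cv2_values
  rep$rates <- rates
  rep
}

# Orchestration ---------------------------------------------------------------

#' Run demo analyses end-to-end
#'
#' Generates the synthetic session (serialized under `out_root`), runs the
#' requested analysis variants with seeds derived from `seed`, and returns
#' the run reports plus the fixture.
#'
#' @param out_root Output root directory.
#' @param seed Master seed.
#' @param variants Subset of c("1.1","1.2","1.3","2.1","2.2","3").
#' @param config Session configuration.
#' @param renderer Renderer passed to the runs.
#' @return List with `fixture` and `runs` (named by variant).
#' @export
run_demo_analyses <- function(out_root, seed = 1L,
                              variants = c("1.1", "1.2", "1.3",
                                           "2.1", "2.2", "3"),
                              config = session_config(),
                              renderer = "auto") {
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  session_path <- file.path(out_root,
                            paste0(config$session_id, "_no_raw.rds"))
  fixture <- generate_session(config, seed = seed, path = session_path)
  registry <- demo_registry()
  runs <- list()
  for (v in variants) {
    run_seed <- derive_seed(seed, match(v, c("1.1", "1.2", "1.3",
                                             "2.1", "2.2", "3")))
    runs[[v]] <- switch(v,
      "1.1" = , "1.2" = , "1.3" =
        run_analysis_1(v, fixture, out_root, run_seed, registry, renderer),
      "2.1" = , "2.2" =
        run_analysis_2(v, fixture, out_root, run_seed, registry, renderer),
      "3" = run_analysis_3(out_root, run_seed, registry, renderer)
    )
  }
  list(fixture = fixture, runs = runs)
}

#' Build the mapped knowledge graph from demo run reports
#'
#' Combines the provenance of the given runs with the ontology, applies the
#' NEAO property mappings and the container-output mapping, and indexes the
#' result for querying.
#'
#' @param runs List of `demo_run` reports (or the `runs` element of
#'   [run_demo_analyses()]).
#' @param onto Materialized ontology (built and materialized by default).
#' @return An indexed, mapped `rdf_graph`.
#' @export
demo_knowledge_graph <- function(runs,
                                 onto = materialize_inferences(
                                   build_neao_subset())) {
  prov <- lapply(runs, function(r) r$prov)
  kg <- build_knowledge_graph(prov, onto)
  kg <- apply_mappings(kg, onto)
  kg <- map_container_outputs(kg, onto)
  kg_index(kg)
}
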