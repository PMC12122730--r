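# Continuous-signal processing for the demo analyses: Butterworth low-pass
# filtering (zero-phase), integer-factor downsampling, and PSD estimation by
# the Welch and multitaper methods.
#
# Both Welch parameterizations (frequency resolution + overlap factor vs.
# window/overlap lengths in samples) drive the same estimator core, so
# equivalent settings give bit-identical spectra. Windows use the periodic
# Hann convention; spectra are one-sided densities (power/Hz).

#' Construct a multi-channel analog segment
#'
#' @param samples Numeric matrix, channels x time samples (a vector is treated
#'   as one channel).
#' @param sampling_rate Sampling rate in Hz.
#' @param t_start Segment start time in seconds.
#' @param trial_id Integer trial identifier.
#' @param correct Logical behavioral flag.
#' @return An `analog_segment`.
#' @export
analog_segment <- function(samples, sampling_rate, t_start = 0,
                           trial_id = NA_integer_, correct = NA) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), sampling_rate > 0, all(is.finite(samples)))
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 t_start = t_start, trial_id = as.integer(trial_id),
                 correct = correct),
            class = "analog_segment")
}

#' @export
print.analog_segment <- function(x, ...) {
  cat(sprintf("<analog_segment> trial %s: %d channel(s) x %d samples @ %g Hz\n",
              x$trial_id, nrow(x$samples), ncol(x$samples), x$sampling_rate))
  invisible(x)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth IIR low-pass filter and applies it forward-backward
#' (zero phase). The two passes square the magnitude response, so the gain at
#' the cutoff frequency is -6 dB; DC gain is exactly 1.
#'
#' @param x An `analog_segment`.
#' @param order Filter order (the order of each pass).
#' @param cutoff Cutoff frequency, Hz (a [qty()] in "Hz" is accepted).
#' @return The filtered `analog_segment` (same length and sampling rate).
#' @export
butterworth_lowpass <- function(x, order = 4L, cutoff) {
  fc <- qty_value(cutoff)
  if (fc >= x$sampling_rate / 2) {
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 fc, x$sampling_rate / 2), call. = FALSE)
  }
  bf <- signal::butter(order, fc / (x$sampling_rate / 2), type = "low")
  # forward-backward filtering over an odd-reflection extension, so edge
  # transients decay inside the padding and DC passes with gain exactly 1
  n <- ncol(x$samples)
  pad <- min(n - 1L, max(9L * (order + 1L),
                         ceiling(6 * x$sampling_rate / fc)))
  filtered <- t(apply(x$samples, 1, function(ch) {
    ext <- c(2 * ch[1] - ch[(pad + 1):2], ch,
             2 * ch[n] - ch[(n - 1):(n - pad)])
    y <- signal::filter(bf, ext)
    y <- rev(signal::filter(bf, rev(y)))
    y[(pad + 1):(pad + n)]
  }))
  analog_segment(filtered, x$sampling_rate, x$t_start, x$trial_id, x$correct)
}

#' Downsample by an integer factor
#'
#' Keeps every k-th sample, k = sampling_rate / target_rate. No additional
#' filtering is applied (the preceding low-pass is the anti-alias stage).
#'
#' @param x An `analog_segment`.
#' @param target_rate Target sampling rate in Hz; must divide the current
#'   rate.
#' @return The downsampled `analog_segment`.
#' @export
downsample <- function(x, target_rate) {
  tr <- qty_value(target_rate)
  k <- x$sampling_rate / tr
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf("sampling rate %g Hz is not an integer multiple of %g Hz",
                 x$sampling_rate, tr), call. = FALSE)
  }
  k <- as.integer(round(k))
  idx <- seq(1L, ncol(x$samples), by = k)
  analog_segment(x$samples[, idx, drop = FALSE], tr, x$t_start, x$trial_id,
                 x$correct)
}

window_taper <- function(name, n) {
  switch(name,
         hann = 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n)),  # periodic Hann
         boxcar = rep(1, n),
         stop(sprintf("unknown window function '%s'", name), call. = FALSE))
}

psd_result <- function(frequencies, power, method,
                       parameterization = method) {
  # `parameterization` records which API produced the estimate (the result
  # object a toolbox returns differs by entry point even when the numbers
  # agree), so equivalent spectra from different routines remain distinct
  # provenance entities.
  structure(list(frequencies = frequencies, power = power, method = method,
                 parameterization = parameterization),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> %s: %d frequencies, 0-%g Hz\n", x$method,
              length(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' @export
tidy.psd_result <- function(x, ...) {
  pw <- x$power
  if (is.null(dim(pw))) pw <- matrix(pw, ncol = 1)
  nch <- ncol(pw)
  tibble::tibble(
    channel = rep(seq_len(nch), each = length(x$frequencies)),
    frequency = rep(x$frequencies, nch),
    power = as.vector(pw),
    method = x$method
  )
}

welch_core <- function(mat, fs, nwin, nover, window,
                       parameterization = "welch") {
  n_t <- ncol(mat)
  if (nwin > n_t) {
    stop(sprintf(paste("insufficient data: segment of %d samples is shorter",
                       "than one window of %d samples"), n_t, nwin),
         call. = FALSE)
  }
  if (nover >= nwin) stop("window overlap must be smaller than the window",
                          call. = FALSE)
  w <- window_taper(window, nwin)
  step <- nwin - nover
  starts <- seq(1L, n_t - nwin + 1L, by = step)
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nwin %/% 2L + 1L
  pw <- matrix(0, nrow = nfreq, ncol = nrow(mat))
  for (s0 in starts) {
    seg <- mat[, s0:(s0 + nwin - 1L), drop = FALSE]
    tap <- sweep(seg, 2, w, `*`)
    ft <- stats::mvfft(t(tap))
    per <- Mod(ft[seq_len(nfreq), , drop = FALSE])^2 * scale
    # one-sided: double everything except DC (and Nyquist when nwin is even)
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nwin %% 2L == 0L) dbl[nfreq] <- 1
    pw <- pw + per * dbl
  }
  pw <- pw / length(starts)
  freqs <- (seq_len(nfreq) - 1L) * fs / nwin
  psd_result(freqs, pw, "welch", parameterization)
}

#' Welch PSD, parameterized by frequency resolution and overlap factor
#'
#' Splits the signal into windows of `sampling_rate / frequency_resolution`
#' samples with fractional overlap, tapers each window, and averages the
#' one-sided periodograms (density normalization, power/Hz). A segment
#' shorter than one window raises an "insufficient data" error.
#'
#' @param x An `analog_segment`.
#' @param frequency_resolution Desired frequency resolution in Hz ([qty()]
#'   accepted).
#' @param overlap_factor Fractional overlap between consecutive windows.
#' @param window Window function name ("hann" or "boxcar").
#' @return A `psd_result` (power is a frequency x channel matrix).
#' @export
welch_psd_by_resolution <- function(x, frequency_resolution,
                                    overlap_factor = 0.5, window = "hann") {
  df <- qty_value(frequency_resolution)
  stopifnot(df > 0, overlap_factor >= 0, overlap_factor < 1)
  nwin <- as.integer(round(x$sampling_rate / df))
  nover <- as.integer(round(overlap_factor * nwin))
  welch_core(x$samples, x$sampling_rate, nwin, nover, window,
             parameterization = "frequency_resolution")
}

#' Welch PSD, parameterized in samples
#'
#' Same estimator as [welch_psd_by_resolution()], with the window and overlap
#' lengths given in samples and the sampling rate passed as a unit-less
#' number. Equivalent settings (e.g. 500/250/125 vs. 2 Hz at overlap 0.5)
#' give element-wise identical spectra.
#'
#' @param x An `analog_segment`.
#' @param sampling_rate Sampling rate as a plain number.
#' @param window_length Window length in samples.
#' @param overlap_length Overlap length in samples (must be < window length).
#' @param window Window function name.
#' @return A `psd_result`.
#' @export
welch_psd_by_samples <- function(x, sampling_rate, window_length,
                                 overlap_length, window = "hann") {
  welch_core(x$samples, sampling_rate, as.integer(window_length),
             as.integer(overlap_length), window, parameterization = "samples")
}

# DPSS (Slepian) tapers from the standard symmetric tridiagonal eigenproblem;
# cached per (n, nw, k) since all trials share the segment length.
dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw, k) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  hit <- get0(key, envir = dpss_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  w <- nw / n
  m <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * m) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * ((n - 1):1) / 2
  A <- matrix(0, n, n)
  diag(A) <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  # sign convention: symmetric tapers positive mean, antisymmetric positive slope
  for (j in seq_len(k)) {
    tj <- tapers[, j]
    if (j %% 2 == 1) {
      if (sum(tj) < 0) tapers[, j] <- -tj
    } else {
      if (sum((n - 1 - 2 * m) * tj) < 0) tapers[, j] <- -tj
    }
  }
  assign(key, tapers, envir = dpss_cache)
  tapers
}

#' Multitaper PSD estimate
#'
#' Averages periodograms of the full segment under `num_tapers` orthogonal
#' DPSS (Slepian) tapers computed from the standard tridiagonal eigenproblem;
#' density normalization, frequency grid as in Welch with the window spanning
#' the whole segment.
#'
#' @param x An `analog_segment`.
#' @param num_tapers Number of tapers (must not exceed `2 * bandwidth_param - 1`).
#' @param bandwidth_param Time-bandwidth product NW.
#' @return A `psd_result`.
#' @export
multitaper_psd <- function(x, num_tapers = 4L, bandwidth_param = 4) {
  stopifnot(num_tapers >= 1)
  if (num_tapers > floor(2 * bandwidth_param - 1)) {
    stop(sprintf(
      "num_tapers = %d exceeds the %d tapers supported by bandwidth_param = %g",
      num_tapers, floor(2 * bandwidth_param - 1), bandwidth_param),
      call. = FALSE)
  }
  n <- ncol(x$samples)
  tapers <- dpss_tapers(n, bandwidth_param, as.integer(num_tapers))
  fs <- x$sampling_rate
  nfreq <- n %/% 2L + 1L
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (n %% 2L == 0L) dbl[nfreq] <- 1
  pw <- matrix(0, nrow = nfreq, ncol = nrow(x$samples))
  for (j in seq_len(ncol(tapers))) {
    tap <- sweep(x$samples, 2, tapers[, j], `*`)
    ft <- stats::mvfft(t(tap))
    pw <- pw + Mod(ft[seq_len(nfreq), , drop = FALSE])^2 * dbl / fs
  }
  pw <- pw / ncol(tapers)
  freqs <- (seq_len(nfreq) - 1L) * fs / n
  psd_result(freqs, pw, "multitaper")
}

#' @export
autoplot.psd_result <- function(object, max_frequency = 100, ...) {
  df <- tidy(object)
  df <- df[df$frequency <= max_frequency, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$power,
                                   group = .data$channel,
                                   color = factor(.data$channel))) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "frequency (Hz)", y = "power density",
                  color = "channel",
                  title = sprintf("PSD (%s)", object$method)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
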