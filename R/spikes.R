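# Spike-train machinery: interspike intervals, interval histograms, the CV2
# local variability statistic, stationary Poisson/gamma generators, and the
# uniform-dithering and trial-shifting surrogate methods.

#' Construct a spike train
#'
#' @param times Spike times in seconds, strictly sorted within
#'   `[t_start, t_stop)`.
#' @param t_start,t_stop Observation window in seconds.
#' @param unit_id Unit identifier string.
#' @param annotations Named list of annotations (e.g. `snr`, `mean_rate`).
#' @return A `spike_train`.
#' @export
spike_train <- function(times, t_start = 0, t_stop, unit_id = NA_character_,
                        annotations = list()) {
  times <- as.numeric(times)
  stopifnot(t_stop > t_start)
  if (length(times)) {
    stopifnot(all(times >= t_start), all(times < t_stop),
              !is.unsorted(times, strictly = FALSE))
  }
  structure(list(times = times, t_start = t_start, t_stop = t_stop,
                 unit_id = unit_id, annotations = annotations),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s> %d spikes in [%g, %g) s\n",
              x$unit_id, length(x$times), x$t_start, x$t_stop))
  invisible(x)
}

#' Interspike intervals
#' @param train A `spike_train` or a numeric vector of spike times.
#' @return Numeric vector of successive differences (length max(0, n - 1)).
#' @export
isi <- function(train) {
  times <- if (inherits(train, "spike_train")) train$times else train
  if (length(times) < 2) return(numeric(0))
  diff(times)
}

#' Interspike interval histogram
#'
#' Half-open uniform bins `[0, t_max)`; intervals at or beyond `t_max` are
#' discarded.
#'
#' @param intervals Numeric vector of intervals in seconds.
#' @param bin_size Bin width in seconds ([qty()] in "ms" accepted).
#' @param t_max Upper edge of the histogram in seconds.
#' @return An `isi_histogram` with `bin_edges` and `counts`.
#' @export
isih <- function(intervals, bin_size, t_max = 0.25) {
  bw <- as_seconds(bin_size)
  stopifnot(bw > 0, t_max > bw)
  edges <- seq(0, t_max, by = bw)
  if (abs(edges[length(edges)] - t_max) > 1e-12) edges <- c(edges, t_max)
  kept <- intervals[intervals >= 0 & intervals < edges[length(edges)]]
  idx <- pmin(floor(kept / bw) + 1L, length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts),
            class = "isi_histogram")
}

#' @export
print.isi_histogram <- function(x, ...) {
  cat(sprintf("<isi_histogram> %d bins of %.1f ms, %d intervals\n",
              length(x$counts), diff(x$bin_edges[1:2]) * 1000, sum(x$counts)))
  invisible(x)
}

#' @export
tidy.isi_histogram <- function(x, ...) {
  tibble::tibble(
    bin_left = x$bin_edges[-length(x$bin_edges)],
    bin_right = x$bin_edges[-1],
    count = x$counts
  )
}

#' @export
autoplot.isi_histogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2 * 1000,
                                   y = .data$count)) +
    ggplot2::geom_col(width = diff(object$bin_edges[1:2]) * 1000,
                      fill = "steelblue") +
    ggplot2::labs(x = "interspike interval (ms)", y = "count") +
    ggplot2::theme_minimal()
}

#' CV2 local variability of interspike intervals
#'
#' The mean over consecutive interval pairs of
#' `2 * |I(i+1) - I(i)| / (I(i+1) + I(i))`. Dimensionless; expectation 1 for
#' a stationary Poisson process.
#'
#' @param intervals Numeric vector with at least two intervals.
#' @return The CV2 value.
#' @export
cv2 <- function(intervals) {
  if (length(intervals) < 2) {
    stop("CV2 is undefined for fewer than two interspike intervals",
         call. = FALSE)
  }
  a <- intervals[-length(intervals)]
  b <- intervals[-1]
  mean(2 * abs(b - a) / (b + a))
}

#' Generate a stationary Poisson spike train
#'
#' Exponential interspike intervals with mean `1/rate`, accumulated over
#' `[0, duration)`.
#'
#' @param rate Firing rate in Hz ([qty()] accepted).
#' @param duration Duration in seconds.
#' @param seed Optional seed for reproducibility.
#' @param unit_id Unit identifier.
#' @return A `spike_train`.
#' @export
poisson_spiketrain <- function(rate, duration, seed = NULL,
                               unit_id = NA_character_) {
  r <- qty_value(rate)
  stopifnot(r > 0, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n_guess <- max(10, ceiling(r * duration + 6 * sqrt(r * duration)))
  times <- cumsum(stats::rexp(n_guess, rate = r))
  while (length(times) && times[length(times)] < duration) {
    times <- c(times, times[length(times)] +
                 cumsum(stats::rexp(n_guess, rate = r)))
  }
  spike_train(times[times < duration], 0, duration, unit_id,
              annotations = list(mean_rate = r))
}

#' Generate a stationary gamma-process spike train
#'
#' Interspike intervals drawn from a gamma distribution with the given shape
#' and mean `1/rate` (scale `1/(shape * rate)`); shape 1 is equivalent to a
#' Poisson process.
#'
#' @param rate Target firing rate in Hz ([qty()] accepted).
#' @param shape Shape factor of the gamma distribution.
#' @param duration Duration in seconds.
#' @param seed Optional seed.
#' @param unit_id Unit identifier.
#' @return A `spike_train`.
#' @export
gamma_spiketrain <- function(rate, shape, duration, seed = NULL,
                             unit_id = NA_character_) {
  r <- qty_value(rate)
  k <- qty_value(shape)
  stopifnot(r > 0, k > 0, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n_guess <- max(10, ceiling(r * duration + 6 * sqrt(r * duration / k)))
  draw <- function(n) stats::rgamma(n, shape = k, rate = k * r)
  times <- cumsum(draw(n_guess))
  while (length(times) && times[length(times)] < duration) {
    times <- c(times, times[length(times)] + cumsum(draw(n_guess)))
  }
  spike_train(times[times < duration], 0, duration, unit_id,
              annotations = list(mean_rate = r))
}

#' Uniform spike-dithering surrogate
#'
#' Displaces each spike independently by `Uniform(-dither, +dither)`; spikes
#' displaced outside the spike-train window are excluded, so the spike count
#' never increases.
#'
#' @param train A `spike_train`.
#' @param dither Dither time in seconds ([qty()] in "ms" accepted).
#' @param seed Optional seed.
#' @return A surrogate `spike_train`.
#' @export
surrogate_uniform_dither <- function(train, dither, seed = NULL) {
  d <- as_seconds(dither)
  stopifnot(d > 0)
  if (!is.null(seed)) set.seed(seed)
  shifted <- train$times + stats::runif(length(train$times), -d, d)
  shifted <- sort(shifted[shifted >= train$t_start & shifted < train$t_stop])
  spike_train(shifted, train$t_start, train$t_stop, train$unit_id,
              train$annotations)
}

#' Trial-shifting surrogate
#'
#' Applies one shift `Uniform(-dither, +dither)` to all spikes of the train,
#' wrapping circularly within `[t_start, t_stop)`; the spike count is
#' preserved exactly and the interspike interval distribution is (nearly)
#' preserved.
#'
#' @param train A `spike_train`.
#' @param dither Dither time in seconds ([qty()] in "ms" accepted).
#' @param seed Optional seed.
#' @return A surrogate `spike_train`.
#' @export
surrogate_trial_shift <- function(train, dither, seed = NULL) {
  d <- as_seconds(dither)
  stopifnot(d > 0)
  if (!is.null(seed)) set.seed(seed)
  shift <- stats::runif(1, -d, d)
  dur <- train$t_stop - train$t_start
  shifted <- ((train$times - train$t_start + shift) %% dur) + train$t_start
  spike_train(sort(shifted), train$t_start, train$t_stop, train$unit_id,
              train$annotations)
}
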