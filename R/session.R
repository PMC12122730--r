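# Synthetic recording session emulating the structure of a multi-electrode
# reach-to-grasp dataset: 161 trials of multi-channel continuous signals at
# 1000 Hz (white noise plus a 20 Hz sinusoid, so PSDs show a verifiable
# peak), and 10 spiking units with SNR / firing-rate annotations of which
# exactly 6 pass the selection filter (SNR >= 5 and mean rate >= 15 Hz).
# Trial 142 is generated shorter than one Welch window at 500 Hz so the
# "too short" skip logic, not a hard-coded list, yields 160 PSD files.

#' Configuration of the synthetic recording session
#'
#' Defaults are the study conditions of the demo analyses: 161 trials of 4 s
#' (trial 142: 0.3 s), 142 correct trials, 5 channels at 1000 Hz, and ten
#' units whose SNR/rate annotations leave exactly six units passing the
#' selection filter.
#'
#' @param n_trials Number of trials.
#' @param n_channels Number of continuous-signal channels.
#' @param trial_duration Trial duration in seconds.
#' @param short_trial_id Trial generated too short for the Welch window.
#' @param short_trial_duration Duration of that trial in seconds.
#' @param sampling_rate Continuous-signal sampling rate in Hz.
#' @param sine_freq,sine_amp Frequency (Hz) and amplitude of the embedded
#'   sinusoid.
#' @param noise_sd Standard deviation of the white noise.
#' @param unit_snr,unit_rate Per-unit SNR annotations and mean firing rates
#'   (Hz).
#' @param incorrect_trials Trial ids flagged as behaviorally incorrect.
#' @param session_id Session identifier used in output paths.
#' @return A `session_config` list.
#' @export
session_config <- function(n_trials = 161L, n_channels = 5L,
                           trial_duration = 4, short_trial_id = 142L,
                           short_trial_duration = 0.3, sampling_rate = 1000,
                           sine_freq = 20, sine_amp = 2, noise_sd = 1,
                           unit_snr = c(6.1, 2.0, 5.0, 7.3, 5.5,
                                        9.0, 4.2, 8.1, 6.7, 3.0),
                           unit_rate = c(20, 25, 16, 3, 18,
                                         22, 30, 17, 15, 19),
                           incorrect_trials = c(142L, seq(8L, by = 8L,
                                                          length.out = 18L)),
                           session_id = "i140703-001") {
  stopifnot(trial_duration > 0, short_trial_duration > 0, sampling_rate > 0,
            all(unit_rate > 0), length(unit_snr) == length(unit_rate))
  structure(list(
    n_trials = as.integer(n_trials), n_channels = as.integer(n_channels),
    trial_duration = trial_duration, short_trial_id = as.integer(short_trial_id),
    short_trial_duration = short_trial_duration,
    sampling_rate = sampling_rate, sine_freq = sine_freq,
    sine_amp = sine_amp, noise_sd = noise_sd,
    unit_snr = unit_snr, unit_rate = unit_rate,
    incorrect_trials = as.integer(unique(incorrect_trials)),
    session_id = session_id
  ), class = "session_config")
}

#' Generate the synthetic recording session
#'
#' Continuous signals are white noise plus a sinusoid; spikes per unit and
#' trial are drawn as a stationary Poisson process at the unit's annotated
#' rate. The fixture is serialized to `path` (when given) so analysis runs
#' can record reading it as a file event.
#'
#' @param config A [session_config()].
#' @param seed Seed controlling all randomness.
#' @param path Optional file path for the serialized session.
#' @return A `session_fixture` with `segments` (list of [analog_segment()]),
#'   `trains` (per unit, per trial [spike_train()]), a `units` annotation
#'   table, and `session_file_path`.
#' @export
generate_session <- function(config = session_config(), seed = 1L,
                             path = NULL) {
  set.seed(seed)
  n_units <- length(config$unit_rate)
  unit_ids <- sprintf("Unit %d", seq_len(n_units))

  durations <- rep(config$trial_duration, config$n_trials)
  if (!is.na(config$short_trial_id) &&
      config$short_trial_id <= config$n_trials) {
    durations[config$short_trial_id] <- config$short_trial_duration
  }
  correct <- !(seq_len(config$n_trials) %in% config$incorrect_trials)

  segments <- vector("list", config$n_trials)
  for (tr in seq_len(config$n_trials)) {
    n_s <- round(durations[tr] * config$sampling_rate)
    tt <- (seq_len(n_s) - 1) / config$sampling_rate
    mat <- matrix(stats::rnorm(config$n_channels * n_s, sd = config$noise_sd),
                  nrow = config$n_channels)
    phases <- stats::runif(config$n_channels, 0, 2 * pi)
    for (ch in seq_len(config$n_channels)) {
      mat[ch, ] <- mat[ch, ] +
        config$sine_amp * sin(2 * pi * config$sine_freq * tt + phases[ch])
    }
    segments[[tr]] <- analog_segment(mat, config$sampling_rate, t_start = 0,
                                     trial_id = tr, correct = correct[tr])
  }

  trains <- vector("list", n_units)
  names(trains) <- unit_ids
  for (u in seq_len(n_units)) {
    trains[[u]] <- vector("list", config$n_trials)
    for (tr in seq_len(config$n_trials)) {
      st <- poisson_spiketrain(config$unit_rate[u], durations[tr],
                               unit_id = unit_ids[u])
      st$annotations <- list(snr = config$unit_snr[u],
                             mean_rate = config$unit_rate[u],
                             trial_id = tr)
      trains[[u]][[tr]] <- st
    }
  }

  fixture <- structure(list(
    config = config,
    segments = segments,
    trains = trains,
    units = tibble::tibble(unit_id = unit_ids, snr = config$unit_snr,
                           mean_rate = config$unit_rate),
    correct = correct,
    session_id = config$session_id,
    session_file_path = NA_character_,
    seed = seed
  ), class = "session_fixture")

  if (!is.null(path)) {
    fixture$session_file_path <- path
    saveRDS(fixture, path)
  }
  fixture
}

#' Units passing the selection filter (SNR >= 5 and mean rate >= 15 Hz)
#' @param fixture A `session_fixture`.
#' @return Character vector of selected unit ids.
#' @export
selected_units <- function(fixture) {
  u <- fixture$units
  u$unit_id[u$snr >= 5 & u$mean_rate >= 15]
}

#' @export
print.session_fixture <- function(x, ...) {
  cat(sprintf(
    "<session_fixture %s> %d trials (%d correct), %d channels, %d units\n",
    x$session_id, length(x$segments), sum(x$correct), x$config$n_channels,
    nrow(x$units)))
  invisible(x)
}

#' @export
tidy.session_fixture <- function(x, ...) {
  tibble::tibble(
    trial_id = vapply(x$segments, function(s) s$trial_id, integer(1)),
    n_samples = vapply(x$segments, function(s) ncol(s$samples), integer(1)),
    duration = vapply(x$segments, function(s)
      ncol(s$samples) / s$sampling_rate, numeric(1)),
    correct = x$correct
  )
}

#' @export
glance.session_fixture <- function(x, ...) {
  tibble::tibble(
    session_id = x$session_id,
    n_trials = length(x$segments),
    n_correct = sum(x$correct),
    n_units = nrow(x$units),
    n_selected_units = length(selected_units(x)),
    seed = x$seed
  )
}
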