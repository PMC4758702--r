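#' Generative parameters of one simulated BCI user
#'
#' A `user_profile` collects everything the synthetic-EEG generator needs to
#' emulate one participant: the strength of the mu rhythm over each motor
#' source, its centre frequency, the per-class depth of the event-related
#' desynchronization (ERD) during motor imagery, the 1/f background level and
#' the occipital alpha gain with closed eyes.
#'
#' `erd_depth` is the fractional amplitude reduction of the SMR oscillation
#' at the class-appropriate source during imagery: 0 leaves the rhythm
#' untouched (the inefficient-user model), 1 suppresses it completely. The
#' spatial pattern is contralateral: left-hand imagery attenuates the source
#' under C4, right-hand imagery the source under C3, foot imagery the source
#' under Cz.
#'
#' @param smr_amplitude_c3,smr_amplitude_c4 amplitude of the mu oscillation
#'   injected at the left/right motor source (signal units, >= 0)
#' @param mu_peak_hz centre frequency of the mu rhythm (Hz, typically 8-13)
#' @param beta_peak_hz centre frequency of the weaker beta component (Hz)
#' @param erd_depth named list/vector with entries `left`, `right`, `foot`,
#'   each in \[0, 1\]
#' @param noise_scale multiplier on the 1/f background (> 0)
#' @param eyes_closed_alpha_gain occipital alpha multiplier with eyes closed
#'   (> 1)
#' @param seed integer seed for this user's private noise stream
#' @return object of class `user_profile`
#' @export
#' @examples
#' p <- user_profile(erd_depth = c(left = 0.6, right = 0.6, foot = 0.3))
#' p$erd_depth$right
user_profile <- function(smr_amplitude_c3 = 2.0,
                         smr_amplitude_c4 = 2.0,
                         mu_peak_hz = 10.5,
                         beta_peak_hz = 21,
                         erd_depth = c(left = 0.5, right = 0.5, foot = 0.4),
                         noise_scale = 1.0,
                         eyes_closed_alpha_gain = 2.0,
                         seed = 1L) {
  erd_depth <- as.list(erd_depth)
  need <- c("left", "right", "foot")
  if (!all(need %in% names(erd_depth)))
    stop_invalid("erd_depth must name all of: %s", paste(need, collapse = ", "))
  if (any(unlist(erd_depth[need]) < 0 | unlist(erd_depth[need]) > 1))
    stop_invalid("erd_depth values must lie in [0, 1]")
  if (smr_amplitude_c3 < 0 || smr_amplitude_c4 < 0)
    stop_invalid("SMR amplitudes must be >= 0")
  if (noise_scale <= 0 && noise_scale != 0)
    stop_invalid("noise_scale must be positive")
  structure(list(
    smr_amplitude_c3 = smr_amplitude_c3,
    smr_amplitude_c4 = smr_amplitude_c4,
    mu_peak_hz = mu_peak_hz,
    beta_peak_hz = beta_peak_hz,
    erd_depth = erd_depth[need],
    noise_scale = noise_scale,
    eyes_closed_alpha_gain = eyes_closed_alpha_gain,
    seed = as.integer(seed)
  ), class = "user_profile")
}

#' Session protocol configuration
#'
#' Timing, run structure, frequency bands and adaptation coefficients of the
#' seven-run co-adaptive protocol. Defaults follow the study protocol: three
#' 40-trial runs with positively biased feedback, then four 80-trial runs
#' with real feedback; trials are 2 s fixation cross + 1 s cue + 3 s
#' feedback with a cursor update every 40 ms; the unsupervised pooled-mean
#' update coefficient is 0.05.
#'
#' @param runs integer vector of trials per run
#' @param phases character vector, `"biased"` or `"real"` per run
#' @param fs simulation sampling rate (Hz)
#' @param cross_s,cue_to_feedback_s,feedback_s trial segment durations (s)
#' @param cursor_update_ms cursor update period (ms)
#' @param break_every,break_s pause schedule within runs (trials, s)
#' @param classes motor-imagery class labels
#' @param alpha_band,beta_band `(low, high)` Hz band edges
#' @param uc_pooled_mean unsupervised pooled-mean update coefficient
#' @param uc_class_mean supervised class-mean update coefficient
#' @param uc_inv_cov adaptive inverse-covariance update coefficient
#' @param decay_per_step centre-decay of the biased cursor per 40 ms step
#' @param online_window_s causal feature window for online classification (s)
#' @param resting_cycles,resting_open_s,resting_closed_s resting protocol
#' @return object of class `session_config`
#' @export
session_config <- function(runs = c(40L, 40L, 40L, 80L, 80L, 80L, 80L),
                           phases = c("biased", "biased", "biased",
                                      "real", "real", "real", "real"),
                           fs = 100,
                           cross_s = 2, cue_to_feedback_s = 1, feedback_s = 3,
                           cursor_update_ms = 40,
                           break_every = 20L, break_s = 15,
                           classes = c("left", "right", "foot"),
                           alpha_band = c(8, 15),
                           beta_band = c(16, 32),
                           uc_pooled_mean = 0.05,
                           uc_class_mean = 0.05,
                           uc_inv_cov = 0.015,
                           decay_per_step = 0.02,
                           online_window_s = 0.75,
                           resting_cycles = 10L,
                           resting_open_s = 15,
                           resting_closed_s = 15) {
  if (length(runs) != length(phases))
    stop_invalid("runs and phases must have equal length")
  if (!all(phases %in% c("biased", "real")))
    stop_invalid("phases must be 'biased' or 'real'")
  for (b in list(alpha_band, beta_band))
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2])
      stop_invalid("bands must be (low, high) with 0 < low < high")
  for (uc in c(uc_pooled_mean, uc_class_mean, uc_inv_cov))
    if (uc <= 0 || uc >= 1) stop_invalid("update coefficients must be in (0, 1)")
  structure(list(
    runs = as.integer(runs), phases = phases, fs = fs,
    cross_s = cross_s, cue_to_feedback_s = cue_to_feedback_s,
    feedback_s = feedback_s,
    cursor_update_ms = cursor_update_ms,
    break_every = as.integer(break_every), break_s = break_s,
    classes = classes,
    alpha_band = alpha_band, beta_band = beta_band,
    uc_pooled_mean = uc_pooled_mean,
    uc_class_mean = uc_class_mean,
    uc_inv_cov = uc_inv_cov,
    decay_per_step = decay_per_step,
    online_window_s = online_window_s,
    resting_cycles = as.integer(resting_cycles),
    resting_open_s = resting_open_s,
    resting_closed_s = resting_closed_s
  ), class = "session_config")
}

#' Continuous multichannel EEG recording
#'
#' @param data channels x samples numeric matrix
#' @param channel_labels character vector, one per row of `data`
#' @param fs sampling rate (Hz)
#' @param markers data.frame with columns `sample` (1-based index) and
#'   `label`
#' @return object of class `eeg_recording`
#' @export
eeg_recording <- function(data, channel_labels, fs,
                          markers = data.frame(sample = integer(),
                                               label = character())) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_labels))
    stop_invalid("channel_labels length must equal number of rows of data")
  if (anyDuplicated(channel_labels))
    stop_invalid("channel_labels must be unique")
  if (nrow(markers) > 0 &&
      (any(markers$sample < 1) || any(markers$sample > ncol(data))))
    stop_invalid("marker sample indices must lie within the recording")
  rownames(data) <- channel_labels
  structure(list(data = data, channel_labels = channel_labels,
                 fs = fs, markers = markers),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d markers\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$markers)))
  invisible(x)
}

#' @export
print.user_profile <- function(x, ...) {
  cat(sprintf(
    "<user_profile> mu %.1f Hz, SMR amp C3/C4 = %.2f/%.2f, ERD l/r/f = %.2f/%.2f/%.2f, noise %.2f\n",
    x$mu_peak_hz, x$smr_amplitude_c3, x$smr_amplitude_c4,
    x$erd_depth$left, x$erd_depth$right, x$erd_depth$foot, x$noise_scale))
  invisible(x)
}
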