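# Synthetic EEG generator: 1/f background, spatially mixed mu/beta sources,
# class-dependent contralateral ERD, and the eyes-open/eyes-closed resting
# protocol.

#' Multichannel 1/f ("pink") background noise
#'
#' Spectrally shaped Gaussian noise whose power spectral density falls off as
#' 1/f above 1 Hz, the standard model for the EEG noise floor. Channels are
#' weakly correlated through a fixed mixing of shared pink sources, emulating
#' volume conduction of distant generators.
#'
#' @param n_channels number of channels
#' @param duration_s duration in seconds (> 0)
#' @param fs sampling rate in Hz (> 0)
#' @param noise_scale amplitude multiplier; 0 yields an all-zero array
#' @param seed integer seed
#' @return `n_channels x (duration_s * fs)` numeric matrix
#' @export
#' @examples
#' x <- pink_noise(2, 10, 100, 1, seed = 1)
#' dim(x)
pink_noise <- function(n_channels, duration_s, fs, noise_scale = 1, seed = 1L) {
  if (duration_s <= 0 || fs <= 0)
    stop_invalid("duration_s and fs must be positive")
  n <- round(duration_s * fs)
  if (noise_scale == 0) return(matrix(0, n_channels, n))
  with_seed(seed, {
    own <- pink_mat(n_channels, n, fs)
    n_src <- max(4L, min(12L, n_channels))
    shared <- pink_mat(n_src, n, fs)
    M <- shared_mixing(n_channels, n_src)
    rho <- 0.4
    noise_scale * (sqrt(1 - rho^2) * own + rho * (M %*% shared))
  })
}

# FFT-shaped pink noise, unit variance per channel in expectation.
# The spectrum is flattened below 1 Hz so the variance stays finite.
pink_mat <- function(nch, n, fs) {
  f <- fs * (0:(n - 1)) / n
  f[f > fs / 2] <- fs - f[f > fs / 2]          # two-sided frequency axis
  amp <- 1 / sqrt(pmax(f, 1))
  amp[1] <- 0                                   # remove DC
  norm <- sqrt(sum(amp^2) / n)                 # -> unit sample variance
  white <- matrix(stats::rnorm(nch * n), n, nch)
  X <- stats::mvfft(white) * amp
  t(Re(stats::mvfft(X, inverse = TRUE)) / n) / norm
}

shared_mixing <- function(nch, n_src) {
  # deterministic mixing weights, independent of the caller's seed
  M <- with_seed(980451L, matrix(stats::rnorm(nch * n_src), nch, n_src))
  M / sqrt(rowSums(M^2))
}

# Band-limited oscillation with slow amplitude modulation and phase jitter.
# Returns a unit-amplitude carrier; callers scale and gate it.
smr_oscillation <- function(n, fs, f0) {
  w_j <- max(3L, round(fs / 4))                 # ~250 ms smoothing
  jitter <- 0.4 * sqrt(w_j) * moving_average(stats::rnorm(n), w_j)
  phase <- cumsum(2 * pi * (f0 + jitter) / fs)
  w_e <- max(3L, round(fs / 2))                 # ~500 ms envelope scale
  env <- 1 + 0.35 * sqrt(w_e) * moving_average(stats::rnorm(n), w_e)
  env <- pmax(0.2, env)
  env * sin(phase + stats::runif(1, 0, 2 * pi))
}

# Gaussian spatial kernel of a source at (x0, y0) over the montage.
source_kernel <- function(montage, x0, y0, sigma = 0.2) {
  exp(-((montage$x - x0)^2 + (montage$y - y0)^2) / (2 * sigma^2))
}

source_positions <- function() {
  list(C3 = c(-0.45, 0), C4 = c(0.45, 0), Cz = c(0, 0), Oz = c(0, -0.95))
}

# Contralateral ERD topography: fraction of the class erd_depth applied to
# each oscillatory source. Left-hand imagery desynchronizes the right motor
# source (under C4) most, and vice versa; foot imagery targets the midline.
erd_topography <- function(mi_class) {
  switch(mi_class,
         left  = c(C3 = 0.30, C4 = 1.00, Cz = 0.15),
         right = c(C3 = 1.00, C4 = 0.30, Cz = 0.15),
         foot  = c(C3 = 0.20, C4 = 0.20, Cz = 1.00),
         stop_invalid("unknown motor-imagery class '%s'", mi_class))
}

# Amplitude of each oscillatory source for a profile. The midline source is
# a fixed fraction of the lateral ones; occipital alpha has a fixed base
# amplitude modulated by the eyes-closed gain at rest.
source_amplitudes <- function(profile) {
  c(C3 = profile$smr_amplitude_c3,
    C4 = profile$smr_amplitude_c4,
    Cz = 0.8 * (profile$smr_amplitude_c3 + profile$smr_amplitude_c4) / 2,
    Oz = 1.5)
}

# Core mixer: background + oscillatory sources with per-source, per-sample
# amplitude gates. gates: named list source -> numeric vector length n.
synthesize_eeg <- function(profile, n, fs, gates, seed) {
  montage <- default_montage()
  nch <- nrow(montage)
  bg <- pink_noise(nch, n / fs, fs, profile$noise_scale, seed = seed)
  amps <- source_amplitudes(profile)
  pos <- source_positions()
  out <- bg
  with_seed(child_seed(seed, 17L), {
    for (src in names(pos)) {
      a <- amps[[src]]
      if (a == 0) next
      f0 <- if (src == "Oz") 10 else profile$mu_peak_hz
      carrier <- smr_oscillation(n, fs, f0)
      if (src != "Oz" && !is.null(profile$beta_peak_hz)) {
        carrier <- carrier + 0.4 * smr_oscillation(n, fs, profile$beta_peak_hz)
      }
      gate <- if (is.null(gates[[src]])) rep(1, n) else gates[[src]]
      k <- source_kernel(montage, pos[[src]][1], pos[[src]][2])
      out <- out + a * (k %o% (gate * carrier))
    }
  })
  out
}

#' Simulate the resting-state measurement
#'
#' Ten cycles of 15 s eyes-open / 15 s eyes-closed EEG (configurable). The mu
#' rhythm is mixed into the C3/C4 neighbourhoods with the profile's
#' amplitudes throughout; occipital alpha is amplified by
#' `eyes_closed_alpha_gain` during closed-eye segments. State markers
#' (`eyes_open` / `eyes_closed`) are placed at every transition.
#'
#' @param profile a [user_profile()]
#' @param config a [session_config()]
#' @return an [eeg_recording()]
#' @export
#' @examples
#' rec <- simulate_resting_state(user_profile(seed = 3), session_config(fs = 100))
#' nrow(rec$markers)   # 20 state markers
simulate_resting_state <- function(profile, config = session_config()) {
  fs <- config$fs
  cyc <- config$resting_cycles
  n_open <- round(config$resting_open_s * fs)
  n_closed <- round(config$resting_closed_s * fs)
  n <- cyc * (n_open + n_closed)

  open_mask <- rep(rep(c(TRUE, FALSE), times = c(n_open, n_closed)), cyc)
  gain <- ifelse(open_mask, 1, profile$eyes_closed_alpha_gain)
  # smooth the occipital gain transition over 250 ms
  gain <- moving_average(gain, max(3L, 2 * round(0.125 * fs) + 1L))

  gates <- list(Oz = gain)
  data <- synthesize_eeg(profile, n, fs, gates, seed = child_seed(profile$seed, 1L))

  seg_starts <- cumsum(c(1L, rep(c(n_open, n_closed), cyc)))[seq_len(2 * cyc)]
  markers <- data.frame(
    sample = as.integer(seg_starts),
    label = rep(c("eyes_open", "eyes_closed"), cyc),
    stringsAsFactors = FALSE
  )
  eeg_recording(data, default_montage()$channel, fs, markers)
}

#' Simulate one motor-imagery trial
#'
#' A 6 s segment: 2 s fixation cross, 1 s cue, 3 s feedback. From cue onset
#' to the end of the trial the mu/beta amplitude at the class-appropriate
#' source(s) is attenuated by the profile's `erd_depth` for that class,
#' ramped in with a 250 ms raised cosine (the ERD is established within the
#' cue interval, before feedback starts).
#'
#' @param profile a [user_profile()]
#' @param mi_class one of the configured class labels
#' @param config a [session_config()]
#' @param seed integer seed for this trial
#' @return an [eeg_recording()] with a cue marker labelled `mi_class`
#' @export
simulate_trial <- function(profile, mi_class, config = session_config(),
                           seed = 1L) {
  if (!mi_class %in% config$classes)
    stop_invalid("unknown motor-imagery class '%s'", mi_class)
  fs <- config$fs
  n <- round((config$cross_s + config$cue_to_feedback_s + config$feedback_s) * fs)
  cue_at <- round(config$cross_s * fs)          # samples before cue onset

  depth <- profile$erd_depth[[mi_class]]
  topo <- erd_topography(mi_class)
  ramp_n <- round(0.25 * fs)
  ramp <- c(rep(0, cue_at),
            0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n)),
            rep(1, n - cue_at - ramp_n))
  gates <- lapply(c(C3 = "C3", C4 = "C4", Cz = "Cz"), function(src) {
    1 - depth * topo[[src]] * ramp
  })
  data <- synthesize_eeg(profile, n, fs, gates, seed = seed)
  markers <- data.frame(sample = cue_at + 1L, label = mi_class,
                        stringsAsFactors = FALSE)
  eeg_recording(data, default_montage()$channel, fs, markers)
}
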