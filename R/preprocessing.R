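# Temporal filtering, resampling, Laplacian derivation, epoching and
# log band-power features: the signal path feeding every classifier.

#' Frequency band specification
#'
#' @param low,high band edges in Hz, `0 < low < high`
#' @param name band label (`"alpha"`, `"beta"` or `"subject_specific"`)
#' @return object of class `band_spec`
#' @export
band_spec <- function(low, high, name = "subject_specific") {
  if (low <= 0 || low >= high)
    stop_invalid("band must satisfy 0 < low < high (got %g, %g)", low, high)
  structure(list(low = low, high = high, name = name), class = "band_spec")
}

#' Band-pass Butterworth filter
#'
#' Order-10 Butterworth band-pass (5 poles per edge), the filter used on the
#' alpha (8-15 Hz) and beta (16-32 Hz) bands. `zero_phase = TRUE` applies
#' forward-backward filtering for offline analyses; online simulation uses
#' the causal single pass.
#'
#' @param x numeric vector or channels x samples matrix
#' @param band a [band_spec()]
#' @param fs sampling rate (Hz)
#' @param order total filter order (even; default 10)
#' @param zero_phase logical; forward-backward filtering if `TRUE`
#' @return filtered signal, same shape as `x`
#' @export
bandpass_butterworth <- function(x, band, fs, order = 10, zero_phase = FALSE) {
  if (band$high >= fs / 2)
    stop_invalid("band upper edge %g Hz is not below Nyquist (%g Hz)",
                 band$high, fs / 2)
  flt <- butter_design(order / 2, band$low, band$high, fs)
  apply_filter(x, flt, zero_phase)
}

apply_filter <- function(x, flt, zero_phase) {
  if (zero_phase) return(fft_zero_phase(x, flt))
  if (is.matrix(x)) {
    # row-vectorized state update pays off only for large batches
    out <- if (nrow(x) >= 64) causal_filter_rows(flt, x)
           else t(apply(x, 1, function(v) as.numeric(signal::filter(flt, v))))
    dimnames(out) <- dimnames(x)
    out
  } else as.numeric(signal::filter(flt, x))
}

# Direct-form-II-transposed IIR filtering, vectorized across rows: the
# state update runs once per time step for all signals simultaneously.
causal_filter_rows <- function(flt, X) {
  b <- as.numeric(flt$b); a <- as.numeric(flt$a)
  b <- b / a[1]; a <- a / a[1]
  ns <- max(length(a), length(b)) - 1L
  b <- c(b, rep(0, ns + 1L - length(b)))
  a <- c(a, rep(0, ns + 1L - length(a)))
  R <- nrow(X); n <- ncol(X)
  Z <- matrix(0, R, ns)
  Y <- matrix(0, R, n)
  for (t in seq_len(n)) {
    xt <- X[, t]
    y <- b[1] * xt + Z[, 1]
    if (ns > 1)
      for (i in seq_len(ns - 1L))
        Z[, i] <- b[i + 1L] * xt + Z[, i + 1L] - a[i + 1L] * y
    Z[, ns] <- b[ns + 1L] * xt - a[ns + 1L] * y
    Y[, t] <- y
  }
  Y
}

# Zero-phase IIR filtering in the frequency domain: multiply the spectrum
# by the squared magnitude response |H|^2 (the forward-backward response),
# vectorized across channels with one FFT pair. Signals are zero-padded to
# absorb the wrap-around transient. Magnitude responses are memoized per
# (filter, FFT length).
.response_cache <- new.env(parent = emptyenv())

squared_response <- function(flt, np) {
  b <- as.numeric(flt$b); a <- as.numeric(flt$a)
  key <- paste(np, paste(signif(c(b, 0.5, a), 12), collapse = ","))
  G <- .response_cache[[key]]
  if (is.null(G)) {
    w <- 2 * pi * (0:(np - 1)) / np
    E <- exp(-1i * outer(w, 0:(max(length(a), length(b)) - 1)))
    H <- (E[, seq_along(b), drop = FALSE] %*% b) /
         (E[, seq_along(a), drop = FALSE] %*% a)
    G <- as.numeric(Mod(H)^2)
    .response_cache[[key]] <- G
  }
  G
}

fft_zero_phase <- function(x, flt) {
  vec_in <- !is.matrix(x)
  X <- if (vec_in) matrix(x, nrow = 1) else x
  n <- ncol(X)
  np <- stats::nextn(n + 256L, 2)
  G <- squared_response(flt, np)
  Xp <- rbind(t(X), matrix(0, np - n, nrow(X)))      # np x channels
  Y <- stats::mvfft(Xp) * G
  out <- t(Re(stats::mvfft(Y, inverse = TRUE))[seq_len(n), , drop = FALSE] / np)
  dimnames(out) <- dimnames(X)
  if (vec_in) as.numeric(out) else out
}

# Memoized Butterworth band-pass design (the online path designs the same
# filter for every trial).
.design_cache <- new.env(parent = emptyenv())

butter_design <- function(order_half, low, high, fs) {
  key <- paste(order_half, low, high, fs, sep = "|")
  flt <- .design_cache[[key]]
  if (is.null(flt)) {
    flt <- signal::butter(order_half, c(low, high) / (fs / 2), type = "pass")
    .design_cache[[key]] <- flt
  }
  flt
}

#' Low-pass filter and downsample to 100 Hz
#'
#' Chebyshev type-I low-pass of order 10 with 3 dB passband ripple and
#' passband edge 40 Hz, followed by decimation to 100 Hz. The stopband
#' attenuation at and above 50 Hz exceeds 40 dB by a wide margin.
#'
#' @param x numeric vector or channels x samples matrix
#' @param fs input sampling rate; must be a multiple of 100
#' @param zero_phase forward-backward filtering (offline default)
#' @return list with `data` (filtered, decimated) and `fs` (100)
#' @export
lowpass_downsample <- function(x, fs, zero_phase = TRUE) {
  if (fs < 100) stop_invalid("input rate %g Hz is below the 100 Hz target", fs)
  if (fs == 100) return(list(data = x, fs = 100))
  q <- fs / 100
  if (abs(q - round(q)) > 1e-9)
    stop_invalid("input rate %g Hz is not an integer multiple of 100 Hz", fs)
  flt <- signal::cheby1(10, 3, 40 / (fs / 2), type = "low")
  y <- apply_filter(x, flt, zero_phase)
  idx <- seq(1, if (is.matrix(y)) ncol(y) else length(y), by = round(q))
  list(data = if (is.matrix(y)) y[, idx, drop = FALSE] else y[idx], fs = 100)
}

#' Small Laplacian derivation
#'
#' Virtual channel formed by subtracting the equally weighted mean of four
#' surrounding channels from the centre channel, sharpening the spatial
#' focus over the underlying cortex.
#'
#' @param recording an [eeg_recording()] (or channels x samples matrix with
#'   rownames)
#' @param center centre channel name
#' @param neighbours character vector of 4 neighbour channel names
#' @return numeric vector, one sample per time point
#' @export
#' @examples
#' rec <- simulate_resting_state(user_profile(seed = 1), session_config())
#' lap <- laplacian_derive(rec, "C3", laplacian_neighbours()$C3)
laplacian_derive <- function(recording, center, neighbours) {
  data <- if (inherits(recording, "eeg_recording")) recording$data else recording
  missing <- setdiff(c(center, neighbours), rownames(data))
  if (length(missing) > 0)
    stop_invalid("channel(s) not in recording: %s",
                 paste(missing, collapse = ", "))
  data[center, ] - colMeans(data[neighbours, , drop = FALSE])
}

#' Segment a recording into cue-locked epochs
#'
#' Cuts a window around every cue marker. Markers whose window would extend
#' beyond the recording are dropped with a warning reporting the count.
#'
#' @param recording an [eeg_recording()]
#' @param markers data.frame (`sample`, `label`); defaults to the recording's
#'   own markers
#' @param window `(start_s, end_s)` relative to the marker, start < end
#' @return object of class `epochs`: list with `data`
#'   (trials x channels x samples array), `labels`, `window`, `fs`
#' @export
epoch_trials <- function(recording, markers = recording$markers,
                         window = c(-0.5, 4)) {
  if (window[1] >= window[2]) stop_invalid("window start must precede end")
  fs <- recording$fs
  n <- ncol(recording$data)
  off0 <- round(window[1] * fs)
  off1 <- round(window[2] * fs) - 1L
  keep <- markers$sample + off0 >= 1 & markers$sample + off1 <= n
  if (any(!keep))
    warning(sprintf("%d trial(s) dropped: window outside recording", sum(!keep)))
  m <- markers[keep, , drop = FALSE]
  n_trials <- nrow(m)
  n_samp <- off1 - off0 + 1L
  data <- array(0, dim = c(n_trials, nrow(recording$data), n_samp),
                dimnames = list(NULL, rownames(recording$data), NULL))
  for (i in seq_len(n_trials)) {
    idx <- (m$sample[i] + off0):(m$sample[i] + off1)
    data[i, , ] <- recording$data[, idx]
  }
  structure(list(data = data, labels = m$label, window = window, fs = fs),
            class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  cat(sprintf("<epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  invisible(x)
}

#' Log band-power features
#'
#' For every trial: band-pass filter, apply the spatial filters, and take
#' the log variance over the analysis interval — one feature per spatial
#' filter. Variances below the floor `eps` are clamped before the log and
#' flagged via the `"clamped"` attribute.
#'
#' @param epochs an [epoch_trials()] result
#' @param spatial_filters channels x filters weight matrix (a Laplacian is a
#'   single signed column; CSP supplies several)
#' @param band a [band_spec()]
#' @param interval `(start_s, end_s)` relative to the cue, inside the epoch
#'   window
#' @param zero_phase forward-backward filtering (offline default)
#' @param eps variance floor before the log
#' @return trials x filters matrix of log band-power values
#' @export
logvar_features <- function(epochs, spatial_filters, band,
                            interval = c(0.5, 4), zero_phase = TRUE,
                            eps = 1e-12) {
  if (interval[1] < epochs$window[1] || interval[2] > epochs$window[2])
    stop_invalid("interval must lie inside the epoch window")
  spatial_filters <- as.matrix(spatial_filters)
  fs <- epochs$fs
  i0 <- round((interval[1] - epochs$window[1]) * fs) + 1L
  i1 <- round((interval[2] - epochs$window[1]) * fs)
  n_trials <- dim(epochs$data)[1]
  k <- ncol(spatial_filters)
  ns <- dim(epochs$data)[3]
  # batch all (trial, filter) signals into one matrix for filtering
  A <- matrix(aperm(epochs$data, c(2, 3, 1)), dim(epochs$data)[2])
  V <- crossprod(spatial_filters, A)              # k x (ns * trials)
  B <- matrix(aperm(array(V, c(k, ns, n_trials)), c(1, 3, 2)),
              k * n_trials, ns)
  filt <- bandpass_butterworth(B, band, fs, zero_phase = zero_phase)
  seg <- filt[, i0:i1, drop = FALSE]
  m <- ncol(seg)
  v <- (rowSums(seg^2) - rowSums(seg)^2 / m) / (m - 1)
  out <- matrix(log(pmax(v, eps)), n_trials, k, byrow = TRUE)
  colnames(out) <- colnames(spatial_filters)
  attr(out, "clamped") <- any(v < eps)
  out
}
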