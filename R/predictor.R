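# Resting-state neurophysiological predictor of BCI performance: smoothed
# PSD at Laplacian C3/C4, 1/f noise-floor fit, peak-deviation score,
# regression against accuracy, and Mahalanobis outlier rejection.

psd_grid <- function() seq(2, 34, by = 0.5)

#' Extract eyes-open 2 s epochs from a resting recording
#'
#' Concatenates the eyes-open intervals and divides each into consecutive
#' non-overlapping epochs; epochs never span a segment boundary and partial
#' tails are dropped. The standard 10 x 15 s protocol yields 70 epochs.
#'
#' @param resting an [eeg_recording()] with `eyes_open` / `eyes_closed`
#'   markers
#' @param epoch_s epoch length in seconds
#' @return a label-free `epochs` object
#' @export
extract_open_epochs <- function(resting, epoch_s = 2) {
  mk <- resting$markers
  if (!any(mk$label == "eyes_open"))
    stop_invalid("recording has no eyes-open segments")
  n <- ncol(resting$data)
  fs <- resting$fs
  ord <- order(mk$sample)
  mk <- mk[ord, , drop = FALSE]
  starts <- mk$sample[mk$label == "eyes_open"]
  ends <- vapply(starts, function(s) {
    nxt <- mk$sample[mk$sample > s]
    if (length(nxt) == 0) n else min(nxt) - 1L
  }, numeric(1))
  len <- round(epoch_s * fs)
  pieces <- list()
  for (i in seq_along(starts)) {
    n_ep <- (ends[i] - starts[i] + 1L) %/% len
    for (j in seq_len(n_ep)) {
      a <- starts[i] + (j - 1L) * len
      pieces[[length(pieces) + 1L]] <- resting$data[, a:(a + len - 1L)]
    }
  }
  data <- array(0, dim = c(length(pieces), nrow(resting$data), len),
                dimnames = list(NULL, rownames(resting$data), NULL))
  for (i in seq_along(pieces)) data[i, , ] <- pieces[[i]]
  structure(list(data = data, labels = rep(NA_character_, length(pieces)),
                 window = c(0, epoch_s), fs = fs),
            class = "epochs")
}

#' Smoothed power spectral density on the standard grid
#'
#' Per-epoch periodogram of the spatially derived signal, interpolated to
#' the 2-34 Hz grid (0.5 Hz step), averaged over epochs, converted to dB
#' and smoothed with a 3 Hz (7-bin) centred moving average whose window
#' shrinks at the grid edges.
#'
#' @param epochs an `epochs` object (e.g. from [extract_open_epochs()])
#' @param derivation numeric channel-weight vector (e.g. a Laplacian
#'   column), named or ordered as the epoch channels
#' @param name derivation label (`"lap_C3"` / `"lap_C4"`)
#' @return object of class `spectrum_grid`: `freqs` (65 values), `psd`
#'   (dB), `derivation`
#' @export
smoothed_psd <- function(epochs, derivation, name = "lap") {
  n_ep <- dim(epochs$data)[1]
  if (n_ep < 1) stop_invalid("need at least one epoch")
  fs <- epochs$fs
  len <- dim(epochs$data)[3]
  grid <- psd_grid()
  freqs <- (0:(len - 1)) * fs / len
  half <- freqs <= fs / 2
  acc <- numeric(sum(half))
  for (i in seq_len(n_ep)) {
    x <- as.numeric(derivation %*% epochs$data[i, , ])
    x <- x - mean(x)
    P <- abs(stats::fft(x))^2 / (len * fs)       # two-sided periodogram
    acc <- acc + P[half]
  }
  acc <- acc / n_ep
  psd_lin <- stats::approx(freqs[half], acc, xout = grid, rule = 2)$y
  psd_smooth <- moving_average(psd_lin, 7L)      # 3 Hz window, linear power
  structure(list(freqs = grid,
                 psd = 10 * log10(pmax(psd_smooth, 1e-300)),
                 derivation = name),
            class = "spectrum_grid")
}

#' Fit the 1/f noise floor of a spectrum
#'
#' Least-squares fit of `g(f) = lambda + k * f^(-gamma)` (dB domain) over
#' the grid bins outside the declared peak-exclusion windows (7-14 Hz
#' around the mu peak and 18-26 Hz around its beta harmonic), with
#' `k >= 0` and `gamma` searched on a grid so the fit is monotone
#' non-increasing. A degenerate fit (best `k < 0`) falls back to a
#' monotone linear-in-log-f fit and is flagged.
#'
#' @param spectrum a [smoothed_psd()] result
#' @param exclude list of `(low, high)` Hz windows excluded from the fit
#' @return list: `values` (fit on the full grid, dB), `lambda`, `k`,
#'   `gamma`, `flagged`
#' @export
fit_noise_floor <- function(spectrum,
                            exclude = list(c(7, 14), c(18, 26))) {
  f <- spectrum$freqs
  y <- spectrum$psd
  if (!all(is.finite(y))) stop_invalid("spectrum must be finite")
  keep <- rep(TRUE, length(f))
  for (w in exclude) keep <- keep & !(f >= w[1] & f <= w[2])
  best <- NULL
  for (g in seq(0.2, 3, by = 0.05)) {
    basis <- f[keep]^(-g)
    fit <- stats::lm.fit(cbind(1, basis), y[keep])
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(lambda = fit$coefficients[1], k = fit$coefficients[2],
                   gamma = g, rss = rss)
  }
  flagged <- FALSE
  if (best$k < 0) {
    # rising spectrum: monotone fallback, linear in log f with slope <= 0
    lf <- log(f[keep])
    fit <- stats::lm.fit(cbind(1, lf), y[keep])
    slope <- min(0, fit$coefficients[2])
    values <- fit$coefficients[1] + slope * log(f)
    return(list(values = values, lambda = fit$coefficients[1], k = slope,
                gamma = NA_real_, flagged = TRUE))
  }
  values <- as.numeric(best$lambda + best$k * f^(-best$gamma))
  list(values = values, lambda = unname(best$lambda), k = unname(best$k),
       gamma = best$gamma, flagged = flagged)
}

#' Peak-deviation predictor from two derivations
#'
#' Per derivation: the maximum elevation of the smoothed PSD above the
#' fitted 1/f floor, floored at 0 dB; the predictor is the mean of the two
#' values — an estimate of the strength of the resting sensorimotor
#' rhythm.
#'
#' @param spec_c3,spec_c4 [smoothed_psd()] results on the standard grid
#' @return scalar predictor (dB)
#' @export
predictor_value <- function(spec_c3, spec_c4) {
  dev1 <- peak_deviation(spec_c3)
  dev2 <- peak_deviation(spec_c4)
  (dev1 + dev2) / 2
}

peak_deviation <- function(spectrum) {
  floor_fit <- fit_noise_floor(spectrum)
  max(0, max(spectrum$psd - floor_fit$values))
}

#' Full resting-state predictor for one recording
#'
#' Convenience wrapper: extracts eyes-open epochs, computes the smoothed
#' PSD at the two motor Laplacian derivations (built from the nine declared
#' monopolar channels), fits the noise floors and returns the averaged
#' peak-deviation predictor with all intermediates.
#'
#' @param resting an [eeg_recording()] of the resting protocol
#' @param epoch_s epoch length (s)
#' @return object of class `predictor_result`: `spectra`, `floors`,
#'   `deviations`, `predictor` (dB)
#' @export
resting_predictor <- function(resting, epoch_s = 2) {
  epochs <- extract_open_epochs(resting, epoch_s)
  laps <- predictor_laplacians()
  spectra <- list(); floors <- list(); devs <- numeric(0)
  for (nm in names(laps)) {
    w <- numeric(nrow(resting$data))
    names(w) <- rownames(resting$data)
    w[laps[[nm]]$center] <- 1
    w[laps[[nm]]$neighbours] <- -0.25
    sp <- smoothed_psd(epochs, w, name = nm)
    fl <- fit_noise_floor(sp)
    spectra[[nm]] <- sp
    floors[[nm]] <- fl
    devs[nm] <- max(0, max(sp$psd - fl$values))
  }
  structure(list(spectra = spectra, floors = floors, deviations = devs,
                 predictor = mean(devs)),
            class = "predictor_result")
}

#' @export
print.predictor_result <- function(x, ...) {
  cat(sprintf("<predictor_result> dev C3 = %.2f dB, dev C4 = %.2f dB, predictor = %.2f dB\n",
              x$deviations[1], x$deviations[2], x$predictor))
  invisible(x)
}

#' Linear prediction model: accuracy vs predictor
#'
#' Ordinary least squares of feedback accuracy (%) on the resting-state
#' predictor (dB), with the Pearson correlation and its two-sided p-value.
#'
#' @param predictors per-user predictor values
#' @param accuracies per-user feedback accuracies (%)
#' @return list: `slope`, `intercept`, `pearson_r`, `p_value`, `n`
#' @export
fit_prediction_model <- function(predictors, accuracies) {
  if (length(predictors) != length(accuracies) || length(predictors) < 3)
    stop_invalid("need >= 3 paired observations")
  if (stats::sd(predictors) == 0)
    stop_invalid("predictor values have zero variance")
  fit <- stats::lm(accuracies ~ predictors)
  ct <- stats::cor.test(predictors, accuracies)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       pearson_r = unname(ct$estimate),
       p_value = ct$p.value,
       n = length(predictors))
}

#' Mahalanobis outlier mask
#'
#' Marks the `ceil(fraction * n)` points with the largest Mahalanobis
#' distance to the sample mean under the sample covariance.
#'
#' @param points n x 2 matrix (predictor, accuracy)
#' @param fraction outlier fraction (default 0.10)
#' @return logical mask, `TRUE` = outlier
#' @export
mahalanobis_outliers <- function(points, fraction = 0.10) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 5) stop_invalid("need at least 5 points")
  S <- stats::cov(points)
  if (abs(det(S)) < 1e-300) stop_invalid("singular covariance")
  d2 <- stats::mahalanobis(points, colMeans(points), S)
  k <- ceiling(fraction * n)
  mask <- rep(FALSE, n)
  mask[order(-d2)[seq_len(k)]] <- TRUE
  mask
}

#' Apply a prediction model to new predictor values
#'
#' @param model a [fit_prediction_model()] result (needs `slope`,
#'   `intercept`)
#' @param predictors new predictor values
#' @return estimated accuracies (%)
#' @export
transfer_predict <- function(model, predictors) {
  if (!is.finite(model$slope) || !is.finite(model$intercept))
    stop_invalid("model coefficients must be finite")
  model$slope * predictors + model$intercept
}
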