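# The study-level statistical surface: binomial chance thresholds, ERD/ERS
# time courses, cohort accuracy summaries and user categorization.

#' Binomial chance threshold for classification accuracy
#'
#' The minimal success count `k_min` such that the binomial CDF
#' `F(k_min; n, p0)` reaches the confidence level — accuracies at or above
#' `k_min / n` are considered significantly better than chance. For the
#' 320 feedback trials of the standard protocol this gives 175 successes,
#' i.e. 54.69%.
#'
#' @param n_trials number of trials (>= 1)
#' @param p0 null success probability
#' @param confidence confidence level
#' @return object of class `chance_threshold`: `n_trials`, `p0`,
#'   `confidence`, `k_min`, `accuracy_pct`
#' @export
#' @examples
#' chance_threshold(320)$accuracy_pct   # 54.69
chance_threshold <- function(n_trials, p0 = 0.5, confidence = 0.95) {
  if (n_trials < 1 || p0 <= 0 || p0 >= 1)
    stop_invalid("need n_trials >= 1 and 0 < p0 < 1")
  k_min <- stats::qbinom(confidence, n_trials, p0)
  structure(list(n_trials = n_trials, p0 = p0, confidence = confidence,
                 k_min = as.integer(k_min),
                 accuracy_pct = round(100 * k_min / n_trials, 2),
                 accuracy_exact = 100 * k_min / n_trials),
            class = "chance_threshold")
}

#' @export
print.chance_threshold <- function(x, ...) {
  cat(sprintf("<chance_threshold> %d/%d successes = %.2f%% (p0 = %g, conf = %g)\n",
              x$k_min, x$n_trials, x$accuracy_pct, x$p0, x$confidence))
  invisible(x)
}

#' ERD/ERS time course
#'
#' Percent band-power change relative to a reference interval: band-pass
#' filter (zero phase), squared-amplitude envelope smoothed with a 200 ms
#' moving average, averaged over the trials of each class, then expressed
#' as `100 * (P(t) - P_ref) / P_ref`. Negative values indicate
#' desynchronization.
#'
#' @param epochs an `epochs` object with class labels
#' @param band a [band_spec()]
#' @param reference `(start_s, end_s)` reference interval relative to the
#'   cue (inside the epoch window)
#' @param channels channel names to analyse (default: all epoch channels)
#' @return data.frame with columns `time_ms`, `channel`, `class`, `erd`
#' @export
erd_time_course <- function(epochs, band, reference = c(-0.5, 0),
                            channels = dimnames(epochs$data)[[2]]) {
  if (reference[1] < epochs$window[1] || reference[2] > epochs$window[2])
    stop_invalid("reference interval must lie inside the epoch window")
  fs <- epochs$fs
  n_samp <- dim(epochs$data)[3]
  ch_idx <- match(channels, dimnames(epochs$data)[[2]])
  if (anyNA(ch_idx)) stop_invalid("unknown channel in 'channels'")
  r0 <- round((reference[1] - epochs$window[1]) * fs) + 1L
  r1 <- round((reference[2] - epochs$window[1]) * fs)
  ma_w <- max(3L, 2L * round(0.1 * fs) + 1L)    # ~200 ms smoothing
  classes <- unique(epochs$labels)
  times <- (seq_len(n_samp) - 1) / fs * 1000 + epochs$window[1] * 1000
  out <- list()
  for (cl in classes) {
    tr <- which(epochs$labels == cl)
    env <- matrix(0, length(ch_idx), n_samp)
    for (i in tr) {
      x <- epochs$data[i, ch_idx, , drop = TRUE]
      if (!is.matrix(x)) x <- matrix(x, nrow = 1)
      xf <- bandpass_butterworth(x, band, fs, zero_phase = TRUE)
      env <- env + t(apply(xf^2, 1, moving_average, k = ma_w))
    }
    env <- env / length(tr)
    for (ci in seq_along(ch_idx)) {
      p_ref <- mean(env[ci, r0:r1])
      if (p_ref <= 0) stop_invalid("zero reference power")
      out[[length(out) + 1L]] <- data.frame(
        time_ms = times, channel = channels[ci], class = cl,
        erd = 100 * (env[ci, ] - p_ref) / p_ref, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Cohort accuracy summary
#'
#' Per-user and per-run feedback accuracies over the real-feedback runs,
#' with flags against the binomial chance threshold and the 70% efficiency
#' threshold, plus cohort counts per category.
#'
#' @param results list of [run_session()] results
#' @param threshold_control efficiency threshold (%)
#' @return list: `users` (data.frame), `counts` (named vector)
#' @export
accuracy_summary <- function(results, threshold_control = 70) {
  if (length(results) < 1) stop_invalid("need at least one session")
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    fb <- r$trials[r$trials$phase == "real", , drop = FALSE]
    if (nrow(fb) == 0) stop_invalid("session %d has no real-feedback trials", i)
    thr <- chance_threshold(nrow(fb))
    acc <- 100 * mean(fb$success)
    data.frame(user = i,
               n_feedback = nrow(fb),
               accuracy = acc,
               above_chance = acc >= thr$accuracy_exact,
               efficient = acc >= threshold_control)
  })
  users <- do.call(rbind, rows)
  users$category <- ifelse(users$efficient, "efficient",
                           ifelse(users$above_chance, "above_chance",
                                  "at_chance"))
  counts <- c(efficient = sum(users$category == "efficient"),
              above_chance = sum(users$category == "above_chance"),
              at_chance = sum(users$category == "at_chance"))
  list(users = users, counts = counts)
}

#' Categorize one simulated user
#'
#' `"efficient"` if the mean real-feedback accuracy reaches the control
#' threshold (70%), `"above_chance"` if it reaches the binomial chance
#' threshold for the user's feedback-trial count, else `"at_chance"`.
#'
#' @param result a [run_session()] result
#' @param threshold_control efficiency threshold (%)
#' @return character scalar
#' @export
categorize_user <- function(result, threshold_control = 70) {
  fb <- result$trials[result$trials$phase == "real", , drop = FALSE]
  if (nrow(fb) == 0) stop_invalid("session has no real-feedback trials")
  acc <- 100 * mean(fb$success)
  thr <- chance_threshold(nrow(fb))
  if (acc >= threshold_control) "efficient"
  else if (acc >= thr$accuracy_exact) "above_chance"
  else "at_chance"
}
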