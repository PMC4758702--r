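# Resting-state spectral predictor: epoch extraction, smoothed PSD, 1/f
# floor fit, peak deviation, regression and outlier rejection.

grid_spectrum <- function(psd, name = "lap_C3") {
  structure(list(freqs = seq(2, 34, 0.5), psd = psd, derivation = name),
            class = "spectrum_grid")
}

test_that("the standard resting protocol yields 70 eyes-open epochs", {
  rec <- simulate_resting_state(user_profile(seed = 6), session_config())
  ep <- extract_open_epochs(rec)
  expect_equal(dim(ep$data)[1], 70)            # 10 segments x 7 epochs
  expect_equal(dim(ep$data)[3], 200)           # 2 s at 100 Hz
  closed_only <- rec
  closed_only$markers <- rec$markers[rec$markers$label == "eyes_closed", ]
  expect_error(extract_open_epochs(closed_only), "eyes-open")
})

test_that("smoothed PSD is flat for white noise and peaked for a sinusoid", {
  set.seed(30)
  mk_ep <- function(gen) {
    data <- array(0, dim = c(100, 1, 200), dimnames = list(NULL, "X", NULL))
    for (i in 1:100) data[i, 1, ] <- gen()
    structure(list(data = data, labels = rep(NA, 100), window = c(0, 2),
                   fs = 100), class = "epochs")
  }
  sp_white <- smoothed_psd(mk_ep(function() rnorm(200)), c(X = 1))
  expect_equal(length(sp_white$freqs), 65)
  mid <- sp_white$freqs >= 5 & sp_white$freqs <= 30
  expect_lte(diff(range(sp_white$psd[mid])), 3)
  # narrow-band oscillation (per-epoch frequency jitter, as in real mu)
  tone <- function(a = 1) {
    f <- 10 + stats::runif(1, -0.7, 0.7)
    a * sin(2 * pi * f * (1:200) / 100) + 0.05 * rnorm(200)
  }
  set.seed(33)
  sp_tone <- smoothed_psd(mk_ep(function() tone(1)), c(X = 1))
  expect_lte(abs(sp_tone$freqs[which.max(sp_tone$psd)] - 10), 0.5)
  set.seed(33)
  sp_tone2 <- smoothed_psd(mk_ep(function() tone(2)), c(X = 1))
  expect_lt(abs(max(sp_tone2$psd) - max(sp_tone$psd) - 6.02), 0.5)
})

test_that("noise-floor fit reproduces an exact 1/f spectrum", {
  f <- seq(2, 34, 0.5)
  sp <- grid_spectrum(3 + 20 * f^(-1))
  fit <- fit_noise_floor(sp)
  expect_lt(max(abs(fit$values - sp$psd)), 0.1)
  expect_false(fit$flagged)
  # flat spectrum: k collapses to ~0
  fit_flat <- fit_noise_floor(grid_spectrum(rep(5, 65)))
  expect_lt(abs(fit_flat$k), 0.05)
  # fit passes under an alpha peak thanks to the exclusion window
  peaked <- 3 + 20 * f^(-1) + 10 * exp(-(f - 10)^2 / 2)
  fit_p <- fit_noise_floor(grid_spectrum(peaked))
  expect_lt(fit_p$values[f == 10], peaked[f == 10])
  # monotone non-increasing over the grid
  expect_true(all(diff(fit_p$values) <= 1e-9))
})

test_that("predictor is the mean floored peak deviation of two spectra", {
  f <- seq(2, 34, 0.5)
  floor_only <- 3 + 20 * f^(-1)
  peaked <- floor_only + 8 * exp(-(f - 10)^2 / (2 * 1.5^2))
  expect_lt(predictor_value(grid_spectrum(floor_only),
                            grid_spectrum(floor_only, "lap_C4")), 0.5)
  both <- predictor_value(grid_spectrum(peaked),
                          grid_spectrum(peaked, "lap_C4"))
  expect_gt(both, 7); expect_lt(both, 9)
  one_side <- predictor_value(grid_spectrum(peaked),
                              grid_spectrum(floor_only, "lap_C4"))
  expect_lt(abs(one_side - both / 2), 0.5)
})

test_that("predictor grows with the injected mu amplitude", {
  cfg <- session_config()
  preds <- vapply(c(0, 1.5, 3), function(a) {
    p <- user_profile(smr_amplitude_c3 = a, smr_amplitude_c4 = a, seed = 50)
    resting_predictor(simulate_resting_state(p, cfg))$predictor
  }, numeric(1))
  expect_true(all(diff(preds) > 0))
  expect_lt(preds[1], 1)                       # no-signal case: ~0 dB
})

test_that("prediction model recovers a perfect linear relation", {
  x <- 1:10
  y <- 3 * x + 7
  m <- fit_prediction_model(x, y)
  expect_equal(m$slope, 3, tolerance = 1e-10)
  expect_equal(m$intercept, 7, tolerance = 1e-10)
  expect_equal(m$pearson_r, 1, tolerance = 1e-10)
  expect_error(fit_prediction_model(rep(1, 5), rnorm(5)), "variance")
  # permutation null: shuffled pairings decorrelate
  set.seed(31)
  xs <- rnorm(148); ys <- rnorm(148)
  rs <- vapply(1:200, function(i) abs(stats::cor(sample(xs), ys)), numeric(1))
  expect_lt(mean(rs), 0.1)
})

test_that("Mahalanobis outlier count follows the ceil rule", {
  set.seed(32)
  pts <- cbind(rnorm(148), rnorm(148))
  mask <- mahalanobis_outliers(pts, 0.10)
  expect_equal(sum(mask), 15)                  # ceil(14.8)
  # the sample-mean point is never flagged while others differ
  pts2 <- rbind(colMeans(pts), pts)
  pts2[1, ] <- colMeans(pts2[-1, ])
  mask2 <- mahalanobis_outliers(pts2, 0.10)
  expect_false(mask2[1])
  expect_error(mahalanobis_outliers(pts[1:3, ]), "5 points")
  # removing an injected gross outlier restores a perfect correlation
  line <- cbind(1:20, 2 * (1:20) + 1)
  spoiled <- rbind(line, c(2, 90))
  mask3 <- mahalanobis_outliers(spoiled, 0.05)
  expect_true(mask3[21])
  r_clean <- stats::cor(spoiled[!mask3, 1], spoiled[!mask3, 2])
  expect_equal(r_clean, 1, tolerance = 1e-12)
})

test_that("transfer_predict applies the linear model element-wise", {
  m <- list(slope = 1, intercept = 0)
  expect_equal(transfer_predict(m, c(1, 2, 3)), c(1, 2, 3))
  m2 <- list(slope = 2.5, intercept = -4)
  expect_equal(transfer_predict(m2, rep(2, 3)), rep(1, 3))
  expect_error(transfer_predict(list(slope = NA, intercept = 0), 1), "finite")
})
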