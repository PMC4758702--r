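# The synthetic EEG generator: spectral shape of the background, resting
# protocol structure, and the class-dependent ERD contract.

test_that("pink noise has a 1/f spectrum with slope near -1", {
  x <- pink_noise(1, 60, 100, 1, seed = 7)
  ps <- stats::spec.pgram(x[1, ], spans = 15, plot = FALSE, taper = 0)
  f <- ps$freq * 100
  keep <- f >= 2 & f <= 34
  slope <- unname(stats::coef(
    stats::lm(log10(ps$spec[keep]) ~ log10(f[keep])))[2])
  expect_gt(slope, -1.3)
  expect_lt(slope, -0.7)
})

test_that("pink noise is deterministic in the seed and zero at scale 0", {
  expect_identical(pink_noise(3, 2, 100, 1, seed = 5),
                   pink_noise(3, 2, 100, 1, seed = 5))
  expect_false(identical(pink_noise(3, 2, 100, 1, seed = 5),
                         pink_noise(3, 2, 100, 1, seed = 6)))
  expect_true(all(pink_noise(2, 1, 100, 0, seed = 1) == 0))
  expect_error(pink_noise(1, -1, 100, 1, 1), "positive")
  expect_error(pink_noise(1, 10, 0, 1, 1), "positive")
})

test_that("channels share weakly correlated background sources", {
  x <- pink_noise(8, 120, 100, 1, seed = 3)
  cors <- stats::cor(t(x))
  off <- cors[upper.tri(cors)]
  # shared sources induce nonzero average dependence, but far from unity
  expect_gt(mean(abs(off)), 0.01)
  expect_lt(max(abs(off)), 0.8)
})

test_that("resting-state protocol has 10 cycles with 20 state markers", {
  rec <- simulate_resting_state(user_profile(seed = 3), session_config())
  expect_s3_class(rec, "eeg_recording")
  expect_equal(ncol(rec$data), 300 * 100)         # 300 s at 100 Hz
  expect_equal(nrow(rec$markers), 20)
  expect_equal(rec$markers$label,
               rep(c("eyes_open", "eyes_closed"), 10))
  expect_true(all(diff(rec$markers$sample) == 15 * 100))
})

test_that("eyes-closed segments carry amplified occipital alpha", {
  p <- user_profile(eyes_closed_alpha_gain = 3, seed = 21)
  rec <- simulate_resting_state(p, session_config())
  alpha <- band_spec(8, 13, "alpha")
  oz <- bandpass_butterworth(rec$data["Oz", ], alpha, 100, zero_phase = TRUE)
  open_idx <- unlist(lapply(which(rec$markers$label == "eyes_open"), function(i)
    rec$markers$sample[i] + 100:1300))
  closed_idx <- unlist(lapply(which(rec$markers$label == "eyes_closed"),
                              function(i) rec$markers$sample[i] + 100:1300))
  expect_gt(stats::var(oz[closed_idx]) / stats::var(oz[open_idx]), 2)
})

test_that("trial segments span cross + cue + feedback and are deterministic", {
  cfg <- session_config()
  tr <- simulate_trial(user_profile(seed = 4), "left", cfg, seed = 9)
  expect_equal(ncol(tr$data), (2 + 1 + 3) * 100)
  expect_equal(tr$markers$label, "left")
  expect_equal(tr$markers$sample, 2 * 100 + 1)
  expect_identical(tr$data,
                   simulate_trial(user_profile(seed = 4), "left", cfg,
                                  seed = 9)$data)
  expect_error(simulate_trial(user_profile(), "tongue", cfg, 1), "unknown")
})

test_that("ERD attenuates contralateral band power by (1 - depth)^2", {
  cfg <- session_config()
  p <- user_profile(erd_depth = c(left = 0.5, right = 0.5, foot = 0.5),
                    noise_scale = 1e-9, beta_peak_hz = NULL, seed = 2)
  alpha <- band_spec(8, 15, "alpha")
  ratios <- vapply(1:20, function(i) {
    tr <- simulate_trial(p, "right", cfg, seed = 100 + i)
    lap <- laplacian_derive(tr, "C3", laplacian_neighbours()$C3)
    y <- bandpass_butterworth(lap, alpha, 100, zero_phase = TRUE)
    stats::var(y[331:600]) / stats::var(y[31:200])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.25), 0.08)
})

test_that("zero ERD depth leaves band power unmodulated", {
  cfg <- session_config()
  p <- user_profile(erd_depth = c(left = 0, right = 0, foot = 0),
                    noise_scale = 1e-9, beta_peak_hz = NULL, seed = 2)
  alpha <- band_spec(8, 15, "alpha")
  ratios <- vapply(1:20, function(i) {
    tr <- simulate_trial(p, "right", cfg, seed = 200 + i)
    lap <- laplacian_derive(tr, "C3", laplacian_neighbours()$C3)
    y <- bandpass_butterworth(lap, alpha, 100, zero_phase = TRUE)
    log(stats::var(y[331:600]) / stats::var(y[31:200]))
  }, numeric(1))
  expect_gt(stats::t.test(ratios)$p.value, 0.05)
})

test_that("ERD is contralateral: right-hand imagery hits C3 harder than C4", {
  cfg <- session_config()
  p <- user_profile(erd_depth = c(left = 0.6, right = 0.6, foot = 0.4),
                    noise_scale = 1e-9, beta_peak_hz = NULL, seed = 5)
  alpha <- band_spec(8, 15, "alpha")
  ratio_at <- function(center, tr) {
    lap <- laplacian_derive(tr, center, laplacian_neighbours()[[center]])
    y <- bandpass_butterworth(lap, alpha, 100, zero_phase = TRUE)
    stats::var(y[331:600]) / stats::var(y[31:200])
  }
  r <- vapply(1:10, function(i) {
    tr <- simulate_trial(p, "right", cfg, seed = 300 + i)
    c(ratio_at("C3", tr), ratio_at("C4", tr))
  }, numeric(2))
  expect_lt(mean(r[1, ]), mean(r[2, ]))
})
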