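# Shared fixtures, built in code: small profiles, a reduced session plan
# for structure tests, and a lazily trained set of prior classifiers.

strong_profile <- function(seed = 11L) {
  user_profile(erd_depth = c(left = 0.6, right = 0.6, foot = 0.4),
               seed = seed)
}

null_profile <- function(seed = 12L) {
  user_profile(erd_depth = c(left = 0, right = 0, foot = 0), seed = seed)
}

# Reduced run plan: same three phases and two retraining points, fewer
# trials, for fast structural tests.
quick_config <- function() {
  session_config(runs = c(12L, 12L, 12L, 16L, 16L, 16L, 16L))
}

.fixture_env <- new.env()

# One set of subject-independent priors shared across test files.
test_prior <- function() {
  if (is.null(.fixture_env$prior)) {
    cohort <- lapply(1:3, function(i)
      user_profile(erd_depth = c(left = 0.6, right = 0.6, foot = 0.4),
                   seed = 100L + i))
    .fixture_env$prior <- make_subject_independent_prior(
      cohort, session_config(), trials_per_class = 6L, seed = 77L)
  }
  .fixture_env$prior
}

# Minimal hand-built session result for the summary/categorization tests.
fake_session <- function(n_success, n_real = 320L, n_biased = 120L) {
  success <- c(rep(TRUE, n_biased),
               rep(c(TRUE, FALSE), times = c(n_success, n_real - n_success)))
  trials <- data.frame(
    run = c(rep(1:3, length.out = n_biased), rep(4:7, each = n_real / 4)),
    trial = seq_len(n_biased + n_real),
    phase = rep(c("biased", "real"), times = c(n_biased, n_real)),
    target = "left",
    final_position = ifelse(success, 0.5, -0.5),
    target_side = 1,
    success = success,
    stringsAsFactors = FALSE)
  structure(list(trials = trials,
                 run_accuracy = vapply(1:7, function(r)
                   100 * mean(trials$success[trials$run == r]), numeric(1)),
                 feedback_accuracy = 100 * n_success / n_real,
                 retraining = list(), seed = 0L),
            class = "session_result")
}
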