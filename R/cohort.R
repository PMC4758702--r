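# Cohort-level simulation: user populations whose SMR strength drives both
# the resting-state spectra and the closed-loop ERD, the regime in which a
# resting-state predictor of feedback accuracy can be recovered.

#' Draw a cohort of simulated user profiles
#'
#' SMR amplitude is drawn uniformly across the population and the ERD depth
#' is proportional to it (clipped to \[0, 0.9\]), so that users with a
#' stronger resting rhythm also modulate it more strongly during imagery —
#' the coupling underlying the predictor-accuracy correlation. Foot-imagery
#' modulation is weaker than hand imagery, and the mu peak frequency and
#' noise level vary mildly across users.
#'
#' @param n cohort size
#' @param seed integer seed
#' @param erd_per_amplitude ERD depth per unit SMR amplitude
#' @return list of [user_profile()] objects
#' @export
cohort_profiles <- function(n, seed = 1L, erd_per_amplitude = 0.25) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      amp <- stats::runif(1, 0.2, 3.2)
      lat <- stats::runif(2, 0.9, 1.1)          # mild lateral asymmetry
      erd_hand <- min(0.9, erd_per_amplitude * amp)
      user_profile(
        smr_amplitude_c3 = amp * lat[1],
        smr_amplitude_c4 = amp * lat[2],
        mu_peak_hz = stats::runif(1, 9, 12),
        beta_peak_hz = stats::runif(1, 19, 24),
        erd_depth = c(left = erd_hand, right = erd_hand,
                      foot = 0.6 * erd_hand),
        noise_scale = stats::runif(1, 0.85, 1.2),
        eyes_closed_alpha_gain = stats::runif(1, 1.5, 2.5),
        seed = child_seed(seed, 7000L + i)
      )
    })
  })
}

#' Simulate a full cohort: resting predictor and closed-loop accuracy
#'
#' For every profile, simulates the resting-state measurement and computes
#' the spectral predictor, then runs the full co-adaptive session and
#' records the real-feedback accuracy. One set of subject-independent
#' priors, trained on a separate cohort of strong users, is shared by all
#' sessions.
#'
#' @param profiles list of [user_profile()]s (e.g. [cohort_profiles()])
#' @param config a [session_config()]
#' @param seed integer seed
#' @param prior optional prior models; trained internally when `NULL`
#' @return list: `table` (data.frame with `user`, `predictor`, `accuracy`,
#'   `category`), `sessions` (list of [run_session()] results), `prior`
#' @export
run_cohort <- function(profiles, config = session_config(), seed = 1L,
                       prior = NULL) {
  if (is.null(prior)) {
    strong <- lapply(1:6, function(i)
      user_profile(erd_depth = c(left = 0.6, right = 0.6, foot = 0.4),
                   mu_peak_hz = 9.5 + 0.5 * i,
                   seed = child_seed(seed, 8000L + i)))
    prior <- make_subject_independent_prior(strong, config,
                                            seed = child_seed(seed, 99L))
  }
  rows <- list(); sessions <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    rest <- simulate_resting_state(p, config)
    pred <- resting_predictor(rest)
    res <- run_session(p, config, prior, seed = child_seed(seed, 300L + i))
    sessions[[i]] <- res
    rows[[i]] <- data.frame(
      user = i,
      smr_amplitude = (p$smr_amplitude_c3 + p$smr_amplitude_c4) / 2,
      erd_left = p$erd_depth$left,
      predictor = pred$predictor,
      accuracy = res$feedback_accuracy,
      category = categorize_user(res),
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), sessions = sessions, prior = prior)
}
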