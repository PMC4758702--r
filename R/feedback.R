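# Rate-control cursor feedback (biased and real modes), trial outcome
# scoring, and the seven-run co-adaptive session with its two retraining
# points.

#' Cursor state for one feedback trial
#'
#' Scalar cursor position in display half-width units. In biased mode the
#' target side is normalized to +1 and the position is confined to
#' \[0, 1\]: the cursor can only move toward the cued target or decay back
#' to the centre. In real mode the position moves freely in \[-1, +1\].
#'
#' @param target cued motor-imagery class
#' @param mode `"biased"` or `"real"`
#' @param target_side +1 or -1: display side of the target in real mode
#' @return object of class `cursor_state`
#' @export
cursor_state <- function(target, mode = c("real", "biased"),
                         target_side = 1) {
  mode <- match.arg(mode)
  structure(list(position = 0, target = target,
                 target_side = if (mode == "biased") 1 else target_side,
                 mode = mode, t_ms = 0),
            class = "cursor_state")
}

#' One positively biased cursor update
#'
#' The two binary classifiers whose pair contains the target are evaluated;
#' scores are oriented so positive favours the target. If at least one is
#' positive, the cursor moves toward the target proportionally to the
#' larger output; otherwise it decays slowly toward the centre. It never
#' moves toward a wrong class (position floor at 0).
#'
#' @param state a [cursor_state()] in biased mode
#' @param score_pair_1,score_pair_2 target-oriented classifier outputs
#' @param dt_ms update period (ms)
#' @param gain position gain per unit score per step
#' @param decay centre-decay per step when neither score favours the target
#' @return updated `cursor_state`
#' @export
biased_cursor_step <- function(state, score_pair_1, score_pair_2,
                               dt_ms = 40, gain = 1 / 75, decay = 0.02) {
  s <- max(score_pair_1, score_pair_2)
  state$position <- if (s > 0) min(1, state$position + gain * s)
                    else max(0, state$position - decay)
  state$t_ms <- state$t_ms + dt_ms
  state
}

#' One real (unbiased) cursor update
#'
#' Rate control: a fraction of the classifier output is added to the cursor
#' position every `dt_ms`, clipped at the display edges. The default gain
#' `1/75` lets a constant unit score reach the edge exactly at the end of
#' the 3 s feedback period (75 steps of 40 ms).
#'
#' @param state a [cursor_state()] in real mode
#' @param score signed classifier output (positive = +1 edge)
#' @param dt_ms update period (ms)
#' @param gain position gain per unit score per step
#' @return updated `cursor_state`
#' @export
real_cursor_step <- function(state, score, dt_ms = 40, gain = 1 / 75) {
  state$position <- min(1, max(-1, state$position + gain * score))
  state$t_ms <- state$t_ms + dt_ms
  state
}

#' Trial outcome from the final cursor position
#'
#' Success iff the final position lies strictly on the target side of the
#' centre; an exactly central cursor counts as failure (declared tie rule).
#'
#' @param state a [cursor_state()] after the feedback period
#' @return logical success flag
#' @export
trial_outcome <- function(state) {
  state$position * state$target_side > 0
}

#' Chance success rate of the positively biased feedback
#'
#' Simulates two independent fair random binary classifiers and returns the
#' fraction of steps in which at least one favours the target. The analytic
#' value is 1 - (1/2)^2 = 0.75: biased feedback makes even a random
#' classifier pair look 75% correct per step.
#'
#' @param n_sim number of simulated steps (>= 1000)
#' @param seed integer seed
#' @param n_classifiers number of independent classifiers (default 2)
#' @return estimated probability
#' @export
biased_chance_rate <- function(n_sim, seed = 1L, n_classifiers = 2L) {
  if (n_sim < 1000) stop_invalid("n_sim must be >= 1000")
  with_seed(seed, {
    hit <- rep(FALSE, n_sim)
    for (k in seq_len(n_classifiers)) {
      hit <- hit | (stats::runif(n_sim) > 0.5)
    }
    mean(hit)
  })
}

# ---- internal feature plumbing ------------------------------------------

# Causally band-filtered virtual channels: W is channels x k.
virtual_filtered <- function(data, W, band, fs) {
  V <- crossprod(W, data)                       # k x n
  flt <- butter_design(5, band$low, band$high, fs)
  out <- t(apply(V, 1, function(v) as.numeric(signal::filter(flt, v))))
  if (nrow(V) == 1) out <- matrix(out, 1)
  rownames(out) <- colnames(W)
  out
}

# Sliding log-variance over causal windows ending at each cursor step, plus
# the whole-feedback-interval log-variance used for per-trial adaptation.
step_trial_logvar <- function(F, fs, config, eps = 1e-12) {
  n <- ncol(F)
  step <- round(fs * config$cursor_update_ms / 1000)
  fb_start <- round((config$cross_s + config$cue_to_feedback_s) * fs)
  n_steps <- round(config$feedback_s * 1000 / config$cursor_update_ms)
  win <- round(config$online_window_s * fs)
  ends <- fb_start + step * seq_len(n_steps)
  k <- nrow(F)
  cs <- cbind(0, t(apply(F, 1, cumsum)))
  cs2 <- cbind(0, t(apply(F^2, 1, cumsum)))
  if (k == 1) { cs <- matrix(cs, 1); cs2 <- matrix(cs2, 1) }
  sx <- cs[, ends + 1L, drop = FALSE] - cs[, ends - win + 1L, drop = FALSE]
  sx2 <- cs2[, ends + 1L, drop = FALSE] - cs2[, ends - win + 1L, drop = FALSE]
  v <- (sx2 - sx^2 / win) / (win - 1)
  steps <- t(log(pmax(v, eps)))
  fb <- F[, (fb_start + 1L):n, drop = FALSE]
  m <- ncol(fb)
  v_tr <- (rowSums(fb^2) - rowSums(fb)^2 / m) / (m - 1)
  trial <- log(pmax(v_tr, eps))
  names(trial) <- rownames(F)
  list(steps = steps, trial = trial)
}

# Run 1-3 feature definition: Laplacian C3/Cz/C4, alpha + beta log
# band-power over the feedback interval (causal filtering, as online).
runs13_features <- function(rec, config) {
  W <- laplacian_filter_matrix(rec$channel_labels, c("C3", "Cz", "C4"))
  out <- numeric(0)
  for (band in list(band_spec(config$alpha_band[1], config$alpha_band[2], "alpha"),
                    band_spec(config$beta_band[1], config$beta_band[2], "beta"))) {
    F <- virtual_filtered(rec$data, W, band, config$fs)
    out <- c(out, step_trial_logvar(F, config$fs, config)$trial)
  }
  names(out) <- c(paste0(c("C3", "Cz", "C4"), "_alpha"),
                  paste0(c("C3", "Cz", "C4"), "_beta"))
  out
}

# Both step features and the trial feature for runs 1-3 (6-d).
runs13_online <- function(rec, config) {
  W <- laplacian_filter_matrix(rec$channel_labels, c("C3", "Cz", "C4"))
  steps <- NULL; trial <- numeric(0)
  for (band in list(band_spec(config$alpha_band[1], config$alpha_band[2], "alpha"),
                    band_spec(config$beta_band[1], config$beta_band[2], "beta"))) {
    F <- virtual_filtered(rec$data, W, band, config$fs)
    stl <- step_trial_logvar(F, config$fs, config)
    steps <- cbind(steps, stl$steps)
    trial <- c(trial, stl$trial)
  }
  list(steps = steps, trial = trial)
}

# Stack stored trial recordings into an epochs object (window relative to
# the cue: -cross_s .. cue_to_feedback_s + feedback_s).
build_epochs <- function(trial_recs, labels, config) {
  n <- length(trial_recs)
  d <- nrow(trial_recs[[1]]$data)
  m <- ncol(trial_recs[[1]]$data)
  data <- array(0, dim = c(n, d, m),
                dimnames = list(NULL, trial_recs[[1]]$channel_labels, NULL))
  for (i in seq_len(n)) data[i, , ] <- trial_recs[[i]]$data
  structure(list(data = data, labels = labels,
                 window = c(-config$cross_s,
                            config$cue_to_feedback_s + config$feedback_s),
                 fs = config$fs),
            class = "epochs")
}

# Balanced pseudo-random cue sequence for one run.
cue_sequence <- function(classes, n_trials, seed) {
  base <- rep(classes, length.out = n_trials)
  with_seed(seed, sample(base))
}

# Signed-r2 scores of every Laplacian candidate from history features.
laplacian_scores <- function(hist_lap, hist_label, pair, window = 100L) {
  n <- nrow(hist_lap)
  keep <- max(1L, n - window + 1L):n
  H <- hist_lap[keep, , drop = FALSE]
  lab <- hist_label[keep]
  sc <- vapply(seq_len(ncol(H)), function(j)
    as.numeric(signed_r2(H[lab == pair[1], j], H[lab == pair[2], j])),
    numeric(1))
  data.frame(channel = colnames(hist_lap),
             region = unname(laplacian_regions()[colnames(hist_lap)]),
             score = sc, stringsAsFactors = FALSE)
}

# ---- the full co-adaptive session ---------------------------------------

#' Run one simulated co-adaptive BCI session
#'
#' Executes the seven-run protocol end to end on synthetic EEG:
#' \describe{
#'   \item{Runs 1-3 (biased feedback)}{Laplacian C3/Cz/C4 alpha + beta log
#'     band-power, the three subject-independent binary LDA priors,
#'     per-trial supervised adaptation (adaptive inverse covariance, then
#'     class mean of the cued class).}
#'   \item{First retraining}{Band selection, class-pair selection by 5-fold
#'     cross-validation, CSP on the first channel subset with automatic
#'     filter count (2-6), six Laplacian channels by signed-r2 (2 per
#'     hemisphere region), shrinkage LDA on the concatenated features.}
#'   \item{Runs 4-5 (real feedback)}{After every trial the six Laplacians
#'     are re-selected over the last 100 trials and the classifier is
#'     recomputed.}
#'   \item{Second retraining}{Band and CSP recomputed on the full montage
#'     from runs 4-5; shrinkage LDA on CSP features only.}
#'   \item{Runs 6-7 (real feedback)}{Unsupervised pooled-mean adaptation
#'     with coefficient `uc_pooled_mean` (0.05).}
#' }
#' Classifier outputs are standardized online by a running estimate of the
#' score spread so the cursor gain is comparable across users.
#'
#' @param profile a [user_profile()]
#' @param config a [session_config()]
#' @param prior three binary priors from [make_subject_independent_prior()]
#' @param seed integer session seed
#' @return object of class `session_result`: per-trial records, per-run
#'   accuracies, and the selections made at each retraining
#' @export
run_session <- function(profile, config = session_config(), prior, seed = 1L) {
  if (!all(c("left-right", "left-foot", "foot-right") %in% names(prior)))
    stop_invalid("prior must contain the three binary pair models")
  fs <- config$fs
  montage_ch <- default_montage()$channel
  lap_table <- laplacian_neighbours()
  W_cand <- laplacian_filter_matrix(montage_ch, names(lap_table), lap_table)

  models <- lapply(prior, identity)
  n_total <- sum(config$runs)
  rec_run <- integer(n_total); rec_target <- character(n_total)
  rec_phase <- character(n_total); rec_pos <- numeric(n_total)
  rec_side <- numeric(n_total); rec_success <- logical(n_total)
  stored_recs <- list(); stored_labels <- character(0)
  hist_lap <- NULL; hist_csp <- NULL; hist_label <- character(0)
  retraining <- list()
  sel <- NULL       # selections after retrain 1 / 2
  score_scale <- NA_real_
  trial_global <- 0L

  n_runs <- length(config$runs)
  for (run in seq_len(n_runs)) {
    phase <- config$phases[run]
    stage <- if (run <= 3) "runs13" else if (run <= 5) "runs45" else "runs67"
    cls <- if (stage == "runs13") config$classes else sel$pair
    cues <- cue_sequence(cls, config$runs[run], child_seed(seed, 500L + run))

    for (t in seq_along(cues)) {
      trial_global <- trial_global + 1L
      target <- cues[t]
      rec <- simulate_trial(profile, target, config,
                            seed = child_seed(seed, 1000L + trial_global))

      if (stage == "runs13") {
        feat <- runs13_online(rec, config)
        # two priors containing the target, scores oriented toward it
        involved <- names(models)[vapply(models, function(m)
          target %in% m$classes, logical(1))]
        orient <- vapply(involved, function(nm)
          if (models[[nm]]$classes[1] == target) 1 else -1, numeric(1))
        S <- cbind(classify(models[[involved[1]]], feat$steps) * orient[1],
                   classify(models[[involved[2]]], feat$steps) * orient[2])
        if (is.na(score_scale)) score_scale <- stats::sd(as.numeric(S))
        if (score_scale <= 0 || !is.finite(score_scale)) score_scale <- 1
        state <- cursor_state(target, "biased")
        for (j in seq_len(nrow(S)))
          state <- biased_cursor_step(state, S[j, 1] / score_scale,
                                      S[j, 2] / score_scale,
                                      dt_ms = config$cursor_update_ms,
                                      decay = config$decay_per_step)
        score_scale <- 0.95 * score_scale + 0.05 * stats::sd(as.numeric(S))
        # supervised adaptation: centre -> inverse covariance -> class mean
        for (nm in involved) {
          m <- models[[nm]]
          m <- adapt_inv_cov(m, feat$trial, config$uc_inv_cov)
          m <- adapt_class_mean(m, feat$trial, target, config$uc_class_mean)
          models[[nm]] <- m
        }
        stored_recs[[length(stored_recs) + 1L]] <- rec
        stored_labels <- c(stored_labels, target)
      } else {
        # runs 4-7: single classifier on the chosen pair
        Fcsp <- virtual_filtered(rec$data, sel$csp_W, sel$band, fs)
        stl_csp <- step_trial_logvar(Fcsp, fs, config)
        if (stage == "runs45") {
          cand_F <- virtual_filtered(rec$data, W_cand, sel$band, fs)
          stl_cand <- step_trial_logvar(cand_F, fs, config)
          lap_idx <- match(sel$laplacians, colnames(W_cand))
          step_feats <- cbind(stl_csp$steps,
                              stl_cand$steps[, lap_idx, drop = FALSE])
          trial_feat <- c(stl_csp$trial, stl_cand$trial[lap_idx])
        } else {
          step_feats <- stl_csp$steps
          trial_feat <- stl_csp$trial
        }
        model <- sel$model
        raw <- classify(model, step_feats)
        if (is.na(score_scale) || score_scale <= 0) score_scale <- stats::sd(raw)
        side <- if (target == model$classes[1]) 1 else -1
        state <- cursor_state(target, "real", target_side = side)
        for (s_j in raw / score_scale)
          state <- real_cursor_step(state, s_j,
                                    dt_ms = config$cursor_update_ms)
        score_scale <- 0.95 * score_scale + 0.05 * stats::sd(raw)

        if (stage == "runs45") {
          # history update + per-trial re-selection and retraining
          hist_lap <- rbind(hist_lap, stl_cand$trial)
          hist_csp <- rbind(hist_csp, stl_csp$trial)
          hist_label <- c(hist_label, target)
          scores <- laplacian_scores(hist_lap, hist_label, sel$pair)
          sel$laplacians <- select_laplacians(scores)
          n_h <- nrow(hist_lap)
          keep <- max(1L, n_h - 99L):n_h
          Xtr <- cbind(hist_csp[keep, , drop = FALSE],
                       hist_lap[keep, sel$laplacians, drop = FALSE])
          sel$model <- train_shrinkage_lda(Xtr, hist_label[keep],
                                           classes = sel$pair)
          stored_recs[[length(stored_recs) + 1L]] <- rec
          stored_labels <- c(stored_labels, target)
        } else {
          sel$model <- adapt_pooled_mean(sel$model, trial_feat,
                                         config$uc_pooled_mean)
        }
      }

      rec_run[trial_global] <- run
      rec_target[trial_global] <- target
      rec_phase[trial_global] <- phase
      rec_pos[trial_global] <- state$position
      rec_side[trial_global] <- state$target_side
      rec_success[trial_global] <- trial_outcome(state)
    }

    # ---- retraining points ---------------------------------------------
    if (run == 3L) {
      epochs <- build_epochs(stored_recs, stored_labels, config)
      fb_int <- c(config$cue_to_feedback_s,
                  config$cue_to_feedback_s + config$feedback_s)
      band <- select_band(epochs, interval = fb_int)
      cand_feats <- logvar_features(epochs, W_cand, band, fb_int,
                                    zero_phase = FALSE)
      pair_sel <- select_class_pair(cand_feats, stored_labels,
                                    seed = child_seed(seed, 42L))
      pair <- pair_sel$pair
      in_pair <- stored_labels %in% pair
      scores <- laplacian_scores(cand_feats[in_pair, , drop = FALSE],
                                 stored_labels[in_pair], pair,
                                 window = nrow(cand_feats))
      lap6 <- select_laplacians(scores)
      sub <- csp_channels_stage1()
      ep_a <- subset_epochs(epochs, stored_labels == pair[1], sub)
      ep_b <- subset_epochs(epochs, stored_labels == pair[2], sub)
      csp <- compute_csp(ep_a, ep_b, band = band, interval = fb_int)
      comp <- select_csp_filters(csp)
      csp_W <- expand_filters(csp$filters[, comp, drop = FALSE],
                              sub, montage_ch)
      csp_feats <- logvar_features(epochs, csp_W, band, fb_int,
                                   zero_phase = FALSE)
      hist_lap <- cand_feats[in_pair, , drop = FALSE]
      hist_csp <- csp_feats[in_pair, , drop = FALSE]
      hist_label <- stored_labels[in_pair]
      Xtr <- cbind(hist_csp, hist_lap[, lap6, drop = FALSE])
      model <- train_shrinkage_lda(Xtr, hist_label, classes = pair)
      sel <- list(band = band, pair = pair, laplacians = lap6,
                  csp_W = csp_W, csp_eigenvalues = csp$eigenvalues,
                  csp_components = comp, model = model)
      retraining$after_run3 <- list(
        band = c(band$low, band$high), pair = pair, laplacians = lap6,
        n_csp = length(comp))
      score_scale <- stats::sd(classify(model, Xtr))
      stored_recs <- list(); stored_labels <- character(0)
    }
    if (run == 5L) {
      epochs <- build_epochs(stored_recs, stored_labels, config)
      fb_int <- c(config$cue_to_feedback_s,
                  config$cue_to_feedback_s + config$feedback_s)
      band <- select_band(epochs, interval = fb_int)
      sub <- csp_channels_stage2()
      ep_a <- subset_epochs(epochs, stored_labels == sel$pair[1], sub)
      ep_b <- subset_epochs(epochs, stored_labels == sel$pair[2], sub)
      csp <- compute_csp(ep_a, ep_b, band = band, interval = fb_int)
      comp <- select_csp_filters(csp)
      csp_W <- expand_filters(csp$filters[, comp, drop = FALSE],
                              sub, montage_ch)
      csp_feats <- logvar_features(epochs, csp_W, band, fb_int,
                                   zero_phase = FALSE)
      model <- train_shrinkage_lda(csp_feats, stored_labels,
                                   classes = sel$pair)
      sel$band <- band; sel$csp_W <- csp_W
      sel$csp_components <- comp; sel$model <- model
      retraining$after_run5 <- list(
        band = c(band$low, band$high), pair = sel$pair, n_csp = length(comp))
      score_scale <- stats::sd(classify(model, csp_feats))
      stored_recs <- list(); stored_labels <- character(0)
    }
  }

  trials <- data.frame(
    run = rec_run, trial = seq_len(n_total), phase = rec_phase,
    target = rec_target, final_position = rec_pos, target_side = rec_side,
    success = rec_success, stringsAsFactors = FALSE)
  run_acc <- vapply(seq_len(n_runs), function(r)
    100 * mean(trials$success[trials$run == r]), numeric(1))
  structure(list(
    trials = trials,
    run_accuracy = run_acc,
    feedback_accuracy = 100 * mean(trials$success[trials$phase == "real"]),
    retraining = retraining,
    seed = seed
  ), class = "session_result")
}

subset_epochs <- function(epochs, trial_mask, channels) {
  ch_idx <- match(channels, dimnames(epochs$data)[[2]])
  structure(list(data = epochs$data[trial_mask, ch_idx, , drop = FALSE],
                 labels = epochs$labels[trial_mask],
                 window = epochs$window, fs = epochs$fs),
            class = "epochs")
}

# Embed filters defined on a channel subset into the full montage order.
expand_filters <- function(W_sub, sub_channels, all_channels) {
  W <- matrix(0, length(all_channels), ncol(W_sub),
              dimnames = list(all_channels,
                              paste0("csp", seq_len(ncol(W_sub)))))
  W[sub_channels, ] <- W_sub
  W
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %d trials, feedback accuracy %.1f%%\n",
              nrow(x$trials), x$feedback_accuracy))
  cat("  per-run accuracy:",
      paste(sprintf("%.1f", x$run_accuracy), collapse = " "), "\n")
  invisible(x)
}
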