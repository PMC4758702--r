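# Common spatial patterns, signed-r2 discriminability, and the constrained
# channel/band/class-pair selection rules used at the retraining points.

#' Common spatial patterns between two classes
#'
#' Solves the generalized eigenvalue problem of the two class covariance
#' matrices. Components are sorted by decreasing class-1 variance ratio
#' (eigenvalue in \[0, 1\]); filters are normalized so that
#' `t(w) %*% (S_a + S_b) %*% w = 1`, and `patterns` are the corresponding
#' forward-model columns (`t(filters) %*% patterns = I`).
#'
#' @param epochs_a,epochs_b [epoch_trials()] objects, one per class, already
#'   band-filtered or accompanied by `band`
#' @param band optional [band_spec()] applied before covariance estimation
#' @param interval `(start_s, end_s)` analysis interval relative to the cue
#' @return object of class `csp_result`: `filters`, `patterns`,
#'   `eigenvalues`
#' @export
compute_csp <- function(epochs_a, epochs_b, band = NULL,
                        interval = c(0.5, 4)) {
  Sa <- class_covariance(epochs_a, band, interval)
  Sb <- class_covariance(epochs_b, band, interval)
  csp_from_cov(Sa, Sb)
}

class_covariance <- function(epochs, band, interval) {
  fs <- epochs$fs
  i0 <- round((interval[1] - epochs$window[1]) * fs) + 1L
  i1 <- round((interval[2] - epochs$window[1]) * fs)
  n_trials <- dim(epochs$data)[1]
  if (n_trials < 2) stop_invalid("need at least 2 trials per class")
  d <- dim(epochs$data)[2]
  S <- matrix(0, d, d)
  for (i in seq_len(n_trials)) {
    x <- epochs$data[i, , , drop = TRUE]
    if (!is.null(band)) x <- bandpass_butterworth(x, band, fs, zero_phase = TRUE)
    x <- x[, i0:i1, drop = FALSE]
    x <- x - rowMeans(x)
    Ci <- tcrossprod(x) / ncol(x)
    S <- S + Ci / sum(diag(Ci))          # trace-normalized per trial
  }
  S <- S / n_trials
  dimnames(S) <- list(dimnames(epochs$data)[[2]], dimnames(epochs$data)[[2]])
  S
}

csp_from_cov <- function(Sa, Sb) {
  C <- Sa + Sb
  eC <- eigen((C + t(C)) / 2, symmetric = TRUE)
  tol <- 1e-10 * max(eC$values)
  if (min(eC$values) < tol) {
    warning("rank-deficient pooled covariance; applying ridge regularization")
    ridge <- 1e-8 * sum(diag(C)) / nrow(C)
    C <- C + ridge * diag(nrow(C))
    eC <- eigen((C + t(C)) / 2, symmetric = TRUE)
  }
  W <- eC$vectors %*% diag(1 / sqrt(eC$values))   # whitener of C
  S <- t(W) %*% Sa %*% W
  eS <- eigen((S + t(S)) / 2, symmetric = TRUE)   # eigenvalues in [0, 1]
  filters <- W %*% eS$vectors
  patterns <- C %*% filters                       # t(filters) %*% patterns = I
  rownames(filters) <- rownames(patterns) <- rownames(Sa)
  structure(list(filters = filters, patterns = patterns,
                 eigenvalues = pmin(pmax(eS$values, 0), 1)),
            class = "csp_result")
}

#' Automatic CSP filter-count selection
#'
#' Retains components symmetrically from both eigenvalue extremes whose
#' variance ratio deviates from 0.5 by at least `theta`, clipped to
#' \[`min_k`, `max_k`\] with at least one component per extreme.
#'
#' @param csp a [compute_csp()] result
#' @param min_k,max_k bounds on the number of retained components
#' @param theta minimal `|eigenvalue - 0.5|` for retention
#' @return integer vector of component indices
#' @export
select_csp_filters <- function(csp, min_k = 2L, max_k = 6L, theta = 0.1) {
  ev <- csp$eigenvalues
  n <- length(ev)
  if (n < max_k) stop_invalid("need at least %d components, got %d", max_k, n)
  per_side <- max_k %/% 2L
  top <- max(1L, sum(ev[seq_len(per_side)] - 0.5 >= theta))
  bot <- max(1L, sum(0.5 - ev[n - seq_len(per_side) + 1L] >= theta))
  top <- min(top, per_side); bot <- min(bot, per_side)
  c(seq_len(top), n - rev(seq_len(bot)) + 1L)
}

#' Signed squared point-biserial correlation
#'
#' The discriminability score `sign(r) * r^2`, where `r` is the
#' point-biserial correlation between group membership and the feature:
#' `r = (mean_a - mean_b) / sd_total * sqrt(n_a * n_b) / (n_a + n_b)`
#' with the population (1/n) total standard deviation.
#'
#' @param values_a,values_b numeric vectors of per-trial feature values
#' @return signed score in \[-1, 1\]; zero total variance returns 0 with
#'   attribute `degenerate = TRUE`
#' @export
signed_r2 <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stop_invalid("both groups must be non-empty")
  na <- length(values_a); nb <- length(values_b)
  all_v <- c(values_a, values_b)
  sd_tot <- sqrt(mean((all_v - mean(all_v))^2))
  if (sd_tot == 0) return(structure(0, degenerate = TRUE))
  r <- (mean(values_a) - mean(values_b)) / sd_tot * sqrt(na * nb) / (na + nb)
  sign(r) * r^2
}

#' Select six Laplacian channels constrained by hemisphere
#'
#' Picks the `per_region` channels with the largest absolute
#' discriminability score within each region (left, center, right), with a
#' deterministic alphabetical tie-break.
#'
#' @param scores data.frame with columns `channel`, `region`, `score`
#' @param per_region channels per region (default 2)
#' @return character vector of selected channels (left, center, right order)
#' @export
select_laplacians <- function(scores, per_region = 2L) {
  out <- character(0)
  for (reg in c("left", "center", "right")) {
    cand <- scores[scores$region == reg, , drop = FALSE]
    if (nrow(cand) < per_region)
      stop_invalid("region '%s' has fewer than %d candidate channels",
                   reg, per_region)
    ord <- order(-abs(cand$score), cand$channel)
    out <- c(out, cand$channel[ord[seq_len(per_region)]])
  }
  out
}

# channels x k matrix of small-Laplacian spatial filters for the given
# centre channels (+1 centre, -1/4 each neighbour).
laplacian_filter_matrix <- function(channel_labels, centers,
                                    neighbour_table = laplacian_neighbours()) {
  W <- matrix(0, length(channel_labels), length(centers),
              dimnames = list(channel_labels, centers))
  for (ch in centers) {
    nb <- neighbour_table[[ch]]
    if (is.null(nb)) stop_invalid("no neighbour table entry for '%s'", ch)
    W[ch, ch] <- 1
    W[nb, ch] <- -0.25
  }
  W
}

#' Select the most discriminative frequency band
#'
#' Scores every candidate band by the sum of the `top_m` largest absolute
#' signed-r2 values of log band-power features over the motor Laplacian
#' channels, maximized over class pairs, and returns the best candidate.
#' Ties fall back to the alpha band (or the first candidate).
#'
#' @param epochs an [epoch_trials()] object with class labels
#' @param candidates list of [band_spec()] candidates
#' @param interval analysis interval `(start_s, end_s)` relative to the cue
#' @param top_m number of channel scores summed per band
#' @return the selected [band_spec()]
#' @export
select_band <- function(epochs, candidates = list(band_spec(8, 15, "alpha"),
                                                  band_spec(16, 32, "beta")),
                        interval = c(0.5, 4), top_m = 3L,
                        zero_phase = FALSE) {
  if (length(candidates) < 2) stop_invalid("need at least 2 candidate bands")
  labels <- unique(epochs$labels)
  laps <- laplacian_neighbours()
  W <- laplacian_filter_matrix(dimnames(epochs$data)[[2]], names(laps), laps)
  score_band <- function(band) {
    feats <- logvar_features(epochs, W, band, interval, zero_phase = zero_phase)
    best <- 0
    for (i in seq_along(labels)) for (j in seq_along(labels)) {
      if (i >= j) next
      r2 <- apply(feats, 2, function(v)
        abs(signed_r2(v[epochs$labels == labels[i]],
                      v[epochs$labels == labels[j]])))
      best <- max(best, sum(sort(r2, decreasing = TRUE)[seq_len(top_m)]))
    }
    best
  }
  sc <- vapply(candidates, score_band, numeric(1))
  if (diff(range(sc)) < 1e-12) {
    is_alpha <- vapply(candidates, function(b) identical(b$name, "alpha"),
                       logical(1))
    return(candidates[[if (any(is_alpha)) which(is_alpha)[1] else 1L]])
  }
  candidates[[which.max(sc)]]
}

#' Select the best-classified class pair by cross-validation
#'
#' Evaluates the three class pairs (left-right, left-foot, foot-right) by
#' k-fold cross-validated shrinkage-LDA accuracy on the supplied features
#' and returns the winner; ties break by the fixed pair order.
#'
#' @param features trials x features matrix
#' @param labels per-trial class labels (3 classes)
#' @param k number of folds
#' @param seed fold-assignment seed
#' @return list with `pair` (character 2-vector) and `accuracy` (named
#'   numeric vector, one entry per pair)
#' @export
select_class_pair <- function(features, labels, k = 5L, seed = 1L) {
  pairs <- list(c("left", "right"), c("left", "foot"), c("foot", "right"))
  acc <- numeric(length(pairs))
  names(acc) <- vapply(pairs, paste, character(1), collapse = "-")
  for (p in seq_along(pairs)) {
    sel <- labels %in% pairs[[p]]
    acc[p] <- cv_accuracy(features[sel, , drop = FALSE], labels[sel],
                          pairs[[p]], k, child_seed(seed, p))
  }
  best <- which.max(acc)   # which.max takes the first maximum: fixed order
  list(pair = pairs[[best]], accuracy = acc)
}

# k-fold cross-validated shrinkage-LDA accuracy for a binary problem.
cv_accuracy <- function(X, y, pair, k = 5L, seed = 1L) {
  n <- nrow(X)
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) next
    model <- train_shrinkage_lda(X[tr, , drop = FALSE], y[tr], classes = pair)
    sc <- X[!tr, , drop = FALSE] %*% model$w + model$b
    pred <- ifelse(sc > 0, pair[1], pair[2])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / n
}
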