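# Linear discriminant analysis (plain and shrinkage-regularized) and the
# three per-trial adaptation schemes: supervised class-mean tracking,
# adaptive inverse-covariance estimation, and unsupervised pooled-mean
# bias tracking.

new_lda_model <- function(means, inv_cov, classes, gamma = 0, n_seen = 0L) {
  w <- as.numeric(inv_cov %*% (means[[1]] - means[[2]]))
  pooled <- (means[[1]] + means[[2]]) / 2
  structure(list(
    classes = classes,
    means = means,
    inv_cov = inv_cov,
    w = w,
    b = -sum(w * pooled),
    pooled_mean = pooled,
    shrinkage_gamma = gamma,
    n_seen = n_seen
  ), class = "lda_model")
}

refresh_weights <- function(model) {
  model$w <- as.numeric(model$inv_cov %*% (model$means[[1]] - model$means[[2]]))
  model$b <- -sum(model$w * model$pooled_mean)
  model
}

#' Train a binary LDA classifier
#'
#' Pooled-covariance linear discriminant: `w = S^-1 (m1 - m2)`,
#' `b = -t(w) (m1 + m2) / 2`; positive decision values map to the first
#' class. A singular pooled covariance falls back to a trace-scaled ridge.
#'
#' @param X trials x features matrix
#' @param y per-trial labels (exactly two classes)
#' @param classes optional length-2 character vector fixing the positive /
#'   negative class order (defaults to order of first appearance)
#' @return object of class `lda_model`
#' @export
train_lda <- function(X, y, classes = NULL) {
  prep <- lda_prep(X, y, classes)
  S <- crossprod(prep$Z) / max(1L, nrow(prep$Z) - 2L)
  inv_cov <- tryCatch(chol2inv(chol(S)), error = function(e) {
    ridge <- 1e-8 * sum(diag(S)) / ncol(S)
    chol2inv(chol(S + ridge * diag(ncol(S))))
  })
  new_lda_model(prep$means, inv_cov, prep$classes, gamma = 0,
                n_seen = nrow(X))
}

lda_prep <- function(X, y, classes) {
  X <- as.matrix(X)
  if (is.null(classes)) classes <- unique(y)
  if (length(classes) != 2 || !all(y %in% classes))
    stop_invalid("exactly two classes required")
  if (length(unique(y)) < 2) stop_invalid("both classes must be present")
  m1 <- colMeans(X[y == classes[1], , drop = FALSE])
  m2 <- colMeans(X[y == classes[2], , drop = FALSE])
  Z <- rbind(sweep(X[y == classes[1], , drop = FALSE], 2, m1),
             sweep(X[y == classes[2], , drop = FALSE], 2, m2))
  list(means = list(m1, m2), Z = Z, classes = classes)
}

#' Train a shrinkage-LDA classifier
#'
#' LDA whose pooled covariance is shrunk toward a scaled identity,
#' `(1 - gamma) S + gamma nu I` with `nu = trace(S)/d`, with `gamma` chosen
#' by the analytic (Ledoit-Wolf-type) risk-minimizing formula. This keeps
#' the classifier well-conditioned when the feature dimension approaches
#' the trial count, the regime of the later training stages.
#'
#' @inheritParams train_lda
#' @param gamma optional fixed shrinkage intensity in \[0, 1\]; `NULL`
#'   selects it analytically
#' @return `lda_model` with `shrinkage_gamma` set
#' @export
train_shrinkage_lda <- function(X, y, classes = NULL, gamma = NULL) {
  prep <- lda_prep(X, y, classes)
  Z <- prep$Z
  n <- nrow(Z); d <- ncol(Z)
  S <- crossprod(Z) / (n - 1L)
  nu <- sum(diag(S)) / d
  if (is.null(gamma)) gamma <- analytic_gamma(Z, S, nu)
  Sh <- (1 - gamma) * S + gamma * nu * diag(d)
  inv_cov <- chol2inv(chol(Sh))
  new_lda_model(prep$means, inv_cov, prep$classes, gamma = gamma,
                n_seen = nrow(X))
}

# Analytic shrinkage intensity toward nu*I (Ledoit-Wolf / Schafer-Strimmer):
# gamma* = sum_ij Var-hat(s_ij) / sum_ij (s_ij - t_ij)^2, clipped to [0, 1].
analytic_gamma <- function(Z, S, nu) {
  n <- nrow(Z); d <- ncol(Z)
  if (n < 3) return(1)
  wbar2_sum <- 0; var_sum <- 0
  # W_k = z_k z_k'; Var(s_ij) = n/(n-1)^3 * sum_k (w_kij - wbar_ij)^2
  Wbar <- crossprod(Z) / n
  sum_w2 <- matrix(0, d, d)
  for (k in seq_len(n)) {
    Wk <- tcrossprod(Z[k, ])
    sum_w2 <- sum_w2 + (Wk - Wbar)^2
  }
  var_hat <- n / (n - 1)^3 * sum_w2
  target <- nu * diag(d)
  denom <- sum((S - target)^2)
  if (denom <= 0) return(1)
  min(1, max(0, sum(var_hat) / denom))
}

#' Linear decision value
#'
#' `score = t(w) x + b`; the sign encodes the class (positive = first
#' class of the model's pair).
#'
#' @param model an `lda_model`
#' @param x feature vector, or trials x features matrix
#' @return numeric decision value(s)
#' @export
classify <- function(model, x) {
  if (is.matrix(x)) {
    if (ncol(x) != length(model$w))
      stop_invalid("feature dimension %d does not match model (%d)",
                   ncol(x), length(model$w))
    return(as.numeric(x %*% model$w + model$b))
  }
  if (length(x) != length(model$w))
    stop_invalid("feature dimension %d does not match model (%d)",
                 length(x), length(model$w))
  sum(model$w * x) + model$b
}

#' Supervised class-mean adaptation
#'
#' Exponentially weighted update of the labelled class mean:
#' `m_label <- (1 - uc) m_label + uc x`; the other class mean is untouched
#' and the hyperplane is recomputed.
#'
#' @param model an `lda_model`
#' @param x observed feature vector
#' @param label class label of the trial
#' @param uc update coefficient in \[0, 1\]
#' @return updated `lda_model`
#' @export
adapt_class_mean <- function(model, x, label, uc) {
  i <- match(label, model$classes)
  if (is.na(i)) stop_invalid("label '%s' not in model classes", label)
  model$means[[i]] <- (1 - uc) * model$means[[i]] + uc * x
  model$pooled_mean <- (model$means[[1]] + model$means[[2]]) / 2
  model$n_seen <- model$n_seen + 1L
  refresh_weights(model)
}

#' Adaptive inverse-covariance update
#'
#' Rank-one update equivalent to `S <- (1 - uc) S + uc xt %*% t(xt)` with
#' `xt = x - pooled_mean`, carried out directly on the inverse via the
#' matrix-inversion lemma (no explicit inversion). Symmetry is enforced
#' after each step; loss of positive definiteness triggers a ridge
#' correction with a warning.
#'
#' @param model an `lda_model`
#' @param x observed feature vector (uncentred)
#' @param uc update coefficient in \[0, 1\]
#' @return updated `lda_model`
#' @export
adapt_inv_cov <- function(model, x, uc) {
  if (uc == 0) return(model)
  P <- model$inv_cov
  xt <- x - model$pooled_mean
  Px <- as.numeric(P %*% xt)
  denom <- 1 + uc / (1 - uc) * sum(xt * Px)
  P_new <- P / (1 - uc) - (uc / (1 - uc)^2) * tcrossprod(Px) / denom
  P_new <- (P_new + t(P_new)) / 2
  if (!all(is.finite(P_new)) ||
      inherits(tryCatch(chol(P_new), error = identity), "error")) {
    warning("inverse covariance lost positive definiteness; ridge-correcting")
    ev <- eigen(P_new, symmetric = TRUE)
    lam <- pmax(ev$values, 1e-10 * max(abs(ev$values), 1e-30))
    P_new <- ev$vectors %*% (lam * t(ev$vectors))
  }
  model$inv_cov <- P_new
  refresh_weights(model)
}

#' Unsupervised pooled-mean adaptation
#'
#' Label-free tracking of the global feature mean,
#' `mu <- (1 - uc) mu + uc x`, shifting the hyperplane bias to
#' `b = -t(w) mu` while leaving `w` unchanged. This is the only adaptation
#' running in the final two runs; the default coefficient is 0.05.
#'
#' @param model an `lda_model`
#' @param x observed feature vector
#' @param uc update coefficient (default 0.05)
#' @return updated `lda_model`
#' @export
adapt_pooled_mean <- function(model, x, uc = 0.05) {
  model$pooled_mean <- (1 - uc) * model$pooled_mean + uc * x
  model$b <- -sum(model$w * model$pooled_mean)
  model$n_seen <- model$n_seen + 1L
  model
}

#' Train the three subject-independent prior classifiers
#'
#' Simulates calibration trials for a cohort of user profiles, extracts the
#' run 1-3 feature set (Laplacian C3/Cz/C4, alpha and beta log band-power),
#' pools trials across users and trains one binary LDA per class pair
#' (left-right, left-foot, foot-right). These priors stand in for the
#' classifiers trained on previously recorded well-performing participants.
#'
#' @param cohort list of [user_profile()] objects
#' @param config a [session_config()]
#' @param trials_per_class simulated calibration trials per class per user
#' @param seed integer seed
#' @return named list of three `lda_model`s
#' @export
make_subject_independent_prior <- function(cohort, config = session_config(),
                                           trials_per_class = 15L,
                                           seed = 1L) {
  if (length(cohort) < 2) stop_invalid("cohort must contain >= 2 profiles")
  feats <- NULL; labs <- character(0)
  tr_i <- 0L
  for (u in seq_along(cohort)) {
    for (cl in config$classes) {
      for (t in seq_len(trials_per_class)) {
        tr_i <- tr_i + 1L
        rec <- simulate_trial(cohort[[u]], cl, config,
                              seed = child_seed(seed, tr_i))
        f <- runs13_features(rec, config)
        feats <- rbind(feats, f)
        labs <- c(labs, cl)
      }
    }
  }
  pairs <- list(c("left", "right"), c("left", "foot"), c("foot", "right"))
  models <- lapply(pairs, function(p) {
    sel <- labs %in% p
    train_lda(feats[sel, , drop = FALSE], labs[sel], classes = p)
  })
  names(models) <- vapply(pairs, paste, character(1), collapse = "-")
  models
}

#' Serialize / restore an LDA model
#'
#' Writes a JSON description plus a binary little-endian double sidecar
#' (`<path>.bin`) holding the numeric arrays, so restored models classify
#' bit-identically.
#'
#' @param model an `lda_model`
#' @param path output path for the JSON file
#' @return `path`, invisibly
#' @export
write_lda_model <- function(model, path) {
  nums <- c(model$means[[1]], model$means[[2]], as.numeric(model$inv_cov),
            model$w, model$b, model$pooled_mean, model$shrinkage_gamma)
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(nums, con, size = 8, endian = "little")
  close(con)
  meta <- list(classes = model$classes, d = length(model$w),
               n_seen = model$n_seen)
  jsonlite::write_json(meta, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- meta$d
  n_num <- 2 * d + d * d + d + 1 + d + 1
  con <- file(paste0(path, ".bin"), "rb")
  nums <- readBin(con, "double", n = n_num, size = 8, endian = "little")
  close(con)
  i <- 0L
  take <- function(k) { out <- nums[(i + 1):(i + k)]; i <<- i + k; out }
  m1 <- take(d); m2 <- take(d)
  inv_cov <- matrix(take(d * d), d, d)
  w <- take(d); b <- take(1); pooled <- take(d); gamma <- take(1)
  structure(list(classes = meta$classes, means = list(m1, m2),
                 inv_cov = inv_cov, w = w, b = b, pooled_mean = pooled,
                 shrinkage_gamma = gamma, n_seen = meta$n_seen),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %s vs %s, d = %d, gamma = %.3f, n_seen = %d\n",
              x$classes[1], x$classes[2], length(x$w), x$shrinkage_gamma,
              x$n_seen))
  invisible(x)
}
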