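# LDA, shrinkage LDA and the three adaptation schemes.

test_that("LDA separates well-separated Gaussian clouds", {
  set.seed(20)
  n <- 200
  X <- rbind(matrix(rnorm(n * 2, mean = 0), n),
             matrix(rnorm(n * 2, mean = 4), n))
  y <- rep(c("a", "b"), each = n)
  model <- train_lda(X, y)
  pred <- ifelse(classify(model, X) > 0, "a", "b")
  expect_gte(mean(pred == y), 0.95)
  # identical class data: near-zero weights
  X0 <- rbind(X[1:n, ], X[1:n, ])
  m0 <- train_lda(X0, y)
  expect_lt(sqrt(sum(m0$w^2)), 0.2)
  expect_error(train_lda(X, rep("a", 2 * n)), "class")
})

test_that("equal-covariance LDA puts the boundary midway between means", {
  set.seed(21)
  n <- 4000
  X <- rbind(matrix(rnorm(n * 2), n),
             cbind(rnorm(n, 2), rnorm(n)))
  y <- rep(c("a", "b"), each = n)
  model <- train_lda(X, y, classes = c("b", "a"))
  # w proportional to (2,0) - (0,0) direction, boundary at x1 = 1
  expect_lt(abs(model$w[2] / model$w[1]), 0.05)
  expect_lt(abs(classify(model, c(1, 0))) / abs(model$w[1]), 0.1)
  # midpoint of the class means scores exactly zero
  mid <- (model$means[[1]] + model$means[[2]]) / 2
  expect_equal(classify(model, mid), 0, tolerance = 1e-12)
  expect_gt(classify(model, model$means[[1]]), 0)
  # affine consistency
  x1 <- rnorm(2); x2 <- rnorm(2)
  expect_equal(classify(model, x1) - classify(model, x2),
               sum(model$w * (x1 - x2)), tolerance = 1e-12)
  expect_error(classify(model, c(1, 2, 3)), "dimension")
})

test_that("analytic shrinkage vanishes for n >> d and regularizes d > n", {
  set.seed(22)
  n <- 5000
  x1 <- rnorm(n)
  X <- cbind(x1, 0.6 * x1 + 2 * rnorm(n))      # anisotropic, correlated
  X[(n / 2 + 1):n, 1] <- X[(n / 2 + 1):n, 1] + 2
  y <- rep(c("a", "b"), each = n / 2)
  plain <- train_lda(X, y)
  shr <- train_shrinkage_lda(X, y)
  expect_lte(shr$shrinkage_gamma, 0.05)
  angle <- acos(sum(plain$w * shr$w) /
                  sqrt(sum(plain$w^2) * sum(shr$w^2))) * 180 / pi
  expect_lt(angle, 5)
  # d > n stays finite and learns the training set better than chance
  d <- 50; m <- 20
  Xs <- rbind(matrix(rnorm(m / 2 * d), m / 2),
              matrix(rnorm(m / 2 * d, mean = 1), m / 2))
  ys <- rep(c("a", "b"), each = m / 2)
  ms <- train_shrinkage_lda(Xs, ys)
  expect_true(all(is.finite(ms$w)))
  pred <- ifelse(classify(ms, Xs) > 0, "a", "b")
  expect_gt(mean(pred == ys), 0.5)
  # gamma = 1 collapses to the scaled-identity covariance
  m1 <- train_shrinkage_lda(Xs, ys, gamma = 1)
  dmean <- m1$means[[1]] - m1$means[[2]]
  expect_gt(abs(stats::cor(m1$w, dmean)), 1 - 1e-10)
})

test_that("class-mean adaptation equals the exponentially weighted mean", {
  set.seed(23)
  model <- train_lda(rbind(matrix(rnorm(40), 20),
                           matrix(rnorm(40) + 2, 20)),
                     rep(c("a", "b"), each = 20))
  uc <- 0.1
  m0 <- model$means[[1]]
  xs <- matrix(rnorm(60), 30)
  for (i in 1:30) model <- adapt_class_mean(model, xs[i, ], "a", uc)
  # brute-force recomputation of the exponentially weighted mean
  expected <- m0
  for (i in 1:30) expected <- (1 - uc) * expected + uc * xs[i, ]
  expect_equal(model$means[[1]], expected, tolerance = 1e-12)
  # uc extremes
  m_id <- adapt_class_mean(model, c(9, 9), "a", 0)
  expect_equal(m_id$means[[1]], model$means[[1]])
  m_jump <- adapt_class_mean(model, c(9, 9), "a", 1)
  expect_equal(m_jump$means[[1]], c(9, 9), ignore_attr = TRUE)
  # the other class mean is untouched
  expect_equal(m_jump$means[[2]], model$means[[2]])
  # w/b stay consistent with the stated identities
  expect_equal(m_jump$w,
               as.numeric(m_jump$inv_cov %*%
                            (m_jump$means[[1]] - m_jump$means[[2]])))
})

test_that("inverse-covariance updates match explicit inversion per step", {
  set.seed(24)
  d <- 4
  X0 <- matrix(rnorm(60 * d), 60)
  model <- train_lda(cbind(X0), rep(c("a", "b"), each = 30))
  uc <- 0.05
  S_explicit <- solve(model$inv_cov)
  worst <- 0
  for (i in 1:100) {
    x <- rnorm(d, mean = model$pooled_mean)
    xt <- x - model$pooled_mean
    S_explicit <- (1 - uc) * S_explicit + uc * tcrossprod(xt)
    model <- adapt_inv_cov(model, x, uc)
    worst <- max(worst, max(abs(model$inv_cov %*% S_explicit - diag(d))))
  }
  expect_lt(worst, 1e-8)
  expect_lt(max(abs(model$inv_cov - t(model$inv_cov))), 1e-12)
  # uc = 0 is a no-op
  m0 <- adapt_inv_cov(model, rnorm(d), 0)
  expect_equal(m0$inv_cov, model$inv_cov)
})

test_that("inverse-covariance estimate converges to the true inverse", {
  set.seed(25)
  d <- 3
  A <- matrix(rnorm(d * d), d)
  Sigma <- crossprod(A) + diag(d)
  true_inv <- solve(Sigma)
  model <- train_lda(matrix(rnorm(40 * d), 40), rep(c("a", "b"), each = 20))
  model$pooled_mean <- rep(0, d)
  uc <- 0.01
  L <- t(chol(Sigma))
  err0 <- sqrt(sum((model$inv_cov - true_inv)^2))
  errs <- numeric(0)
  for (i in 1:2000) {
    model <- adapt_inv_cov(model, as.numeric(L %*% rnorm(d)), uc)
    if (i %in% c(50, 500, 2000))
      errs <- c(errs, sqrt(sum((model$inv_cov - true_inv)^2)))
  }
  expect_lt(errs[1], err0)
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.5 * sqrt(sum(true_inv^2)))
})

test_that("pooled-mean adaptation shifts only the bias, geometrically", {
  set.seed(26)
  model <- train_lda(rbind(matrix(rnorm(40), 20),
                           matrix(rnorm(40) + 3, 20)),
                     rep(c("a", "b"), each = 20))
  w0 <- model$w
  x0 <- c(5, -2)
  m <- model
  for (i in 1:200) m <- adapt_pooled_mean(m, x0)    # default uc = 0.05
  expect_equal(m$w, w0)
  expect_equal(m$pooled_mean, x0, tolerance = 1e-3)
  # geometric rate: after k steps the gap shrinks by (1 - 0.05)^k
  m1 <- adapt_pooled_mean(model, x0, 0.05)
  expect_equal(m1$pooled_mean - x0, (1 - 0.05) * (model$pooled_mean - x0),
               tolerance = 1e-12)
  expect_equal(m1$b, -sum(w0 * m1$pooled_mean))
  # symmetric stream: no systematic drift of the bias
  m2 <- model
  bs <- numeric(500)
  for (i in 1:500) {
    m2 <- adapt_pooled_mean(m2, model$pooled_mean + rnorm(2))
    bs[i] <- m2$b
  }
  expect_gt(stats::t.test(bs - model$b)$p.value, 0.01)
})

test_that("default pooled-mean coefficient from config is 0.05", {
  expect_equal(session_config()$uc_pooled_mean, 0.05)
  expect_equal(formals(adapt_pooled_mean)$uc, 0.05)
})

test_that("serialization round-trips classify outputs bit-exactly", {
  set.seed(27)
  X <- rbind(matrix(rnorm(60), 30), matrix(rnorm(60) + 1, 30))
  model <- train_shrinkage_lda(X, rep(c("left", "right"), each = 30))
  path <- file.path(tempdir(), "model.json")
  write_lda_model(model, path)
  back <- read_lda_model(path)
  probe <- matrix(rnorm(20), 10)
  expect_identical(classify(model, probe), classify(back, probe))
  expect_identical(back$classes, model$classes)
})

test_that("subject-independent priors beat chance on a held-out strong user", {
  prior <- test_prior()
  expect_named(prior, c("left-right", "left-foot", "foot-right"))
  cfg <- session_config()
  held_out <- user_profile(erd_depth = c(left = 0.6, right = 0.6, foot = 0.4),
                           seed = 999)
  correct <- 0L; total <- 0L
  for (cl in c("left", "right")) {
    for (i in 1:15) {
      rec <- simulate_trial(held_out, cl, cfg, seed = 5000 + total)
      f <- smrbci:::runs13_features(rec, cfg)
      pred <- if (classify(prior[["left-right"]], f) > 0) "left" else "right"
      correct <- correct + (pred == cl); total <- total + 1L
    }
  }
  expect_gt(correct / total, 0.5469)
})
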