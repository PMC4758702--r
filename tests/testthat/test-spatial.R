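# CSP, signed-r2 discriminability and the selection rules.

make_epochs <- function(data_fun, n_trials, n_ch, n_samp, labels,
                        ch = paste0("ch", seq_len(n_ch)), fs = 100,
                        window = c(0, n_samp / fs)) {
  data <- array(0, dim = c(n_trials, n_ch, n_samp),
                dimnames = list(NULL, ch, NULL))
  for (i in seq_len(n_trials)) data[i, , ] <- data_fun(i)
  structure(list(data = data, labels = labels, window = window, fs = fs),
            class = "epochs")
}

test_that("CSP recovers the closed-form variance ratio on a diagonal toy", {
  set.seed(10)
  n <- 60; ns <- 300
  ep_a <- make_epochs(function(i) rbind(2 * rnorm(ns), rnorm(ns)),
                      n, 2, ns, rep("a", n))
  ep_b <- make_epochs(function(i) rbind(rnorm(ns), 2 * rnorm(ns)),
                      n, 2, ns, rep("b", n))
  csp <- compute_csp(ep_a, ep_b, interval = c(0, 3))
  # class variances (4, 1) vs (1, 4): top eigenvalue 4/(4+1) = 0.8
  expect_lt(abs(csp$eigenvalues[1] - 0.8), 0.05)
  expect_lt(abs(csp$eigenvalues[2] - 0.2), 0.05)
  expect_equal(csp$eigenvalues, sort(csp$eigenvalues, decreasing = TRUE))
  # filters and patterns are mutually consistent
  expect_equal(t(csp$filters) %*% csp$patterns, diag(2),
               tolerance = 1e-8, ignore_attr = TRUE)
  # top filter dominated by channel 1
  expect_gt(abs(csp$filters[1, 1]), abs(csp$filters[2, 1]))
})

test_that("identical class covariances give eigenvalues at 0.5", {
  set.seed(11)
  ns <- 300
  ep_a <- make_epochs(function(i) matrix(rnorm(3 * ns), 3), 40, 3, ns,
                      rep("a", 40))
  ep_b <- make_epochs(function(i) matrix(rnorm(3 * ns), 3), 40, 3, ns,
                      rep("b", 40))
  csp <- compute_csp(ep_a, ep_b, interval = c(0, 3))
  expect_true(all(abs(csp$eigenvalues - 0.5) < 0.05))
})

test_that("CSP matches brute-force direction search on a 3-channel toy", {
  set.seed(12)
  A <- matrix(rnorm(9), 3); B <- matrix(rnorm(9), 3)
  Sa <- crossprod(A) + diag(3); Sb <- crossprod(B) + diag(3)
  csp <- smrbci:::csp_from_cov(Sa, Sb)
  obj <- function(w) (t(w) %*% Sa %*% w) / (t(w) %*% (Sa + Sb) %*% w)
  dirs <- matrix(rnorm(3 * 10000), 3)
  dirs <- dirs / sqrt(colSums(dirs^2))
  brute <- max(apply(dirs, 2, obj))
  expect_gte(as.numeric(obj(csp$filters[, 1])), brute - 0.01)
  expect_lt(abs(as.numeric(obj(csp$filters[, 1])) - csp$eigenvalues[1]), 1e-10)
})

test_that("CSP filter-count rule keeps 2-6 informative extremes", {
  fake <- function(ev) structure(list(eigenvalues = ev), class = "csp_result")
  expect_equal(select_csp_filters(fake(c(0.9, 0.5, 0.5, 0.5, 0.5, 0.1))),
               c(1L, 6L))
  expect_equal(select_csp_filters(fake(c(0.9, 0.85, 0.8, 0.2, 0.15, 0.1))),
               1:6)
  expect_equal(select_csp_filters(fake(rep(0.5, 8))), c(1L, 8L))
  expect_equal(select_csp_filters(fake(c(0.9, 0.8, 0.5, 0.5, 0.5, 0.5, 0.1))),
               c(1L, 2L, 7L))
})

test_that("signed_r2 equals the signed squared Pearson point-biserial", {
  set.seed(13)
  for (rep in 1:5) {
    a <- rnorm(17, mean = rep); b <- rnorm(23)
    r0 <- stats::cor(c(a, b), rep(c(1, 0), times = c(17, 23)))
    expect_equal(as.numeric(signed_r2(a, b)), sign(r0) * r0^2,
                 tolerance = 1e-12)
  }
  expect_equal(as.numeric(signed_r2(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(as.numeric(signed_r2(rep(1, 4), rep(-1, 4))), 1)
  a <- rnorm(10); b <- rnorm(12)
  expect_equal(as.numeric(signed_r2(a, b)), -as.numeric(signed_r2(b, a)))
  # invariant under a common affine transform
  expect_equal(as.numeric(signed_r2(3 * a + 5, 3 * b + 5)),
               as.numeric(signed_r2(a, b)), tolerance = 1e-12)
  expect_true(attr(signed_r2(rep(2, 3), rep(2, 4)), "degenerate"))
})

test_that("select_laplacians picks top-2 per region with name tie-break", {
  sc <- data.frame(
    channel = c("C3", "C5", "C1", "Cz", "FCz", "CPz", "C4", "C2", "C6"),
    region = c("left", "left", "left", "center", "center", "center",
               "right", "right", "right"),
    score = c(0.4, 0.1, 0.3, 0.2, 0.1, 0.05, -0.5, 0.2, 0.1))
  expect_equal(select_laplacians(sc),
               c("C3", "C1", "Cz", "FCz", "C4", "C2"))
  sc$score <- 0.2
  picked <- select_laplacians(sc)
  expect_equal(picked[1:2], c("C1", "C3"))     # alphabetical among ties
  expect_equal(length(picked), 6)
  expect_error(select_laplacians(sc[-1:-2, ]), "left")
})

test_that("select_band picks the band containing the class contrast", {
  set.seed(14)
  mont <- default_montage()$channel
  build <- function(freq) {
    make_epochs(function(i) {
      base <- matrix(0.3 * rnorm(27 * 400), 27)
      amp <- if (i %% 2 == 0) 1.5 else 0.15    # class-dependent amplitude
      osc <- amp * sin(2 * pi * freq * (1:400) / 100 + runif(1) * 2 * pi)
      base["C3" == mont, ] <- base["C3" == mont, ] + osc
      base
    }, 60, 27, 400, rep(c("left", "right"), 30), ch = mont,
    window = c(-1, 3))
  }
  expect_equal(select_band(build(10), interval = c(0, 3))$name, "alpha")
  expect_equal(select_band(build(20), interval = c(0, 3))$name, "beta")
  flat <- make_epochs(function(i) matrix(0.5, 27, 400), 60, 27, 400,
                      rep(c("left", "right"), 30), ch = mont,
                      window = c(-1, 3))
  expect_equal(select_band(flat, interval = c(0, 3))$name, "alpha")
})

test_that("select_class_pair maximizes cross-validated accuracy", {
  set.seed(15)
  X <- rbind(matrix(rnorm(40 * 2, mean = 3), 40),
             matrix(rnorm(40 * 2, mean = -3), 40),
             matrix(rnorm(40 * 2, mean = 0), 40))
  y <- rep(c("left", "right", "foot"), each = 40)
  out <- select_class_pair(X, y, seed = 3)
  expect_equal(sort(out$pair), c("left", "right"))
  expect_gte(out$accuracy["left-right"], max(out$accuracy))
  # degenerate data: deterministic result under the declared pair order
  X0 <- matrix(rnorm(120 * 2), 120)
  out1 <- select_class_pair(X0, y, seed = 5)
  out2 <- select_class_pair(X0, y, seed = 5)
  expect_identical(out1, out2)
})
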