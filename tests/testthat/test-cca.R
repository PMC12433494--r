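planted_xy <- function(n, p = 6, q = 2, strength = 0.8, seed = 1) {
  withr::with_seed(seed, {
    f <- rnorm(n)
    X <- outer(f, rep(strength, p)) + matrix(rnorm(n * p), n, p)
    Y <- outer(f, rep(strength, q)) + matrix(rnorm(n * q), n, q)
    colnames(X) <- sprintf("x%02d", 1:p)
    colnames(Y) <- sprintf("y%02d", 1:q)
    list(X = X, Y = Y)
  })
}

test_that("a shared column yields a perfect first mode", {
  withr::with_seed(1, {
    X <- cbind(a = rnorm(100), b = rnorm(100))
    Y <- cbind(y1 = X[, 1], y2 = rnorm(100))
  })
  fit <- fit_cca(X, Y)
  expect_equal(fit$canonical_correlations[1], 1, tolerance = 1e-8)
  expect_length(fit$canonical_correlations, 2)
})

test_that("independent blocks produce small canonical correlations", {
  withr::with_seed(19, {
    X <- matrix(rnorm(500 * 3), 500, 3)
    Y <- matrix(rnorm(500 * 2), 500, 2)
  })
  fit <- fit_cca(X, Y)
  expect_true(all(fit$canonical_correlations < 0.3))
  expect_true(all(diff(fit$canonical_correlations) <= 1e-12))
  expect_true(all(fit$canonical_correlations >= 0 &
                    fit$canonical_correlations <= 1))
})

test_that("the number of modes is min(p, q)", {
  withr::with_seed(2, {
    X <- matrix(rnorm(80 * 18), 80, 18)
    Y <- matrix(rnorm(80 * 2), 80, 2)
  })
  fit <- fit_cca(X, Y)
  expect_length(fit$canonical_correlations, 2)
  expect_equal(dim(fit$x_backprojected), c(18, 2))
})

test_that("the SVD closed form agrees with the classical solver", {
  for (seed in c(3, 4, 5)) {
    d <- planted_xy(60, p = 5, q = 3, strength = 0.5, seed = seed)
    fit <- fit_cca(d$X, d$Y)
    ref <- stats::cancor(scale(d$X), scale(d$Y))
    expect_equal(fit$canonical_correlations, ref$cor, tolerance = 1e-8)
  }
})

test_that("canonical correlations are invariant to invertible reparameterisation", {
  d <- planted_xy(90, p = 4, q = 3, strength = 0.6, seed = 6)
  fit <- fit_cca(d$X, d$Y)
  withr::with_seed(7, {
    repeat {
      A <- matrix(rnorm(16), 4, 4)
      if (abs(det(A)) > 0.1) break
    }
  })
  fit_mixed <- fit_cca(d$X %*% A, d$Y)
  expect_equal(fit_mixed$canonical_correlations,
               fit$canonical_correlations, tolerance = 1e-8)
})

test_that("variates have unit variance and loadings follow the sign convention", {
  d <- planted_xy(120, seed = 8)
  fit <- fit_cca(d$X, d$Y)
  expect_equal(unname(apply(fit$x_variates, 2, sd)), rep(1, 2),
               tolerance = 1e-8)
  expect_equal(unname(apply(fit$y_variates, 2, sd)), rep(1, 2),
               tolerance = 1e-8)
  for (k in 1:2) {
    expect_gt(fit$x_backprojected[which.max(abs(fit$x_backprojected[, k])), k], 0)
    expect_gt(fit$y_backprojected[which.max(abs(fit$y_backprojected[, k])), k], 0)
  }
})

test_that("back-projection returns plain correlations with the variates", {
  d <- planted_xy(100, seed = 9)
  d$X[c(3, 11), 1] <- NA  # listwise rows must be respected
  fit <- suppressMessages(fit_cca(d$X, d$Y))
  bp <- backproject(fit, d$X, d$Y)
  keep <- stats::complete.cases(d$X) & stats::complete.cases(d$Y)
  expect_equal(bp$x, stats::cor(d$X[keep, ], fit$x_variates),
               tolerance = 1e-12)
  expect_equal(bp$y, stats::cor(d$Y[keep, ], fit$y_variates),
               tolerance = 1e-12)
  expect_true(all(abs(bp$x) <= 1) && all(abs(bp$y) <= 1))
  # a pure-noise variable stays near orthogonal to the signal-carrying
  # variate (weak trailing modes are themselves noise and are not checked)
  d2 <- planted_xy(400, seed = 10)
  withr::with_seed(77, {
    Xn <- cbind(d2$X, noise = rnorm(400))
  })
  fitn <- fit_cca(Xn, d2$Y)
  bpn <- backproject(fitn, Xn, d2$Y)
  expect_lt(abs(bpn$x["noise", 1]), 2 / sqrt(fitn$n) + 0.05)
})

test_that("planted structure concentrates loadings on the planted variables", {
  withr::with_seed(24, {
    n <- 250
    f <- rnorm(n)
    tagged <- outer(f, rep(0.9, 4)) + matrix(rnorm(n * 4), n, 4)
    untagged <- matrix(rnorm(n * 4), n, 4)
    X <- cbind(tagged, untagged)
    colnames(X) <- c(sprintf("tag%d", 1:4), sprintf("oth%d", 1:4))
    Y <- cbind(burden = f + rnorm(n, 0, 0.5), other = rnorm(n))
  })
  fit <- fit_cca(X, Y)
  bp <- backproject(fit, X, Y)
  mode <- which.max(abs(bp$y["burden", ]))
  expect_gt(mean(abs(bp$x[1:4, mode])), mean(abs(bp$x[5:8, mode])) + 0.2)
})

test_that("permutation inference is deterministic, powered and honest", {
  d <- planted_xy(300, strength = 0.6, seed = 11)
  p1 <- cca_permutation_test(d$X, d$Y, n_perm = 999, seed = 5)
  p2 <- cca_permutation_test(d$X, d$Y, n_perm = 999, seed = 5)
  expect_identical(p1$p, p2$p)
  expect_lte(p1$p[1], 0.001)
  expect_error(cca_permutation_test(d$X, d$Y, n_perm = 99), "999")
})

test_that("degenerate designs are rejected", {
  d <- planted_xy(30, p = 4, q = 2, seed = 12)
  expect_error(fit_cca(d$X[1:5, ], d$Y[1:5, ]), "more complete rows")
  Xdup <- cbind(d$X, dup = d$X[, 1])
  expect_error(fit_cca(Xdup, d$Y), "rank-deficient")
  expect_error(fit_cca(d$X, d$Y[1:10, ]), "same rows")
})
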