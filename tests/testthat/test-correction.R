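test_that("fit_covariates matches the normal-equations oracle", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(10:50, 1); k <- sample(1:5, 1); p <- sample(1:10, 1)
    C <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("c", 1:k)))
    X <- matrix(rnorm(n * p), n, p)
    m <- fit_covariates(X, C)
    Ci <- cbind(1, C)
    beta_oracle <- solve(t(Ci) %*% Ci) %*% t(Ci) %*% X  # brute force
    expect_lt(max(abs(m$beta_hat - beta_oracle)), 1e-10)
  }
})

test_that("intercept-only regression reduces to column means / centering", {
  set.seed(2)
  X <- matrix(rnorm(60), 12, 5)
  m <- fit_covariates(X, data.frame()[seq_len(12), , drop = FALSE])
  expect_equal(unname(m$beta_hat[1, ]), colMeans(X))
  Xa <- apply_covariates(m, X, data.frame()[seq_len(12), , drop = FALSE])
  expect_equal(Xa, scale(X, scale = FALSE), ignore_attr = TRUE)
})

test_that("noiseless covariate effects are recovered and removed exactly", {
  set.seed(3)
  n <- 25
  C <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  B <- matrix(rnorm(4 * 6), 4, 6)
  X <- cbind(1, C) %*% B
  m <- fit_covariates(X, C)
  expect_lt(max(abs(m$beta_hat - B)), 1e-10)
  expect_lt(max(abs(apply_covariates(m, X, C))), 1e-10)
})

test_that("training residuals are orthogonal to the design", {
  set.seed(4)
  n <- 40
  C <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  X <- matrix(rnorm(n * 8), n, 8) + outer(C$age, rnorm(8))
  Xa <- leaky_covariates(X, C)
  Ci <- cbind(1, as.matrix(C))
  expect_lt(max(abs(t(Ci) %*% Xa)), 1e-8)
})

test_that("rank-deficient covariates error naming the collinear column", {
  C <- data.frame(age = 1:10, age2 = 2 * (1:10))
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_covariates(X, C), "collinear.*age2")
})

test_that("apply refuses mismatched covariate columns", {
  set.seed(5)
  C <- data.frame(age = rnorm(10), sex = rbinom(10, 1, 0.5))
  m <- fit_covariates(matrix(rnorm(30), 10, 3), C)
  expect_error(apply_covariates(m, matrix(rnorm(30), 10, 3),
                                C[, c("sex", "age")]),
               "do not match")
})

test_that("train-fitted adjustment removes the planted confound out of sample", {
  # test-set residual correlation with the covariate shrinks as n_train grows
  resid_cor <- function(n_train, seeds = 50) {
    sapply(seq_len(seeds), function(i) {
      set.seed(i)
      n <- n_train + 30
      cv <- rnorm(n)
      X <- matrix(rnorm(n * 4), n, 4) + outer(cv, c(1, 1, 1, 1))
      tr <- seq_len(n_train); te <- (n_train + 1):n
      m <- fit_covariates(X[tr, ], data.frame(c1 = cv[tr]))
      Xte <- apply_covariates(m, X[te, ], data.frame(c1 = cv[te]))
      mean(abs(cor(Xte, cv[te])))
    })
  }
  expect_lt(mean(resid_cor(200)), mean(resid_cor(10)))
  expect_lt(mean(resid_cor(200)), 0.25)
})

test_that("leaky covariate regression is exactly fit + apply on the full data", {
  set.seed(6)
  X <- matrix(rnorm(200), 20, 10)
  C <- data.frame(age = rnorm(20))
  expect_identical(leaky_covariates(X, C),
                   apply_covariates(fit_covariates(X, C), X, C))
  # and differs from the train-fitted adjustment when slopes differ
  tr <- 1:10; te <- 11:20
  m_tr <- fit_covariates(X[tr, ], C[tr, , drop = FALSE])
  leaky_te <- leaky_covariates(X, C)[te, ]
  cv_te <- apply_covariates(m_tr, X[te, ], C[te, , drop = FALSE])
  expect_gt(max(abs(leaky_te - cv_te)), 1e-4)
})

test_that("single-site ComBat is the identity (eb off)", {
  set.seed(7)
  X <- matrix(rnorm(80), 16, 5)
  m <- fit_combat(X, rep("A", 16), eb = FALSE)
  expect_equal(unname(m$gamma_star), matrix(0, 1, 5), tolerance = 1e-12)
  expect_equal(unname(m$delta_star), matrix(1, 1, 5), tolerance = 1e-12)
  expect_equal(apply_combat(m, X, rep("A", 16)), X, tolerance = 1e-12)
})

test_that("ComBat equalizes per-site means and preserves the grand mean (eb off)", {
  set.seed(8)
  n <- 60; p <- 15
  site <- rep(c("A", "B", "C"), each = 20)
  X <- matrix(rnorm(n * p), n, p)
  X[site == "B", ] <- X[site == "B", ] + 1.5
  X[site == "C", ] <- X[site == "C", ] * 2
  Xa <- leaky_combat(X, site, eb = FALSE)
  for (s in c("B", "C"))
    expect_lt(max(abs(colMeans(Xa[site == s, ]) -
                        colMeans(Xa[site == "A", ]))), 1e-8)
  expect_lt(max(abs(colMeans(Xa) - colMeans(X))), 1e-8)
})

test_that("ComBat (eb off) is idempotent", {
  set.seed(9)
  site <- rep(c("A", "B"), c(14, 26))
  X <- matrix(rnorm(40 * 10), 40, 10)
  X[site == "B", ] <- 1.7 * X[site == "B", ] - 0.8
  once <- leaky_combat(X, site, eb = FALSE)
  twice <- leaky_combat(once, site, eb = FALSE)
  expect_lt(max(abs(twice - once)), 1e-8)
})

test_that("ComBat commutes with subject permutation; covariate regression too", {
  set.seed(10)
  n <- 30
  site <- rep(c("A", "B"), each = 15)
  X <- matrix(rnorm(n * 6), n, 6)
  C <- data.frame(age = rnorm(n))
  perm <- sample(n)
  expect_equal(leaky_combat(X, site, eb = FALSE)[perm, ],
               leaky_combat(X[perm, ], site[perm], eb = FALSE),
               tolerance = 1e-12)
  expect_equal(leaky_covariates(X, C)[perm, ],
               leaky_covariates(X[perm, ], C[perm, , drop = FALSE]),
               tolerance = 1e-12)
})

test_that("unseen test site is a named error; single-subject site refused at fit", {
  set.seed(11)
  X <- matrix(rnorm(40), 8, 5)
  m <- fit_combat(X, rep(c("A", "B"), each = 4), eb = FALSE)
  expect_error(apply_combat(m, X[1:2, ], c("A", "Z")), "Z")
  expect_error(fit_combat(X, c(rep("A", 7), "solo")), "solo")
})

test_that("empirical-Bayes shrinkage pulls site effects toward the prior mean", {
  set.seed(12)
  n_per <- 6; p <- 200
  site <- rep(c("A", "B"), each = n_per)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  X[site == "B", ] <- X[site == "B", ] + rnorm(p, 0.5, 0.8)[col(X[site == "B", ])]
  raw <- fit_combat(X, site, eb = FALSE)
  eb <- fit_combat(X, site, eb = TRUE)
  for (k in 1:2) {
    g_hat <- raw$gamma_star[k, ]
    g_eb <- eb$gamma_star[k, ]
    g_bar <- mean(g_hat)
    # every EB estimate lies between the raw estimate and the prior mean
    lo <- pmin(g_hat, g_bar) - 1e-8
    hi <- pmax(g_hat, g_bar) + 1e-8
    expect_true(all(g_eb >= lo & g_eb <= hi))
    # and is strictly shrunk on average
    expect_lt(mean(abs(g_eb - g_bar)), mean(abs(g_hat - g_bar)))
  }
})

test_that("leaky ComBat under null site effects is near-identity at large n", {
  set.seed(13)
  n <- 500; p <- 40
  X <- matrix(rnorm(n * p), n, p)
  site <- sample(rep(c("A", "B"), each = n / 2))
  Xa <- leaky_combat(X, site, eb = FALSE)
  expect_lt(max(abs(Xa - X)), 0.35)        # shrinks with n; loose sanity bound
  expect_lt(mean(abs(Xa - X)), 0.05)
})

test_that("full-data ComBat agrees with the sva reference implementation", {
  set.seed(14)
  n <- 100; p <- 60
  site <- rep(c("A", "B"), c(40, 60))
  X <- matrix(rnorm(n * p), n, p)
  X[site == "B", ] <- 1.3 * X[site == "B", ] + 0.7
  mine <- leaky_combat(X, site, eb = TRUE)
  ref <- t(suppressMessages(sva::ComBat(dat = t(X), batch = site)))
  # conventions differ only in O(1/n_site) variance divisors
  expect_gt(cor(as.numeric(mine), as.numeric(ref)), 0.999)
  expect_lt(mean(abs(mine - ref)), 0.03)
})
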