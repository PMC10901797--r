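test_that("select_features keeps floor(fraction*p) edges, minimum one", {
  set.seed(1)
  X <- matrix(rnorm(30 * 100), 30, 100)
  y <- rnorm(30)
  expect_length(select_features(X, y, 0.05), 5)
  expect_length(select_features(X, y, 0.001), 1)
  expect_length(select_features(X, y, 1), 100)
})

test_that("an edge duplicating the phenotype is always selected", {
  set.seed(2)
  X <- matrix(rnorm(20 * 50), 20, 50)
  y <- rnorm(20)
  X[, 37] <- y
  expect_true(37 %in% select_features(X, y, 0.05))
})

test_that("selection matches the exhaustive sort-all-|r| oracle", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(10:30, 1); p <- sample(20:60, 1)
    X <- matrix(rnorm(n * p), n, p)
    if (i %% 5 == 0) X[, sample(p, 2)] <- 1  # zero-variance columns
    y <- rnorm(n)
    frac <- runif(1, 0.05, 0.5)
    k <- max(1, floor(frac * p))
    r <- brute_cor(X, y)
    oracle <- sort(order(-abs(r), seq_len(p))[seq_len(k)])
    expect_identical(select_features(X, y, frac), oracle)
  }
})

test_that("zero-variance edges rank last; all-zero-variance falls back to first k", {
  X <- matrix(1, 10, 6)
  y <- rnorm(10)
  expect_identical(select_features(X, y, 0.5), 1:3)
  X[, 4] <- rnorm(10)
  expect_identical(select_features(X, y, 1 / 6), 4L)
})

test_that("selection is permutation-equivariant in subjects", {
  set.seed(4)
  X <- matrix(rnorm(25 * 40), 25, 40)
  y <- rnorm(25)
  perm <- sample(25)
  expect_identical(select_features(X, y, 0.2),
                   select_features(X[perm, ], y[perm], 0.2))
})

test_that("single-value grid reduces nested ridge to a direct fit", {
  set.seed(5)
  n <- 40; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  spec <- model_spec(alpha_grid = 1, feature_fraction = 1)
  m <- fit_ridge_nested(X, y, spec, seed = 1)
  expect_equal(m$chosen_alpha, 1)
  # independent oracle: augmented least squares solved by lm on centered data
  Xc <- scale(X, scale = FALSE)
  aug <- rbind(Xc, sqrt(1) * diag(p))
  fit <- lm.fit(aug, c(y - mean(y), rep(0, p)))
  expect_equal(unname(m$coefficients), unname(fit$coefficients),
               tolerance = 1e-8)
})

test_that("ridge interpolates an exactly linear phenotype at tiny penalty", {
  set.seed(6)
  n <- 50; p <- 40
  X <- matrix(rnorm(n * p), n, p)
  y <- 2 * X[, 7] - 1
  spec <- model_spec(alpha_grid = c(1e-8, 1), feature_fraction = 0.05)
  m <- fit_ridge_nested(X, y, spec, seed = 1)
  expect_lt(max(abs(predict(m, X) - y)), 1e-6)
})

test_that("nested alpha choice matches a brute-force inner-loop oracle", {
  set.seed(7)
  n <- 60; p <- 200
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(rnorm(10), rep(0, p - 10))
  y <- as.numeric(X %*% beta) + rnorm(n, 0, 2)
  spec <- model_spec(alpha_grid = 10^(-1:2), feature_fraction = 0.1)
  m <- fit_ridge_nested(X, y, spec, seed = 9)

  # independent re-implementation of the inner loop
  folds <- plain_kfold(n, spec$inner_k, seed = 9)
  preds <- matrix(NA_real_, n, length(spec$alpha_grid))
  for (f in folds) {
    tr <- setdiff(seq_len(n), f)
    r <- brute_cor(X[tr, ], y[tr])
    sel <- sort(order(-abs(r), seq_len(p))[1:20])
    for (ai in seq_along(spec$alpha_grid)) {
      a <- spec$alpha_grid[ai]
      Xtr <- X[tr, sel]; xm <- colMeans(Xtr); ym <- mean(y[tr])
      Xc <- sweep(Xtr, 2, xm)
      b <- solve(crossprod(Xc) + a * diag(20), crossprod(Xc, y[tr] - ym))
      preds[f, ai] <- sweep(X[f, sel], 2, xm) %*% b + ym
    }
  }
  r_grid <- apply(preds, 2, cor, y = y)
  oracle_alpha <- spec$alpha_grid[utils::tail(order(r_grid, spec$alpha_grid), 1)]
  expect_equal(m$chosen_alpha, oracle_alpha)
  expect_equal(unname(m$inner_r), unname(r_grid), tolerance = 1e-8)
})

test_that("ridge coefficient norm shrinks monotonically in the penalty", {
  set.seed(8)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- rnorm(30)
  norms <- sapply(10^(-2:4), function(a) {
    m <- fit_ridge_nested(X, y, model_spec(alpha_grid = a, feature_fraction = 1),
                          seed = 1)
    sqrt(sum(m$coefficients^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("ridge predictions match a hand-computed dot product", {
  m <- structure(list(kind = "ridge", selected_edges = c(1L, 3L),
                      coefficients = c(2, -1), intercept = 0.5, n_edges = 4),
                 class = c("ridge_model", "connectome_model"))
  X <- rbind(c(1, 9, 2, 9), c(0, 9, 1, 9), c(-1, 9, 0, 9))
  expect_equal(predict(m, X), c(1 * 2 - 2 + 0.5, -1 + 0.5, -2 + 0.5))
  expect_error(predict(m, X[, 1:3]), "expects")
})

test_that("fitted models never see test rows (sentinel)", {
  set.seed(9)
  n <- 50; p <- 60
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  tr <- 1:35
  spec <- model_spec(alpha_grid = c(0.1, 10), feature_fraction = 0.1)
  m1 <- fit_ridge_nested(X[tr, ], y[tr], spec, seed = 5)
  X2 <- X; X2[36:50, ] <- 999; y2 <- y; y2[36:50] <- -999
  m2 <- fit_ridge_nested(X2[tr, ], y2[tr], spec, seed = 5)
  expect_identical(m1, m2)
  c1 <- fit_cpm(X[tr, ], y[tr], spec)
  c2 <- fit_cpm(X2[tr, ], y2[tr], spec)
  expect_identical(c1, c2)
})

test_that("CPM with one positively correlated edge is simple regression", {
  set.seed(10)
  n <- 40
  X <- matrix(rnorm(n * 20), n, 20)
  y <- X[, 5] + rnorm(n, 0, 0.1)
  m <- fit_cpm(X, y, model_spec(kind = "cpm", feature_fraction = 0.05))
  expect_identical(m$selected_edges, 5L)
  expect_equal(unname(m$cpm_signs), 1)
  ols <- lm(y ~ X[, 5])
  expect_equal(m$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
  expect_equal(m$slope, unname(coef(ols)[2]), tolerance = 1e-10)
})

test_that("CPM recovers a sum-minus-sum construction", {
  set.seed(11)
  n <- 200; p <- 100
  X <- matrix(rnorm(n * p), n, p)
  pos <- 1:5; neg <- 6:10
  y <- rowSums(X[, pos]) - rowSums(X[, neg]) + rnorm(n, 0, 0.5)
  m <- fit_cpm(X, y, model_spec(kind = "cpm", feature_fraction = 0.1))
  expect_gt(cor(predict(m, X), y), 0.9)
  expect_true(all(m$cpm_signs[m$selected_edges %in% pos] == 1))
  expect_true(all(m$cpm_signs[m$selected_edges %in% neg] == -1))
})

test_that("CPM sign split ignores phenotype location; predictions match hand math", {
  set.seed(12)
  X <- matrix(rnorm(30 * 12), 30, 12)
  y <- rnorm(30)
  spec <- model_spec(kind = "cpm", feature_fraction = 0.25)
  m1 <- fit_cpm(X, y, spec)
  m2 <- fit_cpm(X, y + 100, spec)
  expect_identical(m1$cpm_signs, m2$cpm_signs)
  expect_identical(m1$selected_edges, m2$selected_edges)

  # 4-subject hand example: score = x1 - x2, line y = 1 + 2*score
  m <- structure(list(kind = "cpm", selected_edges = c(1L, 2L),
                      cpm_signs = c(1, -1), slope = 2, intercept = 1,
                      n_edges = 3),
                 class = c("cpm_model", "connectome_model"))
  Xh <- rbind(c(1, 0, 5), c(0, 1, 5), c(2, 2, 5), c(-1, 1, 5))
  expect_equal(predict(m, Xh), 1 + 2 * c(1, -1, 0, -2))
  # constant input gives a constant prediction
  expect_equal(predict(m, rbind(c(3, 3, 0), c(3, 3, 9))), rep(1, 2))
})

test_that("CPM errors on a zero-variance summary score", {
  expect_error(fit_cpm(matrix(1, 10, 4), rnorm(10),
                       model_spec(kind = "cpm", feature_fraction = 0.5)),
               "zero variance")
})

test_that("coef embeds fold coefficients into the full edge space", {
  set.seed(13)
  X <- matrix(rnorm(40 * 30), 40, 30)
  y <- rnorm(40)
  m <- fit_ridge_nested(X, y, model_spec(alpha_grid = 1, feature_fraction = 0.1),
                        seed = 2)
  full <- coef(m)
  expect_length(full, 30)
  expect_equal(full[m$selected_edges], m$coefficients)
  expect_true(all(full[-m$selected_edges] == 0))

  cm <- fit_cpm(X, y, model_spec(kind = "cpm", feature_fraction = 0.1))
  fc <- coef(cm)
  expect_equal(fc[cm$selected_edges], cm$cpm_signs * cm$slope)
})

test_that("SVR conforms to the common fit/predict contract", {
  set.seed(14)
  n <- 60; p <- 40
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 1] + rnorm(n, 0, 0.3)
  spec <- model_spec(kind = "svr", c_grid = c(0.1, 1, 10),
                     feature_fraction = 0.1)
  m <- fit_model(X, y, spec, seed = 1)
  expect_s3_class(m, "svr_model")
  expect_true(m$chosen_alpha %in% spec$c_grid)
  expect_length(predict(m, X), n)
  expect_gt(cor(predict(m, X), y), 0.5)
  expect_true(all(is.na(coef(m))))
})
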