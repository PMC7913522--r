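test_that("feature extraction obeys shape, determinism, scaler semantics", {
  ds <- toy_dataset(n_groups = 5, per_group = 2, side = 64, seed = 3)
  net <- tiny_fusion(widths = c(8L, 16L))
  fm <- extract_features(net, ds)
  expect_equal(dim(fm$rows), c(10L, 24L))
  expect_identical(fm$ids, dataset_ids(ds))
  expect_identical(extract_features(net, ds)$rows, fm$rows)
  # train rows scaled by their own scaler span [0,1]
  sc <- mriqa:::apply_minmax_scaler(fm$scaler, fm$rows)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(unname(apply(sc, 2, min)), rep(0, 24))
  # a disjoint set scaled with the train scaler may leave [0,1]
  ds2 <- toy_dataset(n_groups = 5, per_group = 2, side = 64, seed = 99)
  fm2 <- extract_features(net, ds2, scaler = fm$scaler)
  sc2 <- mriqa:::apply_minmax_scaler(fm2$scaler, fm2$rows)
  expect_true(any(sc2 < 0 | sc2 > 1))
})

test_that("the RBF kernel matches its closed form", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 3), 1)
  expect_equal(rbf_kernel(0, 1, 1), exp(-1), tolerance = 1e-12)
  v <- rbf_kernel(c(0, 0), c(1, 1), c(0.1))
  expect_equal(v, exp(-0.2), tolerance = 1e-12)
  # monotone decay to 0 with gamma for distinct points
  g <- c(0.1, 1, 10, 100)
  vals <- vapply(g, function(gg) rbf_kernel(0, 0.5, gg), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[4], 1e-10)
  expect_error(rbf_kernel(1:2, 1:3, 1), "equal length")
  expect_error(rbf_kernel(1, 2, 0), "gamma")
})

test_that("constant targets give the bias-only solution", {
  set.seed(4)
  X <- matrix(runif(30), 10, 3)
  m <- svr_fit(X, rep(3, 10), C = 2, gamma = 0.5, epsilon = 0.1)
  expect_equal(m$coefficients, rep(0, 10))
  expect_equal(m$bias, 3, tolerance = 1e-9)
  expect_equal(svr_predict(m, X), rep(3, 10), tolerance = 1e-9)
})

test_that("the interpolation regime reproduces a smooth 1-D function", {
  x <- matrix(seq(0, 1, length.out = 5), ncol = 1)
  q <- sin(2 * x[, 1]) + 2.5
  m <- svr_fit(x, q, C = 2^10, gamma = 2, epsilon = 0, scale = FALSE)
  expect_lt(max(abs(svr_predict(m, x) - q)), 1e-3)
})

test_that("dual feasibility holds for arbitrary fits", {
  set.seed(9)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    X <- matrix(rnorm(n * 4), n, 4)
    q <- runif(n, 1, 5)
    C <- sample(c(0.5, 2, 16), 1)
    m <- svr_fit(X, q, C = C, gamma = 0.3, epsilon = 0.1)
    expect_lt(abs(sum(m$coefficients)), 1e-8)
    expect_lte(max(abs(m$coefficients)), C + 1e-8)
    # points strictly inside the tube (clear of the boundary by more than
    # solver precision) carry no weight
    resid <- abs(svr_predict(m, X) - q)
    inside <- resid < m$epsilon - 1e-4
    expect_true(all(abs(m$coefficients[inside]) < 1e-6))
  }
})

test_that("prediction batches consistently and checks dimensions", {
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  q <- 3 + X[, 1] - 0.5 * X[, 2] + rnorm(20, sd = 0.05)
  q <- pmin(pmax(q, 1), 5)
  m <- svr_fit(X, q, C = 4, gamma = 1, epsilon = 0.05)
  two <- svr_predict(m, X[1:2, ])
  expect_equal(two, c(svr_predict(m, X[1, ]), svr_predict(m, X[2, ])))
  expect_error(svr_predict(m, matrix(0, 1, 5)), "dimension mismatch")
  # all-zero coefficients predict the bias everywhere
  m0 <- m; m0$coefficients[] <- 0
  expect_equal(svr_predict(m0, X)[1:3],
               rep(m0$bias, 3) + as.numeric(
                 mriqa:::rbf_cross(
                   mriqa:::apply_minmax_scaler(m0$scaler, X[1:3, ]),
                   m0$support_vectors, m0$gamma) %*%
                 m0$coefficients[m0$support_index]))
})

test_that("fits are invariant to permuting the training rows", {
  set.seed(6)
  X <- matrix(rnorm(60), 20, 3)
  q <- pmin(pmax(3 + X[, 1], 1), 5)
  m1 <- svr_fit(X, q, C = 8, gamma = 0.5, epsilon = 0.1, tolerance = 1e-10)
  perm <- sample(20)
  m2 <- svr_fit(X[perm, ], q[perm], C = 8, gamma = 0.5, epsilon = 0.1,
                tolerance = 1e-10)
  Xnew <- matrix(rnorm(15), 5, 3)
  expect_equal(svr_predict(m1, Xnew), svr_predict(m2, Xnew),
               tolerance = 1e-10)
})

test_that("hyperparameter selection follows grid and tie-break contracts", {
  set.seed(7)
  X <- matrix(runif(80), 40, 2)
  q <- pmin(pmax(2 + 2 * X[, 1], 1), 5)
  single <- list(C = 2, gamma = 0.5, epsilon = 0.1)
  hp <- select_hyperparams(X, q, grid = single, folds = 4, seed = 1)
  expect_equal(hp[c("C", "gamma", "epsilon")],
               list(C = 2, gamma = 0.5, epsilon = 0.1))
  # constant targets score every grid point identically: smallest C, then
  # smallest gamma, wins the tie-break
  hp2 <- select_hyperparams(X, rep(3, 40),
                            grid = list(C = c(1, 4, 16), gamma = c(0.25, 2),
                                        epsilon = 0.01),
                            folds = 4, seed = 1)
  expect_equal(hp2$C, 1)
  expect_equal(hp2$gamma, 0.25)
  expect_error(select_hyperparams(X[1:3, ], q[1:3], folds = 5), "folds")
})

test_that("the selected gamma tracks the generating kernel width", {
  set.seed(8)
  X <- matrix(runif(120), 60, 2)
  gamma_star <- 2^1
  t_true <- rnorm(60)
  t_true <- t_true - mean(t_true)
  K <- mriqa:::rbf_cross(X, X, gamma_star)
  f <- as.numeric(K %*% t_true)
  q <- 3 + 1.5 * (f - mean(f)) / sd(f)
  grid <- list(C = 2^c(1, 5), gamma = 2^seq(-7, 3, by = 2), epsilon = 0.01)
  hp <- select_hyperparams(X, q, grid = grid, folds = 5, seed = 2)
  expect_lte(abs(log2(hp$gamma) - log2(gamma_star)), 2)
})

test_that("SVR models survive the archive round trip", {
  set.seed(10)
  X <- matrix(rnorm(40), 20, 2)
  q <- pmin(pmax(3 + X[, 1], 1), 5)
  m <- svr_fit(X, q, C = 4, gamma = 1, epsilon = 0.1)
  d <- withr::local_tempdir()
  save_svr_model(m, file.path(d, "m.json"))
  back <- load_svr_model(file.path(d, "m.json"))
  Xnew <- matrix(rnorm(10), 5, 2)
  expect_equal(svr_predict(back, Xnew), svr_predict(m, Xnew),
               tolerance = 1e-12)
})

test_that("SVR predictions agree with the library's own predictor", {
  # our kernel-expansion evaluation vs the solver's internal predict
  set.seed(11)
  X <- matrix(rnorm(90), 30, 3)
  q <- pmin(pmax(3 + X[, 1] - X[, 2], 1), 5)
  rows <- mriqa:::apply_minmax_scaler(mriqa:::fit_minmax_scaler(X), X)
  fit <- e1071::svm(rows, q, type = "eps-regression", kernel = "radial",
                    cost = 4, gamma = 0.8, epsilon = 0.1, scale = FALSE,
                    tolerance = 1e-7)
  m <- svr_fit(X, q, C = 4, gamma = 0.8, epsilon = 0.1)
  expect_equal(svr_predict(m, X), unname(predict(fit, rows)),
               tolerance = 1e-10)
})
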