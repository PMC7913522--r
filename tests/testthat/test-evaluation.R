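test_that("rank correlations match their worked examples", {
  expect_equal(srcc(1:10, 1:10), 1)
  expect_equal(srcc(1:10, 10:1), -1)
  expect_equal(srcc(c(1, 2, 3, 4, 5), c(1, 2, 3, 5, 4)), 0.9)
  expect_equal(krcc(1:6, 1:6), 1)
  expect_equal(krcc(1:6, 6:1), -1)
  expect_equal(krcc(c(1, 2, 3, 4), c(1, 2, 4, 3)), 2 / 3)
  expect_error(srcc(1:4, 1:5), "equal length")
  expect_error(krcc(1:4, 1:5), "equal length")
  expect_error(srcc(rep(1, 5), 1:5), "constant")
})

test_that("rank correlations agree with brute-force oracles", {
  # oracle 1: rank both vectors, apply the closed-form rank-difference sum
  srcc_oracle <- function(x, y) {
    d <- rank(x) - rank(y); m <- length(x)
    1 - 6 * sum(d^2) / (m * (m^2 - 1))
  }
  # oracle 2: enumerate all pairs and count concordances explicitly
  krcc_oracle <- function(x, y) {
    m <- length(x); mc <- 0L; md <- 0L
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) mc <- mc + 1L else if (s < 0) md <- md + 1L
    }
    (mc - md) / (0.5 * m * (m - 1))
  }
  set.seed(123)
  for (k in 1:200) {
    m <- sample(3:30, 1)
    x <- sample(seq_len(1000), m)  # tie-free
    y <- sample(seq_len(1000), m)
    expect_lt(abs(srcc(x, y) - srcc_oracle(x, y)), 1e-12)
    expect_lt(abs(krcc(x, y) - krcc_oracle(x, y)), 1e-12)
  }
})

test_that("rank correlations are invariant under monotone transforms", {
  set.seed(31)
  x <- runif(25); y <- runif(25)
  expect_equal(srcc(exp(3 * x), y), srcc(x, y))
  expect_equal(krcc(x, y^3 + 2 * y), krcc(x, y))
  perm <- sample(25)
  expect_equal(srcc(x[perm], y[perm]), srcc(x, y))
  expect_equal(krcc(x[perm], y[perm]), krcc(x, y))
})

test_that("ties fall back to the documented generalizations", {
  x <- c(1, 1, 2, 3); y <- c(1, 2, 2, 3)
  expect_equal(srcc(x, y), cor(rank(x), rank(y)))
  # tau-a: tied pairs count as neither concordant nor discordant
  expect_equal(krcc(x, y), (4 - 0) / 6)
})

test_that("PLCC and RMSE match their closed forms", {
  expect_equal(plcc(c(1, 2, 3), c(1, 2, 3)), 1)
  x <- c(1, 2, 5); expect_equal(plcc(x, -x), -1)
  expect_equal(plcc(c(1, 2, 3), c(1, 2, 4)), 0.981981, tolerance = 1e-5)
  expect_error(plcc(rep(2, 4), 1:4), "constant")
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 2), c(3, 4)), 2)
  expect_equal(rmse(1.5, 4), 2.5)
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("the logistic mapping recovers representable relations", {
  set.seed(41)
  qo <- runif(40, 1, 5)
  # identity data: fallback-or-fit must reproduce qs exactly
  fit_id <- fit_logistic_mapping(qo, qo)
  expect_lte(sum((apply_mapping(fit_id, qo) - qo)^2), 1e-8)
  # data generated by known parameters through the mapping
  beta_star <- c(2, 1.5, 3, 0.5, 0.3)
  qs <- apply_mapping(beta_star, qo)
  fit <- fit_logistic_mapping(qo, qs)
  expect_lte(sum((apply_mapping(fit, qo) - qs)^2), 1e-6)
  # affine relations live in the family via beta4, beta5
  fit_lin <- fit_logistic_mapping(qo, 2 * qo + 1)
  expect_lte(sum((apply_mapping(fit_lin, qo) - (2 * qo + 1))^2), 1e-6)
  expect_error(fit_logistic_mapping(rep(1, 10), runif(10)), "constant")
})

test_that("mapping evaluation honours its parameters", {
  qo <- c(-1, 0, 2, 4)
  expect_equal(apply_mapping(c(0, 1, 0, 1, 0), qo), qo)
  expect_equal(apply_mapping(c(0, 1, 0, 0, 5), qo), rep(5, 4))
  expect_equal(apply_mapping(c(2, 1, 0, 0, 0), 0), 0)
  expect_error(apply_mapping(c(1, 2, 3), qo), "five")
})

test_that("the fitted mapping never lowers PLCC when it converges", {
  set.seed(51)
  for (k in 1:10) {
    qo <- runif(30, 0, 3)
    qs <- pmin(pmax(1 + qo + rnorm(30, sd = 0.4), 1), 5)
    fit <- fit_logistic_mapping(qo, qs)
    expect_gte(plcc(apply_mapping(fit, qo), qs), plcc(qo, qs) - 1e-9)
  }
})

test_that("grouped splits are disjoint, sized by rounding, reproducible", {
  ds <- toy_dataset(n_groups = 30, per_group = 2, seed = 61)
  sp <- group_split(ds, 0.8, seed = 1)
  expect_length(dataset_groups(sp$train), 24)
  expect_length(dataset_groups(sp$test), 6)
  expect_length(intersect(dataset_groups(sp$train),
                          dataset_groups(sp$test)), 0)
  expect_identical(dataset_ids(group_split(ds, 0.8, seed = 1)$train),
                   dataset_ids(sp$train))
  diffs <- vapply(1:20, function(s) !identical(
    dataset_ids(group_split(ds, 0.8, seed = s)$train),
    dataset_ids(sp$train)), logical(1))
  expect_true(any(diffs))

  ds2 <- toy_dataset(n_groups = 2, per_group = 3, seed = 62)
  sp2 <- group_split(ds2, 0.5, seed = 3)
  expect_length(dataset_groups(sp2$train), 1)
  expect_length(dataset_groups(sp2$test), 1)
  expect_error(group_split(ds2, 0.05, seed = 1), "empty side")
})

test_that("the protocol is exact for an oracle and null for noise", {
  ds <- toy_dataset(n_groups = 10, per_group = 4, seed = 71)
  oracle <- function(train, test, seed) unname(dataset_mos(test))
  res <- run_protocol(ds, n_iterations = 10, seed = 3, predictor = oracle)
  expect_equal(nrow(res$per_iteration), 10)
  expect_equal(unname(res$medians),
               c(1, 1, 1, 0), tolerance = 1e-9)

  noise <- function(train, test, seed)
    mriqa:::with_seed(seed, runif(length(test), 1, 5))
  res2 <- run_protocol(ds, n_iterations = 10, seed = 4, predictor = noise)
  expect_lt(abs(res2$medians[["srcc"]]), 0.3)
})

test_that("cross-database evaluation surfaces degenerate predictions", {
  ds1 <- toy_dataset(n_groups = 4, per_group = 3, seed = 81, name = "A")
  ds2 <- toy_dataset(n_groups = 4, per_group = 3, seed = 82, name = "B")
  oracle <- function(train, test, seed) unname(dataset_mos(test))
  res <- cross_database(ds1, ds2, predictor = oracle)
  expect_equal(res$medians[["srcc"]], 1)
  expect_equal(res$n_iterations, 1)
  constant <- function(train, test, seed) rep(3, length(test))
  expect_error(cross_database(ds1, ds2, predictor = constant), "degenerate")
})

test_that("the significance matrix scores clearly separated methods", {
  a <- seq(0.90, 0.95, length.out = 10)
  b <- seq(0.10, 0.15, length.out = 10)
  sm <- wilcoxon_score_matrix(list(good = a, bad = b, good2 = a))
  expect_equal(sm$scores["good", "bad"], 1L)
  expect_equal(sm$scores["bad", "good"], -1L)
  expect_equal(sm$scores["good", "good2"], 0L)
  expect_equal(unname(sm$row_sums), c(1, -2, 1))
  # rank-sum oracle at alpha = 0.05, one-sided
  p <- stats::wilcox.test(a, b, alternative = "greater", exact = FALSE)$p.value
  expect_lt(p, 0.05)
})

test_that("significance matrices are antisymmetric with zero diagonal", {
  set.seed(91)
  samples <- replicate(5, runif(8, -1, 1), simplify = FALSE)
  names(samples) <- paste0("m", 1:5)
  sm <- wilcoxon_score_matrix(samples)
  expect_true(all(diag(sm$scores) == 0))
  expect_identical(sm$scores, -t(sm$scores))
  expect_error(wilcoxon_score_matrix(samples[1]), "at least 2")
  expect_error(wilcoxon_score_matrix(list(a = 1:5, b = 1:2)), "at least 3")
})

test_that("evaluation reports round-trip through their writers", {
  ds <- toy_dataset(n_groups = 6, per_group = 6, seed = 95)
  oracle <- function(train, test, seed) unname(dataset_mos(test))
  res <- run_protocol(ds, n_iterations = 3, seed = 5, predictor = oracle)
  d <- withr::local_tempdir()
  write_eval_csv(res, file.path(d, "r.csv"), method = "oracle")
  tab <- read.csv(file.path(d, "r.csv"))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$srcc, res$per_iteration$srcc)
  write_eval_json(res, file.path(d, "r.json"))
  js <- jsonlite::read_json(file.path(d, "r.json"))
  expect_equal(js$medians$srcc, 1)
  sm <- wilcoxon_score_matrix(list(a = runif(5), b = runif(5)))
  write_significance_csv(sm, file.path(d, "s.csv"))
  expect_true(file.exists(file.path(d, "s.csv")))
})
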