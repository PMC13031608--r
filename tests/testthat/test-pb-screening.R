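test_that("generated designs are balanced and pairwise orthogonal", {
  for (n_runs in c(8, 12, 16, 20, 24)) {
    d <- pb_design(n_runs - 1, n_runs)
    m <- unclass(d)
    expect_true(all(m %in% c(-1, 1)))
    expect_equal(colSums(m), setNames(rep(0, ncol(m)), colnames(m)))
    # brute-force orthogonality: explicit elementwise products
    for (i in seq_len(ncol(m) - 1))
      for (j in (i + 1):ncol(m))
        expect_equal(sum(m[, i] * m[, j]), 0)
  }
  # 20-run, 13-factor case: exactly one all-minus row
  d20 <- unclass(pb_design(13, 20))
  expect_equal(dim(d20), c(20, 13))
  expect_equal(sum(apply(d20, 1, function(r) all(r == -1))), 1)
})

test_that("unsupported design requests error", {
  expect_error(pb_design(5, 10), "unsupported n_runs")
  expect_error(pb_design(20, 20), "n_factors must be")
})

test_that("split-sum effects behave on null and single-column signals", {
  d <- pb_design(13, 20)
  expect_equal(unname(pb_effects(d, rep(7, 20))), rep(0, 13))
  y <- unclass(d)[, 1]
  e <- pb_effects(d, y)
  expect_equal(unname(e[1]), 1)
  expect_equal(unname(e[-1]), rep(0, 12))
  expect_error(pb_effects(d, 1:5), "response length")
})

test_that("fixture effects match an independent split-sum computation", {
  runs <- load_fixture("pb_runs")
  m <- as.matrix(table_settings(runs))
  y <- runs$response
  # independent oracle: explicit per-level sums, no matrix algebra
  oracle <- vapply(seq_len(ncol(m)), function(i) {
    (sum(y[m[, i] == 1]) - sum(y[m[, i] == -1])) / length(y)
  }, numeric(1))
  expect_equal(unname(pb_effects(m, y)), oracle, tolerance = 1e-12)
})

test_that("first-order fit recovers a noiseless linear model exactly", {
  d <- pb_design(9, 12)
  set.seed(3)
  b <- rnorm(9)
  y <- 5 + unclass(d) %*% b
  fit <- pb_screen(d, drop(y))
  expect_equal(unname(fit$coefficients), b, tolerance = 1e-10)
  expect_equal(fit$intercept, 5, tolerance = 1e-10)
})

test_that("on balanced designs OLS slope equals the split-sum effect and
           the intercept equals the grand mean", {
  set.seed(4)
  for (n_runs in c(12, 20)) {
    d <- pb_design(n_runs - 3, n_runs)
    y <- runif(n_runs, 10, 80)
    fit <- pb_screen(d, y)
    expect_equal(fit$coefficients, pb_effects(d, y), tolerance = 1e-10)
    expect_equal(fit$intercept, mean(y), tolerance = 1e-10)
    expect_equal(fit$effect_diff_means, 2 * fit$effects)
    expect_equal(fit$residual_df, n_runs - (n_runs - 3) - 1)
  }
})

test_that("screening is invariant to run order and response rescaling", {
  d <- unclass(pb_design(13, 20))
  set.seed(5)
  y <- runif(20, 10, 80)
  fit <- pb_screen(d, y)
  perm <- sample(20)
  fit_p <- pb_screen(d[perm, ], y[perm])
  expect_equal(fit_p$coefficients, fit$coefficients)
  expect_equal(fit_p$t_value, fit$t_value)
  expect_equal(fit_p$p_value, fit$p_value)
  # affine rescaling of the response leaves t and p unchanged
  fit_s <- pb_screen(d, 3.7 * y + 11)
  expect_equal(fit_s$t_value, fit$t_value, tolerance = 1e-10)
  expect_equal(fit_s$p_value, fit$p_value, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected", {
  d <- unclass(pb_design(3, 8))
  d[, 3] <- d[, 1]
  expect_error(pb_screen(d, rnorm(8)), "rank deficient")
  expect_error(pb_screen(unclass(pb_design(7, 8)), rnorm(8)),
               "runs > factors")
})

test_that("significance selection reproduces the published factor set", {
  printed <- printed_screening()
  expect_equal(select_significant(printed, 0.05),
               c("ZmPAL", "GmCHS", "MsCHR", "pH", "volume"))
  expect_equal(select_significant(printed, 0), character(0))
  expect_equal(select_significant(printed, 1.0000001),
               factor_names(load_fixture("pb_factors")))
  # refit from the raw design agrees on the significant set
  runs <- load_fixture("pb_runs")
  fit <- pb_screen(as.matrix(table_settings(runs)), runs$response)
  expect_equal(select_significant(fit, 0.05),
               select_significant(printed, 0.05))
})

test_that("first-order prediction is the affine form it claims", {
  runs <- load_fixture("pb_runs")
  fit <- pb_screen(as.matrix(table_settings(runs)), runs$response)
  k <- length(fit$coefficients)
  expect_equal(predict(fit, rep(0, k)), fit$intercept)
  set.seed(6)
  a <- runif(k, -1, 1); b <- runif(k, -1, 1)
  expect_equal(predict(fit, a) + predict(fit, b) - fit$intercept,
               predict(fit, a + b), tolerance = 1e-10)
  # independent dot-product oracle on 50 random points
  X <- matrix(runif(50 * k, -2, 2), 50)
  manual <- apply(X, 1, function(r) fit$intercept +
                    sum(r * fit$coefficients))
  expect_equal(unname(predict(fit, X)), manual, tolerance = 1e-12)
  expect_error(predict(fit, rep(0, k - 1)), "length")
})
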