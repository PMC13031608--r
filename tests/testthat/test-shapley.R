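test_that("exact attribution satisfies the linearity and dummy axioms", {
  set.seed(41)
  a <- c(3, -2, 0, 1.5)          # feature 3 is ignored by the model
  f <- function(X) 7 + as.matrix(X) %*% a
  bg <- matrix(rnorm(40), 10, 4)
  x <- c(1, 2, 3, -1)
  res <- shapley_exact(f, x, bg)
  # additive model: phi_i = a_i * (x_i - mean background_i)
  expect_equal(unname(res$contributions),
               a * (x - colMeans(bg)), tolerance = 1e-10)
  expect_equal(unname(res$contributions[3]), 0)
  # efficiency: base + sum(phi) = prediction, exactly
  expect_equal(res$base + sum(res$contributions), as.numeric(f(rbind(x))),
               tolerance = 1e-12)
  expect_equal(res$base, mean(f(bg)), tolerance = 1e-12)
  expect_error(shapley_exact(f, rep(0, 13), matrix(0, 2, 13)), "> 12")
})

test_that("exact attribution handles interactions consistently", {
  f <- function(X) X[, 1] * X[, 2] + 2 * X[, 1]
  bg <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  x <- c(1, 1)
  res <- shapley_exact(f, x, bg)
  expect_equal(res$base + sum(res$contributions), 3, tolerance = 1e-12)
  # symmetric construction: interchangeable features in f(X)=x1*x2 share
  g <- function(X) X[, 1] * X[, 2]
  rs <- shapley_exact(g, c(2, 2), matrix(c(0, 1, 0, 1), 2, 2))
  expect_equal(unname(rs$contributions[1]), unname(rs$contributions[2]),
               tolerance = 1e-12)
})

test_that("sampled attribution is seeded, symmetric and convergent", {
  set.seed(42)
  a <- c(2, -3, 1, 0.5, 2)       # features 1 and 5 play identical roles
  f <- function(X) as.matrix(X) %*% a + 0.5 * X[, 2] * X[, 3]
  bg <- matrix(rnorm(25), 5, 5)
  bg[, 5] <- bg[, 1]             # symmetry needs identical backgrounds too
  x <- c(1.2, -0.7, 0.4, 2, 1.2)
  s1 <- shapley_sampled(f, x, bg, n_permutations = 200, seed = 3)
  s2 <- shapley_sampled(f, x, bg, n_permutations = 200, seed = 3)
  expect_identical(s1, s2)
  ex <- shapley_exact(f, x, bg)
  # convergence toward enumeration across increasing budgets
  budgets <- c(20, 200, 2000)
  devs <- vapply(budgets, function(np) {
    s <- shapley_sampled(f, x, bg, n_permutations = np, seed = 11)
    max(abs(s$contributions - ex$contributions))
  }, numeric(1))
  expect_lt(devs[3], devs[1] + 1e-12)
  rng <- diff(range(f(rbind(bg, x))))
  expect_lt(devs[3], 0.02 * rng)
  # symmetric features agree within Monte-Carlo tolerance
  s <- shapley_sampled(f, x, bg, n_permutations = 2000, seed = 11)
  expect_lt(abs(s$contributions[1] - s$contributions[5]),
            4 * (s$mc_se[1] + s$mc_se[5]) + 1e-6)
  expect_error(shapley_sampled(f, x, bg[0, , drop = FALSE], 10), "empty")
})

test_that("the summary ranks a configured dominant factor first", {
  sp <- default_bounds_space()
  cfg <- oracle_config(
    curvature = c(ZmPAL = -90, At4CL4 = -5, GmCHS = -5, MsCHR = -5,
                  ZmCHI = -5, CoA = -5, ATP = -5, NADPH = -5,
                  tyrosine = -5, pH = -5, temperature = -5, time = -5,
                  volume = -5),
    interactions = matrix(0, 13, 13,
                          dimnames = list(factor_names(sp),
                                          factor_names(sp))),
    inhibition = list(), noise_sd = 0, noise_cv = 0)
  f <- function(X) oracle_truth(cfg, to_natural(sp, as.matrix(X)))
  set.seed(43)
  inst <- matrix(runif(8 * 13, -0.8, 0.8), 8, 13,
                 dimnames = list(NULL, factor_names(sp)))
  bg <- matrix(runif(6 * 13, -0.8, 0.8), 6, 13,
               dimnames = list(NULL, factor_names(sp)))
  res <- lapply(seq_len(nrow(inst)), function(i)
    shapley_sampled(f, inst[i, ], bg, n_permutations = 300, seed = i))
  summ <- shapley_summary(res, inst)
  expect_equal(summ$feature[summ$rank == 1], "ZmPAL")
  # ranking unchanged when the input feature order is permuted
  perm <- sample(13)
  res_p <- lapply(seq_len(nrow(inst)), function(i)
    shapley_sampled(function(X) f(X[, order(perm), drop = FALSE]),
                    inst[i, perm], bg[, perm, drop = FALSE],
                    n_permutations = 300, seed = i))
  summ_p <- shapley_summary(res_p, inst[, perm, drop = FALSE])
  expect_equal(summ_p$feature[summ_p$rank == 1], "ZmPAL")
})

test_that("degenerate attributions summarize as ties with NA association", {
  zero <- lapply(1:3, function(i)
    structure(list(base = 5, contributions = c(a = 0, b = 0),
                   prediction = 5, method = "exact"),
              class = "attribution"))
  fv <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("a", "b")))
  summ <- shapley_summary(zero, fv)
  expect_equal(summ$rank, c(1, 1))
  expect_true(all(is.na(summ$sign_association)))
})

test_that("waterfall sequences accumulate from base to prediction", {
  res <- structure(list(base = 10, contributions = c(u = 2, v = -1),
                        prediction = 11, method = "exact"),
                   class = "attribution")
  wf <- waterfall_data(res)
  expect_equal(wf$feature, c("u", "v"))
  expect_equal(wf$cumulative, c(12, 11))
  expect_equal(tail(wf$cumulative, 1), res$prediction)
  one <- structure(list(base = 3, contributions = c(z = 4), prediction = 7,
                        method = "exact"), class = "attribution")
  expect_equal(waterfall_data(one)$cumulative, 7)
  # additivity oracle on 50 random instances of a linear model
  set.seed(44)
  a <- rnorm(4)
  f <- function(X) as.matrix(X) %*% a
  bg <- matrix(rnorm(20), 5, 4)
  for (i in 1:50) {
    x <- rnorm(4)
    r <- shapley_exact(f, x, bg)
    expect_equal(tail(waterfall_data(r)$cumulative, 1), as.numeric(f(rbind(x))),
                 tolerance = 1e-9)
  }
})
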