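test_that("default fold counts are 9 outer / 3 inner", {
  f <- formals(nested_cv)
  expect_equal(f$outer_folds, 9)
  expect_equal(f$inner_folds, 3)
})

test_that("a realizable linear truth scores perfect test correlation", {
  tab <- linear_table(27, b = c(3, -2, 1), noise = 0)
  rep <- nested_cv(tab, unit_space(3), linear_registry(),
                   outer_folds = 9, inner_folds = 3, seed = 1)
  expect_equal(rep$models$linear$mean_correlation, 1, tolerance = 1e-6)
  expect_equal(rep$selected, "linear")
})

test_that("outer scores equal an independently coded double loop", {
  tab <- linear_table(24, b = c(2, -1), noise = 3, seed = 7)
  sp <- unit_space(2)
  reg <- linear_registry()
  rep <- nested_cv(tab, sp, reg, outer_folds = 6, inner_folds = 3,
                   seed = 42)
  # manual re-implementation over the same deterministic fold indices
  X <- to_coded(sp, table_settings(tab)); y <- tab$response
  set.seed(42); ord <- sample.int(24)
  folds <- split(ord, cut(seq_len(24), 6, labels = FALSE))
  manual <- vapply(folds, function(idx) {
    tr <- setdiff(seq_len(24), idx)
    cf <- stats::lm.fit(cbind(1, X[tr, , drop = FALSE]), y[tr])$coefficients
    pred <- drop(cbind(1, X[idx, , drop = FALSE]) %*% cf)
    stats::cor(y[idx], pred)
  }, numeric(1))
  expect_equal(rep$models$linear$fold_correlation, unname(manual),
               tolerance = 1e-10)
  expect_equal(rep$models$linear$mean_correlation, mean(manual),
               tolerance = 1e-10)
})

test_that("held-out responses cannot influence hyperparameter choice", {
  tab <- linear_table(18, b = c(4, -3), noise = 2, seed = 9)
  sp <- unit_space(2)
  reg <- model_registry(c("random-forest", "gaussian-process"))
  rep1 <- nested_cv(tab, sp, reg, outer_folds = 3, inner_folds = 3,
                    seed = 5)
  # corrupt exactly the rows of outer fold 1 and re-run
  set.seed(5); ord <- sample.int(18)
  fold1 <- split(ord, cut(seq_len(18), 3, labels = FALSE))[[1]]
  tab2 <- tab
  tab2$response[fold1] <- rev(tab2$response[fold1]) + 25
  rep2 <- nested_cv(tab2, sp, reg, outer_folds = 3, inner_folds = 3,
                    seed = 5)
  for (id in names(reg))
    expect_identical(rep1$models[[id]]$chosen_params[[1]],
                     rep2$models[[id]]$chosen_params[[1]])
})

test_that("reports are bit-identical given the same seed and data", {
  tab <- linear_table(18, b = c(1, 2), noise = 4, seed = 13)
  sp <- unit_space(2)
  reg <- model_registry(c("random-forest", "multilayer-perceptron",
                          "gradient-boosted-trees-A"))
  r1 <- nested_cv(tab, sp, reg, outer_folds = 3, inner_folds = 2, seed = 8)
  r2 <- nested_cv(tab, sp, reg, outer_folds = 3, inner_folds = 2, seed = 8)
  expect_identical(r1, r2)
})

test_that("model selection is the argmax of mean test correlation", {
  fake <- function(scores) {
    structure(list(models = lapply(scores, function(s)
      list(mean_correlation = s))), class = "cv_report")
  }
  expect_equal(select_best(fake(list(only = 0.4))), "only")
  expect_equal(select_best(fake(list(a = 0.7, b = 0.9))), "b")
  set.seed(31)
  scores <- as.list(runif(7, -1, 1))
  names(scores) <- paste0("m", 1:7)
  rep <- fake(scores)
  expect_equal(select_best(rep),
               names(scores)[which.max(unlist(scores))])
  # tie goes to the first in registry order
  expect_equal(select_best(fake(list(a = 0.5, b = 0.5))), "a")
})

test_that("input validation catches short or incomplete data", {
  tab <- linear_table(5, b = 1)
  expect_error(nested_cv(tab, unit_space(1), linear_registry(),
                         outer_folds = 9), "at least outer_folds")
  tab2 <- linear_table(12, b = 1)
  tab2$response[3] <- NA
  expect_error(nested_cv(tab2, unit_space(1), linear_registry(),
                         outer_folds = 3), "responses")
})

test_that("the full surrogate stack predicts and reports uncertainty", {
  tab <- linear_table(24, b = c(5, -3), b0 = 50, noise = 1, seed = 15)
  sp <- unit_space(2)
  reg <- model_registry(c("random-forest", "gaussian-process"))
  rep <- nested_cv(tab, sp, reg, outer_folds = 4, inner_folds = 2,
                   seed = 3)
  for (ens in c("none", "averaging", "nnls", "stacking")) {
    surr <- fit_surrogate(tab, sp, rep, reg, ensemble = ens, seed = 3)
    pr <- predict_surrogate(surr, data.frame(x1 = c(0, 0.5),
                                             x2 = c(0, -0.5)))
    expect_length(pr$mean, 2)
    expect_true(all(is.finite(pr$mean)))
    expect_true(all(pr$sd >= 0))
  }
  # out-of-fold predictions carry no row from its own training fold:
  # a model memorizing y exactly still cannot be perfect out of fold
  memor <- list(mem = list(
    model_id = "mem", grid = data.frame(d = 1),
    fit = function(X, y, params, seed) list(X = X, y = y),
    predict = function(fit, X) {
      key <- apply(round(X, 10), 1, paste, collapse = ",")
      trkey <- apply(round(fit$X, 10), 1, paste, collapse = ",")
      out <- fit$y[match(key, trkey)]
      ifelse(is.na(out), mean(fit$y), out)
    }))
  P <- oof_predictions(to_coded(sp, table_settings(tab)), tab$response,
                       memor, list(mem = data.frame(d = 1)), n_folds = 4,
                       seed = 1)
  expect_gt(sum((P[, 1] - tab$response)^2), 0)
})
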