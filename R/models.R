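# Seven-family surrogate registry. Each spec carries a small hyperparameter
# grid (a data frame of combinations), a fit(X, y, params, seed) closure and
# a predict(fit, X) closure. Features X are coded factor values; responses y
# are mg/L, unscaled (families that are scale-sensitive standardize y
# internally and invert on predict).

scale_y <- function(y) {
  mu <- mean(y); s <- stats::sd(y)
  if (!is.finite(s) || s == 0) s <- 1
  list(mu = mu, s = s, ys = (y - mu) / s)
}

fit_rf <- function(X, y, params, seed) {
  ranger::ranger(x = as.data.frame(X), y = y, num.trees = 300,
                 mtry = min(params$mtry, ncol(X)),
                 min.node.size = params$min_node,
                 seed = seed, num.threads = 1)
}
predict_rf <- function(fit, X) {
  stats::predict(fit, data = as.data.frame(X), num.threads = 1)$predictions
}

fit_svm <- function(X, y, params, seed) {
  sc <- scale_y(y)
  mod <- e1071::svm(x = as.matrix(X), y = sc$ys, type = "eps-regression",
                    kernel = "radial", cost = params$cost,
                    gamma = params$gamma / ncol(X), scale = FALSE)
  list(model = mod, mu = sc$mu, s = sc$s)
}
predict_svm <- function(fit, X) {
  as.numeric(stats::predict(fit$model, as.matrix(X))) * fit$s + fit$mu
}

fit_mlp <- function(X, y, params, seed) {
  sc <- scale_y(y)
  set.seed(seed)
  mod <- nnet::nnet(x = as.matrix(X), y = sc$ys, size = params$size,
                    decay = params$decay, linout = TRUE, maxit = 300,
                    trace = FALSE)
  list(model = mod, mu = sc$mu, s = sc$s)
}
predict_mlp <- function(fit, X) {
  as.numeric(stats::predict(fit$model, as.matrix(X))) * fit$s + fit$mu
}

fit_gbt <- function(X, y, params, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1)
  xgboost::xgb.train(params = list(eta = params$eta,
                                   max_depth = params$max_depth,
                                   subsample = params$subsample,
                                   min_child_weight = params$min_child,
                                   objective = "reg:squarederror",
                                   nthread = 1),
                     data = dtrain, nrounds = params$nrounds, verbose = 0)
}
predict_gbt <- function(fit, X) {
  stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(X), nthread = 1))
}

fit_gp <- function(X, y, params, seed) {
  sc <- scale_y(y)
  mod <- kernlab::gausspr(x = as.matrix(X), y = sc$ys, kernel = "rbfdot",
                          kpar = list(sigma = params$sigma),
                          var = params$noise, variance.model = TRUE,
                          scaled = FALSE)
  list(model = mod, mu = sc$mu, s = sc$s)
}
predict_gp <- function(fit, X) {
  as.numeric(kernlab::predict(fit$model, as.matrix(X))) * fit$s + fit$mu
}
predict_gp_sd <- function(fit, X) {
  sd <- as.numeric(kernlab::predict(fit$model, as.matrix(X),
                                    type = "sdeviation"))
  pmax(sd, 0) * fit$s
}

#' Default surrogate-model registry
#'
#' Seven regression families spanning the usual small-data surrogate zoo:
#' random forest, RBF-kernel support-vector regression, a single-hidden-
#' layer perceptron, three gradient-boosted-tree configurations (shallow/
#' slow, deeper/slower, aggressive), and Gaussian-process regression.
#' Hyperparameter grids are intentionally small (<= 4 combinations per
#' family), sized for datasets of a few dozen runs; the registry is an
#' ordinary named list and can be subset or extended.
#'
#' @param models optional character vector to subset the registry (in the
#'   given order).
#' @return Named list of model specs, each with elements `model_id`,
#'   `grid` (data frame of hyperparameter combinations), `fit` and
#'   `predict` closures, and optionally `predict_sd` (Gaussian process).
#' @export
model_registry <- function(models = NULL) {
  reg <- list(
    `random-forest` = list(
      grid = expand.grid(mtry = c(4L, 8L), min_node = c(2L, 5L)),
      fit = fit_rf, predict = predict_rf),
    `kernel-support-vector` = list(
      grid = expand.grid(cost = c(1, 10), gamma = c(1, 3)),
      fit = fit_svm, predict = predict_svm),
    `multilayer-perceptron` = list(
      grid = expand.grid(size = c(3L, 6L), decay = c(0.01, 0.1)),
      fit = fit_mlp, predict = predict_mlp),
    `gradient-boosted-trees-A` = list(
      grid = expand.grid(nrounds = 150L, eta = 0.05, max_depth = 2L,
                         subsample = c(0.8, 1), min_child = 1L),
      fit = fit_gbt, predict = predict_gbt),
    `gradient-boosted-trees-B` = list(
      grid = expand.grid(nrounds = 250L, eta = 0.03, max_depth = 3L,
                         subsample = 0.9, min_child = c(1L, 3L)),
      fit = fit_gbt, predict = predict_gbt),
    `gradient-boosted-trees-C` = list(
      grid = expand.grid(nrounds = 80L, eta = 0.1, max_depth = c(4L, 6L),
                         subsample = 1, min_child = 1L),
      fit = fit_gbt, predict = predict_gbt),
    `gaussian-process` = list(
      grid = expand.grid(sigma = c(0.25, 1), noise = c(0.01, 0.1)),
      fit = fit_gp, predict = predict_gp, predict_sd = predict_gp_sd)
  )
  for (id in names(reg)) reg[[id]]$model_id <- id
  if (!is.null(models)) {
    unknown <- setdiff(models, names(reg))
    if (length(unknown))
      stop("unknown model id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    reg <- reg[models]
  }
  reg
}
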