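# Deterministic fold assignment: seeded shuffle of row indices split into
# k contiguous groups. Depends only on (n, k, seed) -- never on responses --
# so hyperparameter choices cannot leak information from held-out folds.
make_folds <- function(n, k, seed) {
  if (k < 2) stop("need at least 2 folds", call. = FALSE)
  if (n < k) stop("need at least as many rows (", n, ") as folds (", k,
                  ")", call. = FALSE)
  ord <- local({ set.seed(seed %% 2147483647); sample.int(n) })
  split(ord, cut(seq_len(n), breaks = k, labels = FALSE))
}

fit_seed <- function(seed, fold, model_index) {
  (as.numeric(seed) * 7 + fold * 131 + model_index * 7919) %% 2147483647
}

# Inner grid search: mean squared error across inner folds, ties to the
# first grid row. Returns the winning row index of spec$grid.
inner_tune <- function(spec, X, y, inner_folds, seed, model_index) {
  grid <- spec$grid
  if (nrow(grid) == 1L) return(1L)
  folds <- make_folds(nrow(X), min(inner_folds, nrow(X)), seed + 17)
  mse <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- unlist(lapply(seq_along(folds), function(fi) {
      idx <- folds[[fi]]
      tr <- setdiff(seq_len(nrow(X)), idx)
      fit <- spec$fit(X[tr, , drop = FALSE], y[tr], grid[g, , drop = FALSE],
                      fit_seed(seed, fi, model_index))
      pred <- spec$predict(fit, X[idx, , drop = FALSE])
      (y[idx] - pred)^2
    }))
    mean(errs)
  }, numeric(1))
  which.min(mse)
}

safe_cor <- function(a, b) {
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0)
    return(NA_real_)
  stats::cor(a, b)
}

rsq <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

#' Nested cross-validation over the surrogate registry
#'
#' Evaluates every registered model family with an outer/inner nested
#' cross-validation: for each outer fold, an inner grid search (mean
#' squared error across `inner_folds` folds of the outer-training rows
#' only) picks the hyperparameters, the model is refit on the full
#' outer-training set, and the held-out fold supplies the test metrics.
#' Test-set correlation is the Pearson correlation between held-out
#' predictions and responses; R-squared is `1 - SSE/SST`. Folds are a
#' seeded shuffle, independent of the responses, so the procedure is
#' deterministic given `(seed, dataset)` and corrupting a held-out fold's
#' responses cannot change the chosen hyperparameters.
#'
#' @param data an [experiment_table()] with all responses present.
#' @param space a [factor_space()]; features are `to_coded(space, settings)`.
#' @param registry a [model_registry()].
#' @param outer_folds,inner_folds fold counts (defaults 9 and 3).
#' @param seed integer seed controlling fold shuffles and stochastic fits.
#' @return A `cv_report`: per model, outer-fold correlations and
#'   R-squared values, their means, and chosen hyperparameters per fold;
#'   plus `selected` (the [select_best()] winner) and bookkeeping fields.
#' @export
nested_cv <- function(data, space, registry = model_registry(),
                      outer_folds = 9, inner_folds = 3, seed = 1) {
  X <- to_coded(space, table_settings(data))
  y <- data$response
  if (anyNA(y)) stop("all rows must have responses for model training",
                     call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (nrow(X) < outer_folds)
    stop("need at least outer_folds (", outer_folds, ") rows; got ",
         nrow(X), call. = FALSE)
  folds <- make_folds(nrow(X), outer_folds, seed)
  models <- lapply(seq_along(registry), function(mi) {
    spec <- registry[[mi]]
    fold_cor <- fold_r2 <- numeric(length(folds))
    chosen <- vector("list", length(folds))
    for (fi in seq_along(folds)) {
      idx <- folds[[fi]]
      tr <- setdiff(seq_len(nrow(X)), idx)
      g <- inner_tune(spec, X[tr, , drop = FALSE], y[tr], inner_folds,
                      seed + 1000 * fi, mi)
      fit <- spec$fit(X[tr, , drop = FALSE], y[tr],
                      spec$grid[g, , drop = FALSE], fit_seed(seed, fi, mi))
      pred <- spec$predict(fit, X[idx, , drop = FALSE])
      fold_cor[fi] <- safe_cor(y[idx], pred)
      fold_r2[fi] <- rsq(y[idx], pred)
      chosen[[fi]] <- spec$grid[g, , drop = FALSE]
    }
    list(model_id = spec$model_id,
         fold_correlation = fold_cor, fold_r2 = fold_r2,
         mean_correlation = mean(fold_cor, na.rm = TRUE),
         mean_r2 = mean(fold_r2, na.rm = TRUE),
         chosen_params = chosen)
  })
  names(models) <- names(registry)
  rep <- structure(list(models = models, outer_folds = outer_folds,
                        inner_folds = inner_folds, seed = seed,
                        n = nrow(X)),
                   class = "cv_report")
  rep$selected <- select_best(rep)
  rep
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Nested CV report (%d outer / %d inner folds, n = %d)\n",
              x$outer_folds, x$inner_folds, x$n))
  df <- data.frame(
    model = names(x$models),
    mean_correlation = round(vapply(x$models, `[[`, 0, "mean_correlation"),
                             3),
    mean_r2 = round(vapply(x$models, `[[`, 0, "mean_r2"), 3))
  print(df, row.names = FALSE)
  cat("selected:", x$selected, "\n")
  invisible(x)
}

#' Pick the best surrogate from a CV report
#'
#' Argmax of mean outer-fold test correlation; ties break to the earliest
#' model in registry order.
#'
#' @param report a `cv_report` from [nested_cv()].
#' @return The winning `model_id` string.
#' @export
select_best <- function(report) {
  if (!length(report$models)) stop("empty CV report", call. = FALSE)
  scores <- vapply(report$models, `[[`, 0, "mean_correlation")
  scores[is.na(scores)] <- -Inf
  names(report$models)[which.max(scores)]
}

# Most frequently chosen hyperparameter row across outer folds; ties to the
# earliest grid row.
consensus_params <- function(spec, chosen) {
  if (nrow(spec$grid) == 1L) return(spec$grid[1, , drop = FALSE])
  key <- vapply(chosen, function(p) paste(unlist(p), collapse = "|"), "")
  gridkey <- apply(spec$grid, 1, function(r) paste(r, collapse = "|"))
  counts <- table(factor(key, levels = gridkey))
  spec$grid[which.max(counts), , drop = FALSE]
}

#' Fit the full surrogate stack on all available data
#'
#' Refits every registry family on the complete dataset using, per family,
#' the hyperparameters most often chosen across the outer CV folds. The
#' returned surrogate predicts with the selected model (or an ensemble
#' fusion, see `ensemble`) and reports an uncertainty: the Gaussian-process
#' posterior standard deviation when the GP is the selected model,
#' otherwise the spread (sd) of the base-model predictions.
#'
#' @param data an [experiment_table()] with responses.
#' @param space a [factor_space()].
#' @param report a `cv_report` from [nested_cv()] on the same data.
#' @param registry the [model_registry()] used for the report.
#' @param ensemble `"none"` (predict with the selected single model),
#'   `"stacking"`, `"averaging"` or `"nnls"`: fuse all base models, with
#'   fusion weights fit on out-of-fold predictions (stacking) or training
#'   predictions (nnls).
#' @param seed integer seed.
#' @return A `surrogate` object; see [predict_surrogate()].
#' @export
fit_surrogate <- function(data, space, report, registry = model_registry(),
                          ensemble = c("none", "stacking", "averaging",
                                       "nnls"),
                          seed = 1) {
  ensemble <- match.arg(ensemble)
  X <- to_coded(space, table_settings(data))
  y <- data$response
  fits <- params <- list()
  for (mi in seq_along(registry)) {
    spec <- registry[[mi]]
    p <- consensus_params(spec, report$models[[spec$model_id]]$chosen_params)
    params[[spec$model_id]] <- p
    fits[[spec$model_id]] <- spec$fit(X, y, p, fit_seed(seed, 0, mi))
  }
  weights <- NULL
  if (ensemble != "none") {
    k <- length(registry)
    weights <- switch(ensemble,
      averaging = fit_average(k, names(registry)),
      nnls = {
        P <- vapply(names(registry),
                    function(id) registry[[id]]$predict(fits[[id]], X),
                    numeric(nrow(X)))
        fit_nnls(P, y)
      },
      stacking = {
        P <- oof_predictions(X, y, registry, params, n_folds = 5,
                             seed = seed)
        fit_stacking(P, y, seed = seed)
      })
  }
  structure(list(fits = fits, params = params, registry = registry,
                 selected = report$selected, ensemble = ensemble,
                 weights = weights, space = space, seed = seed,
                 n_train = nrow(X)),
            class = "surrogate")
}

#' Out-of-fold base-model predictions
#'
#' Builds the leak-free prediction matrix used to train the stacking
#' meta-learner: each row's predictions come from base models fit without
#' that row's fold.
#'
#' @param X coded feature matrix.
#' @param y responses.
#' @param registry a [model_registry()].
#' @param params named list of single-row hyperparameter frames per model.
#' @param n_folds fold count (default 5).
#' @param seed integer seed.
#' @return Matrix rows x models of out-of-fold predictions.
#' @export
oof_predictions <- function(X, y, registry, params, n_folds = 5, seed = 1) {
  folds <- make_folds(nrow(X), min(n_folds, nrow(X)), seed + 31)
  P <- matrix(NA_real_, nrow(X), length(registry),
              dimnames = list(NULL, names(registry)))
  for (mi in seq_along(registry)) {
    spec <- registry[[mi]]
    for (fi in seq_along(folds)) {
      idx <- folds[[fi]]
      tr <- setdiff(seq_len(nrow(X)), idx)
      fit <- spec$fit(X[tr, , drop = FALSE], y[tr], params[[spec$model_id]],
                      fit_seed(seed, fi, mi))
      P[idx, mi] <- spec$predict(fit, X[idx, , drop = FALSE])
    }
  }
  P
}

#' Predict mean and uncertainty from a fitted surrogate
#'
#' @param surrogate a [fit_surrogate()] object.
#' @param settings natural-unit settings (named vector, data frame) or,
#'   with `coded = TRUE`, an already-coded matrix.
#' @param coded set `TRUE` when `settings` is already in coded units.
#' @return List with numeric vectors `mean` (mg/L) and `sd` (mg/L): the
#'   selected model's (or ensemble's) prediction and the uncertainty
#'   described in [fit_surrogate()].
#' @export
predict_surrogate <- function(surrogate, settings, coded = FALSE) {
  X <- if (coded) {
    m <- as.matrix(settings)
    if (is.null(dim(settings))) m <- matrix(settings, nrow = 1)
    colnames(m) <- factor_names(surrogate$space)
    m
  } else {
    to_coded(surrogate$space, settings)
  }
  reg <- surrogate$registry
  P <- vapply(names(reg),
              function(id) reg[[id]]$predict(surrogate$fits[[id]], X),
              numeric(nrow(X)))
  if (nrow(X) == 1L) P <- matrix(P, nrow = 1,
                                 dimnames = list(NULL, names(reg)))
  mean_pred <- if (surrogate$ensemble == "none") {
    P[, surrogate$selected]
  } else {
    predict_ensemble(surrogate$weights, P)
  }
  sd_pred <- if (surrogate$ensemble == "none" &&
                 surrogate$selected == "gaussian-process" &&
                 !is.null(reg[["gaussian-process"]]$predict_sd)) {
    reg[["gaussian-process"]]$predict_sd(
      surrogate$fits[["gaussian-process"]], X)
  } else if (ncol(P) >= 2) {
    apply(P, 1, stats::sd)
  } else {
    rep(0, nrow(X))  # single-model stack carries no spread information
  }
  list(mean = as.numeric(mean_pred), sd = as.numeric(sd_pred))
}

#' @export
print.surrogate <- function(x, ...) {
  cat(sprintf(
    "Surrogate stack: %d base models on %d runs; selected = %s%s\n",
    length(x$fits), x$n_train, x$selected,
    if (x$ensemble != "none") paste0(", fused by ", x$ensemble) else ""))
  invisible(x)
}
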