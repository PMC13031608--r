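#' Non-negative least-squares ensemble weights
#'
#' Finds weights `w >= 0` minimizing `||P w - y||^2` (no sum-to-one
#' constraint, no intercept) via the Lawson-Hanson active-set solver.
#' Base models that hurt the fit receive weight exactly zero.
#'
#' @param base_predictions numeric matrix, runs x k, of base-model
#'   predictions (training-set or out-of-fold).
#' @param response numeric vector of observed responses.
#' @return An `ensemble_weights` object: `method = "nnls"`, `weights`
#'   (named if the matrix has column names), `intercept = 0`.
#' @export
fit_nnls <- function(base_predictions, response) {
  P <- as.matrix(base_predictions)
  if (!all(is.finite(P))) stop("non-finite base predictions", call. = FALSE)
  if (all(P == 0))
    stop("degenerate all-zero base predictions", call. = FALSE)
  w <- pracma::lsqnonneg(P, as.numeric(response))$x
  structure(list(method = "nnls",
                 weights = stats::setNames(w, colnames(P)),
                 intercept = 0),
            class = "ensemble_weights")
}

# Closed-form ridge with unpenalized intercept: columns and response are
# centered, w = (P'P + lambda I)^-1 P'y, intercept = ybar - w . Pbar.
ridge_solve <- function(P, y, lambda) {
  Pm <- colMeans(P); ym <- mean(y)
  Pc <- sweep(P, 2, Pm); yc <- y - ym
  A <- crossprod(Pc) + diag(lambda, ncol(P))
  w <- solve(A, crossprod(Pc, yc))
  list(weights = drop(w), intercept = ym - sum(w * Pm))
}

#' Stacking ensemble with a ridge meta-learner
#'
#' Fits a ridge-penalized linear meta-learner on out-of-fold base-model
#' predictions (the caller is responsible for supplying leak-free
#' out-of-fold predictions, e.g. from [oof_predictions()]). The penalty is
#' chosen by internal k-fold cross-validated mean squared error over
#' `lambda_grid`; ties go to the larger penalty. The intercept is not
#' penalized.
#'
#' @param oof_predictions numeric matrix, runs x k, of out-of-fold base
#'   predictions.
#' @param response numeric vector of observed responses (length >= 2).
#' @param lambda_grid positive penalties to search (default
#'   `10^seq(-6, 2)`).
#' @param n_folds internal CV folds (default 5, capped at the row count).
#' @param seed seed for the internal fold shuffle.
#' @return An `ensemble_weights` with `method = "stacking"`, `weights`,
#'   `intercept`, and the chosen `lambda`.
#' @export
fit_stacking <- function(oof_predictions, response,
                         lambda_grid = 10^seq(-6, 2), n_folds = 5,
                         seed = 1) {
  P <- as.matrix(oof_predictions)
  y <- as.numeric(response)
  if (nrow(P) < 2) stop("need at least 2 rows for stacking", call. = FALSE)
  k <- min(n_folds, nrow(P))
  folds <- make_folds(nrow(P), k, seed)
  cv_mse <- vapply(lambda_grid, function(lam) {
    errs <- unlist(lapply(folds, function(idx) {
      tr <- setdiff(seq_len(nrow(P)), idx)
      f <- ridge_solve(P[tr, , drop = FALSE], y[tr], lam)
      pred <- f$intercept + P[idx, , drop = FALSE] %*% f$weights
      (y[idx] - pred)^2
    }))
    mean(errs)
  }, numeric(1))
  # ties (and near-ties within numerical noise) resolve to the larger lambda
  best <- max(which(cv_mse <= min(cv_mse) + 1e-12))
  f <- ridge_solve(P, y, lambda_grid[best])
  structure(list(method = "stacking",
                 weights = stats::setNames(f$weights, colnames(P)),
                 intercept = f$intercept, lambda = lambda_grid[best]),
            class = "ensemble_weights")
}

#' Simple-averaging ensemble weights
#'
#' @param k number of base models.
#' @param ids optional names for the weights.
#' @return An `ensemble_weights` with all weights `1/k` and zero intercept.
#' @export
fit_average <- function(k, ids = NULL) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  structure(list(method = "averaging",
                 weights = stats::setNames(rep(1 / k, k), ids),
                 intercept = 0),
            class = "ensemble_weights")
}

#' Predict from ensemble weights
#'
#' @param weights an `ensemble_weights` from [fit_nnls()],
#'   [fit_stacking()] or [fit_average()].
#' @param base_predictions numeric matrix, rows x k, of base-model
#'   predictions at the query points.
#' @return Numeric vector: `intercept + base_predictions %*% weights`.
#' @export
predict_ensemble <- function(weights, base_predictions) {
  P <- as.matrix(base_predictions)
  if (ncol(P) != length(weights$weights))
    stop("base prediction columns (", ncol(P),
         ") != number of weights (", length(weights$weights), ")",
         call. = FALSE)
  drop(weights$intercept + P %*% weights$weights)
}

#' @export
print.ensemble_weights <- function(x, ...) {
  cat(sprintf("Ensemble fusion (%s)%s\n", x$method,
              if (!is.null(x$lambda)) sprintf(", lambda = %g", x$lambda)
              else ""))
  w <- round(x$weights, 4)
  print(w)
  if (x$intercept != 0) cat("intercept:", round(x$intercept, 4), "\n")
  invisible(x)
}
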