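# Published cyclic generating rows for two-level screening designs.
# Row i (i = 1..N-1) of the design is the generator cyclically shifted
# right by i-1 positions; run N is all minus. Columns are balanced and
# mutually orthogonal for every supported run count.
pb_generators <- list(
  `8`  = c(1, 1, 1, -1, 1, -1, -1),
  `12` = c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1),
  `16` = c(1, 1, 1, 1, -1, 1, -1, 1, 1, -1, -1, 1, -1, -1, -1),
  `20` = c(1, 1, -1, -1, 1, 1, 1, 1, -1, 1, -1, 1, -1, -1, -1, -1, 1, 1,
           -1),
  `24` = c(1, 1, 1, 1, 1, -1, 1, -1, 1, 1, -1, -1, 1, 1, -1, -1, 1, -1, 1,
           -1, -1, -1, -1)
)

#' Generate a Plackett-Burman screening design
#'
#' Builds the classical saturated two-level screening design by cyclic
#' shifts of the published generating row for the requested run count,
#' closed with an all-minus run. Up to `n_runs - 1` main effects can be
#' screened in `n_runs` experiments; interactions are deliberately
#' confounded with main effects (the method's screening assumption).
#'
#' @param n_factors number of factors (columns), `<= n_runs - 1`.
#' @param n_runs one of 8, 12, 16, 20, 24.
#' @param factor_names optional character vector naming the columns (e.g.
#'   from [factor_names()]); defaults to `X1..Xk`.
#' @return A `pb_design`: an `n_runs x n_factors` matrix of -1/+1 with one
#'   all-minus run. Every column has equally many +1 and -1 entries and
#'   any two columns are orthogonal.
#' @examples
#' d <- pb_design(13, 20)
#' colSums(unclass(d))            # all zero (balance)
#' crossprod(unclass(d))[1, 2]    # zero (orthogonality)
#' @export
pb_design <- function(n_factors, n_runs, factor_names = NULL) {
  key <- as.character(n_runs)
  if (!key %in% names(pb_generators))
    stop("unsupported n_runs ", n_runs, "; supported: ",
         paste(names(pb_generators), collapse = ", "), call. = FALSE)
  if (n_factors < 1 || n_factors > n_runs - 1)
    stop("n_factors must be between 1 and n_runs - 1 (= ", n_runs - 1, ")",
         call. = FALSE)
  g <- pb_generators[[key]]
  k <- n_runs - 1
  full <- rbind(
    t(vapply(0:(k - 1), function(s) g[((seq_len(k) - 1 - s) %% k) + 1],
             numeric(k))),
    rep(-1, k))
  d <- full[, seq_len(n_factors), drop = FALSE]
  if (is.null(factor_names)) factor_names <- paste0("X", seq_len(n_factors))
  dimnames(d) <- list(NULL, factor_names)
  class(d) <- c("pb_design", class(d))
  d
}

#' @export
print.pb_design <- function(x, ...) {
  cat(sprintf("Plackett-Burman design: %d runs x %d factors\n",
              nrow(x), ncol(x)))
  m <- unclass(x)
  print(m)
  invisible(x)
}

design_matrix <- function(design) {
  m <- unclass(design)
  if (!is.matrix(m)) m <- as.matrix(as.data.frame(design))
  storage.mode(m) <- "double"
  m
}

#' Per-factor main effects from a two-level design
#'
#' For each factor, the effect is the sum of responses at the high level
#' minus the sum at the low level, divided by the total number of runs N.
#' On a balanced orthogonal design this equals the slope of the first-order
#' coded-model fit; the half-difference-of-means reading of the same
#' contrast is `2 * effect` (reported by [pb_screen()] as
#' `effect_diff_means`).
#'
#' @param design a [pb_design()] or -1/+1 matrix.
#' @param response numeric vector of responses, one per run.
#' @return Named numeric vector of effects (mg/L per coded unit).
#' @export
pb_effects <- function(design, response) {
  m <- design_matrix(design)
  if (length(response) != nrow(m))
    stop("response length ", length(response), " != number of runs ",
         nrow(m), call. = FALSE)
  n <- nrow(m)
  eff <- as.numeric(crossprod(m, response)) / n
  stats::setNames(eff, colnames(m))
}

#' First-order screening regression on a coded design
#'
#' Ordinary least squares of the response on the coded -1/+1 design matrix
#' with an intercept: `y = beta + sum_i E_i x_i`. Per-factor t-statistics
#' are coefficient / standard error and two-sided p-values use the Student
#' t distribution with `runs - factors - 1` residual degrees of freedom.
#'
#' @param design a [pb_design()] or -1/+1 matrix (runs x factors).
#' @param response numeric vector of responses (mg/L), one per run.
#' @param alpha significance level for the screening flag (default 0.05).
#' @return An object of class `pb_screening` with elements `intercept`,
#'   `coefficients`, `effects` (identical to coefficients on a balanced
#'   orthogonal design), `effect_diff_means` (`2 * effects`; the
#'   high-minus-low difference of level means), `se`, `t_value`, `p_value`,
#'   `significant`, `residual_df`, `alpha`, `sigma`, `n_runs`.
#' @export
pb_screen <- function(design, response, alpha = 0.05) {
  m <- design_matrix(design)
  if (length(response) != nrow(m))
    stop("response length must equal the number of runs", call. = FALSE)
  if (nrow(m) <= ncol(m) + 1)
    stop("need runs > factors + 1 for a residual error estimate",
         call. = FALSE)
  X <- cbind(`(Intercept)` = 1, m)
  fit <- stats::lm.fit(X, response)
  if (fit$rank < ncol(X))
    stop("design matrix is rank deficient; cannot fit first-order model",
         call. = FALSE)
  df <- nrow(m) - ncol(m) - 1L
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  coefs <- fit$coefficients
  tval <- coefs / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  nm <- colnames(m)
  res <- list(intercept = unname(coefs[1]),
              coefficients = stats::setNames(coefs[-1], nm),
              effects = pb_effects(m, response),
              effect_diff_means = 2 * pb_effects(m, response),
              se = stats::setNames(se[-1], nm),
              t_value = stats::setNames(tval[-1], nm),
              p_value = stats::setNames(pval[-1], nm),
              significant = stats::setNames(pval[-1] < alpha, nm),
              residual_df = df, alpha = alpha,
              sigma = sqrt(sigma2), n_runs = nrow(m))
  class(res) <- "pb_screening"
  res
}

#' @export
print.pb_screening <- function(x, ...) {
  cat(sprintf(
    "First-order screening fit: intercept %.2f mg/L, %d factors, df = %d\n",
    x$intercept, length(x$coefficients), x$residual_df))
  df <- data.frame(coefficient = round(x$coefficients, 3),
                   t_value = round(x$t_value, 3),
                   p_value = round(x$p_value, 4),
                   significant = ifelse(x$significant, "*", ""))
  print(df)
  cat(sprintf("'*' p < %.3g\n", x$alpha))
  invisible(x)
}

#' Select the significant screening factors
#'
#' @param result a `pb_screening` from [pb_screen()] or
#'   [printed_screening()].
#' @param alpha significance level; defaults to the level stored in the
#'   result.
#' @return Character vector of factor names with `p < alpha`, in original
#'   factor order.
#' @export
select_significant <- function(result, alpha = result$alpha) {
  names(result$p_value)[result$p_value < alpha]
}

#' Predict from a first-order screening model
#'
#' @param object a `pb_screening`.
#' @param coded numeric vector (length = factor count) or matrix of coded
#'   factor values.
#' @param ... unused.
#' @return Predicted response(s): intercept + coded %*% coefficients.
#' @export
predict.pb_screening <- function(object, coded, ...) {
  k <- length(object$coefficients)
  if (is.null(dim(coded))) {
    if (length(coded) != k)
      stop("coded vector length ", length(coded), " != factor count ", k,
           call. = FALSE)
    coded <- matrix(coded, nrow = 1)
  } else if (ncol(coded) != k) {
    stop("coded matrix must have ", k, " columns", call. = FALSE)
  }
  drop(object$intercept + as.matrix(coded) %*% object$coefficients)
}
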