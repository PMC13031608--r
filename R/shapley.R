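# Shapley attribution under the interventional (marginal-expectation)
# value function: v(S) = mean over background rows b of f(x_S, b_{-S}).
# The base value is v(empty) = mean prediction over the background, and
# v(all features) = f(instance), so exact attributions satisfy
# base + sum(contributions) = prediction (efficiency axiom).

as_pred_fun <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "surrogate"))
    return(function(X) predict_surrogate(model, X, coded = TRUE)$mean)
  stop("model must be a prediction function or a surrogate", call. = FALSE)
}

instance_blend <- function(instance, background, mask) {
  # rows = background with masked features overwritten by the instance
  out <- background
  if (any(mask))
    out[, mask] <- matrix(rep(instance[mask], each = nrow(background)),
                          nrow(background))
  out
}

#' Exact Shapley attribution by subset enumeration
#'
#' Computes exact Shapley values for one instance under the marginal-
#' expectation value function with the supplied background sample. Cost is
#' `2^d` model evaluations over the background, so the feature count is
#' capped at 12; use [shapley_sampled()] above that.
#'
#' @param model a prediction function `f(X matrix) -> numeric` or a
#'   [fit_surrogate()] object (evaluated in coded units).
#' @param instance numeric feature vector (named or not).
#' @param background numeric matrix of background rows (the training set
#'   is the conventional choice).
#' @return An `attribution` object: `base` (mean background prediction),
#'   `contributions` (named per-feature), `prediction`, `method = "exact"`.
#' @export
shapley_exact <- function(model, instance, background) {
  f <- as_pred_fun(model)
  background <- as.matrix(background)
  d <- length(instance)
  if (d > 12)
    stop("feature count ", d, " > 12; use shapley_sampled()", call. = FALSE)
  if (ncol(background) != d)
    stop("background columns != instance length", call. = FALSE)
  nb <- nrow(background)
  masks <- 0:(2^d - 1)
  # evaluate v for every subset in one stacked prediction call
  big <- do.call(rbind, lapply(masks, function(m) {
    instance_blend(instance, background,
                   as.logical(bitwAnd(m, bitwShiftL(1, 0:(d - 1)))))
  }))
  preds <- f(big)
  v <- vapply(seq_along(masks),
              function(i) mean(preds[((i - 1) * nb + 1):(i * nb)]),
              numeric(1))
  sizes <- vapply(masks, function(m) sum(
    as.logical(bitwAnd(m, bitwShiftL(1, 0:(d - 1))))), numeric(1))
  # weight is only used for subsets excluding the target feature, so the
  # full set (size d) gets a placeholder zero
  w <- ifelse(sizes < d,
              factorial(sizes) * factorial(pmax(d - sizes - 1, 0)) /
                factorial(d), 0)
  phi <- numeric(d)
  for (i in seq_len(d)) {
    bit <- bitwShiftL(1, i - 1)
    without <- which(bitwAnd(masks, bit) == 0)
    with_i <- match(masks[without] + bit, masks)
    phi[i] <- sum(w[without] * (v[with_i] - v[without]))
  }
  nms <- names(instance)
  if (is.null(nms)) nms <- colnames(background)
  if (is.null(nms)) nms <- paste0("x", seq_len(d))
  structure(list(base = v[1],
                 contributions = stats::setNames(phi, nms),
                 prediction = v[length(v)],
                 method = "exact"),
            class = "attribution")
}

#' Monte-Carlo Shapley attribution by permutation sampling
#'
#' Unbiased permutation-sampling estimator of the Shapley values, with
#' antithetic permutation pairs (each sampled ordering is also used
#' reversed) to reduce variance. Deterministic given the seed; converges
#' to [shapley_exact()] as `n_permutations` grows.
#'
#' @inheritParams shapley_exact
#' @param n_permutations number of feature orderings to average (>= 1).
#' @param seed integer seed.
#' @return An `attribution` with `method = "sampled"`, `n_permutations`,
#'   `seed`, and `mc_se` (per-feature Monte-Carlo standard errors).
#' @export
shapley_sampled <- function(model, instance, background, n_permutations,
                            seed = 1) {
  f <- as_pred_fun(model)
  background <- as.matrix(background)
  if (nrow(background) < 1) stop("empty background", call. = FALSE)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  d <- length(instance)
  nb <- nrow(background)
  set.seed(seed %% 2147483647)
  n_pairs <- ceiling(n_permutations / 2)
  perms <- vector("list", n_permutations)
  pi_ <- 1L
  for (p in seq_len(n_pairs)) {
    prm <- sample.int(d)
    perms[[pi_]] <- prm; pi_ <- pi_ + 1L
    if (pi_ > n_permutations) break
    perms[[pi_]] <- rev(prm); pi_ <- pi_ + 1L
  }
  base <- mean(f(background))
  phi_sum <- phi_sq <- numeric(d)
  for (prm in perms) {
    # stacked prefix states: background, then cumulative feature insertion
    mask <- rep(FALSE, d)
    blocks <- vector("list", d + 1)
    blocks[[1]] <- background
    for (k in seq_len(d)) {
      mask[prm[k]] <- TRUE
      blocks[[k + 1]] <- instance_blend(instance, background, mask)
    }
    preds <- f(do.call(rbind, blocks))
    vk <- vapply(seq_len(d + 1),
                 function(k) mean(preds[((k - 1) * nb + 1):(k * nb)]),
                 numeric(1))
    contrib <- numeric(d)
    contrib[prm] <- diff(vk)
    phi_sum <- phi_sum + contrib
    phi_sq <- phi_sq + contrib^2
  }
  m <- length(perms)
  phi <- phi_sum / m
  mc_se <- if (m > 1) sqrt(pmax(phi_sq / m - phi^2, 0) / m) else
    rep(NA_real_, d)
  nms <- names(instance)
  if (is.null(nms)) nms <- colnames(background)
  if (is.null(nms)) nms <- paste0("x", seq_len(d))
  structure(list(base = base,
                 contributions = stats::setNames(phi, nms),
                 prediction = base + sum(phi),
                 method = "sampled", n_permutations = m, seed = seed,
                 mc_se = stats::setNames(mc_se, nms)),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("Shapley attribution (%s%s): base %.3f -> prediction %.3f\n",
              x$method,
              if (x$method == "sampled")
                sprintf(", %d permutations", x$n_permutations) else "",
              x$base, x$prediction))
  print(round(sort(x$contributions, decreasing = TRUE), 4))
  invisible(x)
}

#' Summarize attributions over a dataset
#'
#' Per-feature summary across instances: mean absolute contribution,
#' importance rank (1 = largest), and sign association (Pearson
#' correlation between feature value and contribution; `NA` when either
#' is constant). This is the tabular analogue of a beeswarm-style
#' attribution summary plot.
#'
#' @param results list of `attribution` objects (one per instance).
#' @param feature_values matrix/data frame of the instances' feature
#'   values (rows aligned with `results`).
#' @return Data frame with columns `feature`, `mean_abs`, `rank`,
#'   `sign_association`, ordered by rank.
#' @export
shapley_summary <- function(results, feature_values) {
  phi <- t(vapply(results, `[[`, results[[1]]$contributions,
                  "contributions"))
  fv <- as.matrix(feature_values)[, colnames(phi), drop = FALSE]
  mean_abs <- colMeans(abs(phi))
  rk <- rank(-mean_abs, ties.method = "min")
  assoc <- vapply(seq_len(ncol(phi)),
                  function(j) safe_cor(fv[, j], phi[, j]), numeric(1))
  out <- data.frame(feature = colnames(phi), mean_abs = mean_abs,
                    rank = rk, sign_association = assoc,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$rank), ]
}

#' Waterfall decomposition of one attribution
#'
#' Orders features by absolute contribution (largest first) and
#' accumulates from the base value; the final cumulative value equals the
#' model prediction (exactly for the enumeration method, within
#' Monte-Carlo error for the sampled one).
#'
#' @param result an `attribution`.
#' @return Data frame with columns `feature`, `contribution`,
#'   `cumulative`; `attr(-, "base")` and `attr(-, "prediction")` carry the
#'   endpoints.
#' @export
waterfall_data <- function(result) {
  ord <- order(abs(result$contributions), decreasing = TRUE)
  contr <- result$contributions[ord]
  out <- data.frame(feature = names(contr), contribution = as.numeric(contr),
                    cumulative = result$base + cumsum(as.numeric(contr)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "base") <- result$base
  attr(out, "prediction") <- result$prediction
  out
}
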