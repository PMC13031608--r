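#' Upper-confidence-bound acquisition score
#'
#' `score = mean + kappa * uncertainty`. With `kappa = 0` the search is
#' purely exploitative; larger `kappa` rewards uncertain regions.
#'
#' @param mean predicted mean response (mg/L).
#' @param sd predicted uncertainty (mg/L), `>= 0`.
#' @param kappa exploration weight (default 1).
#' @return Numeric acquisition score(s).
#' @export
acquisition_ucb <- function(mean, sd, kappa = 1) {
  if (any(sd < 0)) stop("uncertainty must be >= 0", call. = FALSE)
  mean + kappa * sd
}

#' Propose a validation batch by surrogate-guided search
#'
#' Scores `n_iterations` candidate points in coded space with the
#' upper-confidence-bound acquisition: the first quarter is a seeded
#' Latin-hypercube space-filling sample over the full (coded) box, the
#' remainder are Gaussian perturbations around the best scorer found so
#' far, with the perturbation scale annealed from 0.3 to 0.05 coded units.
#' All candidates are clipped to the box before scoring. The top
#' `batch_size` distinct candidates are returned after a greedy
#' minimum-pairwise-distance diversity filter.
#'
#' @param surrogate a [fit_surrogate()] object.
#' @param space a [factor_space()] whose low/high levels define the search
#'   bounds (coded -1..+1).
#' @param n_iterations candidate evaluations (default 2000).
#' @param batch_size proposals to return (default 12).
#' @param min_distance minimum pairwise Euclidean distance between
#'   returned proposals, in coded units (default 0.05).
#' @param kappa UCB exploration weight (default 1).
#' @param anchor optional coded point (e.g. the best condition observed so
#'   far) used as a second perturbation center during refinement; chunks
#'   then alternate between the best scorer and the anchor, so the search
#'   always also exploits the incumbent's neighbourhood.
#' @param seed integer seed; identical (seed, surrogate, bounds) give an
#'   identical batch.
#' @return A `candidate_batch`: data frame of proposed settings (natural
#'   units) with `pred_mean`, `pred_sd` and `acquisition` columns, sorted
#'   by acquisition descending; attributes record the search settings.
#' @export
propose_batch <- function(surrogate, space, n_iterations = 2000,
                          batch_size = 12, min_distance = 0.05, kappa = 1,
                          anchor = NULL, seed = 1) {
  d <- n_factors(space)
  set.seed(seed %% 2147483647)
  n_init <- max(batch_size, ceiling(n_iterations * 0.25))
  n_init <- min(n_init, n_iterations)
  cand <- 2 * lhs::randomLHS(n_init, d) - 1
  pr <- predict_surrogate(surrogate, cand, coded = TRUE)
  acq <- acquisition_ucb(pr$mean, pr$sd, kappa)
  all_cand <- cand; all_mean <- pr$mean; all_sd <- pr$sd; all_acq <- acq
  n_left <- n_iterations - n_init
  chunk <- 50L
  use_anchor <- FALSE
  while (n_left > 0) {
    m <- min(chunk, n_left)
    frac <- 1 - n_left / max(1, n_iterations - n_init)
    scale <- 0.3 * (1 - frac) + 0.05 * frac
    center <- if (use_anchor && !is.null(anchor)) as.numeric(anchor)
              else all_cand[which.max(all_acq), ]
    use_anchor <- !use_anchor
    pts <- matrix(rep(center, each = m), nrow = m) +
      matrix(stats::rnorm(m * d, sd = scale), nrow = m)
    pts <- pmin(pmax(pts, -1), 1)
    pr <- predict_surrogate(surrogate, pts, coded = TRUE)
    all_cand <- rbind(all_cand, pts)
    all_mean <- c(all_mean, pr$mean)
    all_sd <- c(all_sd, pr$sd)
    all_acq <- c(all_acq, acquisition_ucb(pr$mean, pr$sd, kappa))
    n_left <- n_left - m
  }
  ord <- order(all_acq, decreasing = TRUE)
  picked <- integer(0)
  for (i in ord) {
    if (length(picked) == batch_size) break
    if (length(picked)) {
      dmin <- min(sqrt(rowSums(
        (all_cand[picked, , drop = FALSE] -
           matrix(all_cand[i, ], length(picked), d, byrow = TRUE))^2)))
      if (dmin < min_distance) next
    }
    picked <- c(picked, i)
  }
  if (length(picked) < batch_size)
    stop(sprintf(paste0("only %d distinct candidates survive the ",
                        "min_distance = %g filter (requested %d)"),
                 length(picked), min_distance, batch_size), call. = FALSE)
  nat <- to_natural(space, all_cand[picked, , drop = FALSE])
  out <- cbind(as.data.frame(nat),
               data.frame(pred_mean = all_mean[picked],
                          pred_sd = all_sd[picked],
                          acquisition = all_acq[picked]))
  rownames(out) <- NULL
  attr(out, "factors") <- factor_names(space)
  attr(out, "search") <- list(n_iterations = n_iterations,
                              batch_size = batch_size,
                              min_distance = min_distance, kappa = kappa,
                              seed = seed)
  class(out) <- c("candidate_batch", "data.frame")
  out
}

#' @export
print.candidate_batch <- function(x, ...) {
  s <- attr(x, "search")
  cat(sprintf(
    "Candidate batch: %d proposals (%d evaluations, kappa = %g)\n",
    nrow(x), s$n_iterations, s$kappa))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
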