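# Synthetic yield landscape standing in for the wet lab. Concave quadratic
# in optimum-centered scaled coordinates, plus symmetric pairwise
# interactions, a sharp substrate-inhibition collapse above a threshold,
# and replicate noise (additive sd + multiplicative CV). The landscape is
# a test harness emulating the qualitative findings of the cell-free
# liquiritigenin system, not a kinetic model.

#' Default widened factor space for the synthetic landscape
#'
#' The 13 screening factors with bounds widened to the region actually
#' explored downstream of screening (ascent trials plus the final
#' optimized condition), so the optimum is interior.
#'
#' @return A [factor_space()] of 13 factors.
#' @export
default_bounds_space <- function() {
  factor_space(
    name = c("ZmPAL", "At4CL4", "GmCHS", "MsCHR", "ZmCHI", "CoA", "ATP",
             "NADPH", "tyrosine", "pH", "temperature", "time", "volume"),
    units = c("mg/mL", "mg/mL", "mg/mL", "mg/mL", "mg/mL", "mM", "mM",
              "mM", "mM", "pH", "degC", "h", "uL"),
    low = c(0.5, 0.5, 0.25, 0.5, 0.5, 0.5, 0.5, 0.5, 1, 5, 16, 12, 25),
    high = c(4.5, 3.0, 2.5, 4.0, 2.5, 3.0, 3.0, 3.0, 8, 9, 44, 60, 150))
}

#' Configure the synthetic yield oracle
#'
#' Defaults emulate the liquiritigenin cell-free system: the optimum sits
#' at the study's final optimized condition, the maximum yield is 155
#' mg/L, substrate (tyrosine) above 6 mM collapses the yield by 97%, and
#' replicate noise is 3 mg/L additive plus 5% CV. Curvatures are per-unit
#' scaled coordinates `u = (x - optimum) / half-range(bounds)` and must be
#' <= 0 (concave); interaction entries couple pairs of scaled coordinates.
#'
#' @param space [factor_space()] of search bounds.
#' @param optimum named numeric vector: landscape argmax (natural units,
#'   inside bounds).
#' @param max_yield noiseless yield at the optimum (mg/L).
#' @param curvature named numeric vector, one entry per factor, all <= 0:
#'   mg/L lost at one scaled unit from the optimum.
#' @param interactions symmetric matrix (factors x factors, zero diagonal)
#'   of pairwise coupling coefficients in mg/L per scaled-unit product, or
#'   `NULL` for none.
#' @param inhibition list of rules, each
#'   `list(factor=, threshold=, collapse=, steepness=)`: yield is
#'   multiplied by `1 - collapse * plogis(steepness * (x - threshold))`.
#' @param noise_sd additive replicate noise sd (mg/L).
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param n_reps default replicate count per query.
#' @param seed integer seed of the oracle's private noise stream.
#' @return An `oracle_config`.
#' @export
oracle_config <- function(space = default_bounds_space(),
                          optimum = NULL, max_yield = 155,
                          curvature = NULL, interactions = NULL,
                          inhibition = NULL,
                          noise_sd = 3, noise_cv = 0.05, n_reps = 3,
                          seed = 20250101) {
  nm <- factor_names(space)
  if (is.null(optimum) && identical(nm, factor_names(default_bounds_space())))
    optimum <- c(ZmPAL = 4, At4CL4 = 1.2, GmCHS = 1.3, MsCHR = 3,
                 ZmCHI = 1.5, CoA = 1.2, ATP = 2.2, NADPH = 2.4,
                 tyrosine = 2, pH = 7.3, temperature = 39, time = 30,
                 volume = 108)
  if (is.null(curvature) && identical(nm, factor_names(default_bounds_space())))
    curvature <- c(ZmPAL = -40, At4CL4 = -15, GmCHS = -25, MsCHR = -30,
                   ZmCHI = -15, CoA = -15, ATP = -15, NADPH = -15,
                   tyrosine = -40, pH = -30, temperature = -25,
                   time = -10, volume = -35)
  if (is.null(inhibition) && "tyrosine" %in% nm)
    inhibition <- list(list(factor = "tyrosine", threshold = 6,
                            collapse = 0.97, steepness = 3))
  if (is.null(optimum) || is.null(curvature))
    stop("optimum and curvature must be supplied for a custom space",
         call. = FALSE)
  optimum <- optimum[nm]; curvature <- curvature[nm]
  if (anyNA(optimum) || anyNA(curvature))
    stop("optimum/curvature must name every factor", call. = FALSE)
  if (any(optimum < space$low | optimum > space$high))
    stop("optimum must lie inside the factor bounds", call. = FALSE)
  if (any(curvature > 0))
    stop("positive curvature (non-concave landscape) rejected",
         call. = FALSE)
  if (is.null(interactions)) {
    interactions <- matrix(0, length(nm), length(nm),
                           dimnames = list(nm, nm))
    if (all(c("ZmPAL", "MsCHR", "GmCHS", "pH", "temperature") %in% nm)) {
      pairs <- list(c("ZmPAL", "MsCHR", 6), c("GmCHS", "MsCHR", -6),
                    c("pH", "temperature", 4))
      for (p in pairs) {
        interactions[p[1], p[2]] <- as.numeric(p[3])
        interactions[p[2], p[1]] <- as.numeric(p[3])
      }
    }
  }
  if (!isSymmetric(unname(interactions)))
    stop("interaction matrix must be symmetric", call. = FALSE)
  structure(list(space = space, optimum = optimum, max_yield = max_yield,
                 curvature = curvature, interactions = interactions,
                 inhibition = inhibition, noise_sd = noise_sd,
                 noise_cv = noise_cv, n_reps = n_reps, seed = seed),
            class = "oracle_config")
}

#' Instantiate a synthetic yield oracle
#'
#' @param config an [oracle_config()].
#' @return An `oracle`: environment holding the config, a private seeded
#'   noise stream (global RNG state is never touched), and a log of
#'   out-of-bounds clip warnings.
#' @export
make_oracle <- function(config) {
  stopifnot(inherits(config, "oracle_config"))
  env <- new.env(parent = emptyenv())
  env$config <- config
  env$n_queries <- 0L
  env$clip_log <- list()
  class(env) <- "oracle"
  env
}

#' Noiseless landscape value
#'
#' @param oracle an `oracle` (or `oracle_config`).
#' @param settings named vector / data frame of natural-unit settings.
#' @return Numeric vector of noiseless yields (mg/L, clipped at 0).
#' @export
oracle_truth <- function(oracle, settings) {
  cfg <- if (inherits(oracle, "oracle")) oracle$config else oracle
  m <- settings_matrix(cfg$space, settings)
  halfrange <- (cfg$space$high - cfg$space$low) / 2
  u <- sweep(sweep(m, 2, cfg$optimum, "-"), 2, halfrange, "/")
  y <- cfg$max_yield + (u^2) %*% cfg$curvature +
    rowSums((u %*% cfg$interactions) * u) / 2
  y <- as.numeric(y)
  for (rule in cfg$inhibition) {
    x <- m[, rule$factor]
    steep <- if (is.null(rule$steepness)) 3 else rule$steepness
    y <- y * (1 - rule$collapse * stats::plogis(steep * (x - rule$threshold)))
  }
  pmax(as.numeric(y), 0)
}

#' Query the oracle with replicate noise
#'
#' Each run draws `n_reps` replicates `truth + N(0, sd_total)` with
#' `sd_total^2 = noise_sd^2 + (noise_cv * truth)^2`, clipped at 0, and
#' returns their mean and sd. The noise stream is private and advances
#' with the query index, so an identical (config, query sequence) gives
#' identical outputs regardless of the caller's RNG use. Out-of-bounds
#' settings are clipped to the bounds and recorded in the oracle's
#' `clip_log`.
#'
#' @param oracle an `oracle` from [make_oracle()].
#' @param settings named vector or data frame of natural-unit settings.
#' @param n_reps replicates per run (default from the config).
#' @return Data frame with columns `response` (mean, mg/L),
#'   `replicate_sd`, `n_reps`.
#' @export
oracle_query <- function(oracle, settings, n_reps = NULL) {
  cfg <- oracle$config
  if (is.null(n_reps)) n_reps <- cfg$n_reps
  m <- settings_matrix(cfg$space, settings)
  lo <- matrix(cfg$space$low, nrow(m), ncol(m), byrow = TRUE)
  hi <- matrix(cfg$space$high, nrow(m), ncol(m), byrow = TRUE)
  clipped <- m < lo | m > hi
  if (any(clipped)) {
    oracle$clip_log[[length(oracle$clip_log) + 1L]] <-
      list(query = oracle$n_queries + 1L, rows = which(rowSums(clipped) > 0))
    warning("out-of-bounds settings clipped to factor bounds",
            call. = FALSE)
    m <- pmin(pmax(m, lo), hi)
  }
  truth <- oracle_truth(oracle, m)
  # private RNG scope keyed by (config seed, query index)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  out <- data.frame(response = numeric(nrow(m)),
                    replicate_sd = numeric(nrow(m)),
                    n_reps = rep(as.integer(n_reps), nrow(m)))
  for (i in seq_len(nrow(m))) {
    oracle$n_queries <- oracle$n_queries + 1L
    set.seed((cfg$seed + 97L * oracle$n_queries) %% 2147483647)
    sd_tot <- sqrt(cfg$noise_sd^2 + (cfg$noise_cv * truth[i])^2)
    draws <- pmax(truth[i] + stats::rnorm(n_reps, 0, sd_tot), 0)
    out$response[i] <- mean(draws)
    out$replicate_sd[i] <- if (n_reps > 1) stats::sd(draws) else NA_real_
  }
  out
}

#' Ground-truth optimum of the oracle
#'
#' @param oracle an `oracle` or `oracle_config`.
#' @return List with `settings` (named natural-unit vector) and `yield`
#'   (noiseless yield at that point).
#' @export
true_optimum <- function(oracle) {
  cfg <- if (inherits(oracle, "oracle")) oracle$config else oracle
  list(settings = cfg$optimum,
       yield = oracle_truth(cfg, cfg$optimum))
}

#' @export
print.oracle <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic yield oracle: %d factors, optimum %.1f mg/L, %d queries\n",
    n_factors(cfg$space), cfg$max_yield, x$n_queries))
  invisible(x)
}
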