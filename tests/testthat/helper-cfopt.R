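# Shared builders for the test suite. All fixtures are generated in code.

# k-factor space with low = -1, high = +1, so coded == natural units.
unit_space <- function(k) {
  factor_space(paste0("x", seq_len(k)), rep("", k), rep(-1, k), rep(1, k))
}

# experiment table with a known linear response y = b0 + X %*% b (+ noise)
linear_table <- function(n, b, b0 = 10, noise = 0, seed = 1) {
  k <- length(b)
  set.seed(seed)
  X <- matrix(runif(n * k, -1, 1), n, k,
              dimnames = list(NULL, paste0("x", seq_len(k))))
  y <- b0 + drop(X %*% b) + rnorm(n, 0, noise)
  experiment_table(as.data.frame(X), response = pmax(y, 0))
}

# one-model registry wrapping ordinary least squares -- a family that
# contains the linear truth exactly (for realizable-truth tests)
linear_registry <- function() {
  spec <- list(
    model_id = "linear",
    grid = data.frame(dummy = 1),
    fit = function(X, y, params, seed) stats::lm.fit(cbind(1, X), y),
    predict = function(fit, X) drop(cbind(1, X) %*% fit$coefficients))
  list(linear = spec)
}

# small fast registry for loop-level tests
fast_registry <- function() {
  model_registry(c("random-forest", "gradient-boosted-trees-A"))
}

# tiny 2-factor oracle for cheap closed-loop tests
tiny_oracle_config <- function(noise_sd = 1, noise_cv = 0, seed = 99) {
  sp <- factor_space(c("a", "b"), c("", ""), c(0, 0), c(10, 10))
  oracle_config(space = sp, optimum = c(a = 7, b = 3), max_yield = 100,
                curvature = c(a = -50, b = -50),
                interactions = matrix(0, 2, 2,
                                      dimnames = list(c("a", "b"),
                                                      c("a", "b"))),
                inhibition = list(), noise_sd = noise_sd,
                noise_cv = noise_cv, seed = seed)
}

# hand-made surrogate whose single "model" is an arbitrary function of the
# coded matrix; optionally records every scored candidate in `trace_env`
fun_surrogate <- function(space, f, sd_f = function(X) rep(0, nrow(X)),
                          trace_env = NULL) {
  spec <- list(
    model_id = "fun",
    grid = data.frame(dummy = 1),
    fit = function(X, y, params, seed) NULL,
    predict = function(fit, X) {
      if (!is.null(trace_env))
        trace_env$pool <- rbind(trace_env$pool, unname(as.matrix(X)))
      f(X)
    })
  structure(list(fits = list(fun = NULL), params = list(),
                 registry = list(fun = spec), selected = "fun",
                 ensemble = "none", weights = NULL, space = space,
                 seed = 1, n_train = 0),
            class = "surrogate")
}
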