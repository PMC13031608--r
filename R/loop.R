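#' Configuration for the active-learning loop
#'
#' @param space [factor_space()] defining the search bounds and feature
#'   coding.
#' @param registry surrogate [model_registry()].
#' @param outer_folds,inner_folds nested-CV fold counts (defaults 9/3).
#' @param ensemble fusion passed to [fit_surrogate()] (default
#'   "stacking": the ridge-meta-learner fusion of all seven base models,
#'   the fusion the study itself retained; "none" predicts with the
#'   CV-selected single model).
#' @param n_iterations,batch_size,kappa,min_distance search settings for
#'   [propose_batch()] (defaults 2000, 12, 1, 0.05).
#' @param threshold,patience,max_rounds convergence rule for [run_loop()]:
#'   stop when the relative best-so-far improvement stays below
#'   `threshold` (default 2%) for `patience` (default 2) consecutive
#'   rounds, or after `max_rounds` (default 10).
#' @param n_reps replicates requested from the responder.
#' @param seed master seed; per-round seeds are derived from it.
#' @return A `loop_config` list.
#' @export
loop_config <- function(space, registry = model_registry(),
                        outer_folds = 9, inner_folds = 3,
                        ensemble = "stacking",
                        n_iterations = 2000, batch_size = 12, kappa = 1,
                        min_distance = 0.05,
                        threshold = 0.02, patience = 2, max_rounds = 10,
                        n_reps = 3, seed = 1) {
  structure(list(space = space, registry = registry,
                 outer_folds = outer_folds, inner_folds = inner_folds,
                 ensemble = ensemble, n_iterations = n_iterations,
                 batch_size = batch_size, kappa = kappa,
                 min_distance = min_distance, threshold = threshold,
                 patience = patience, max_rounds = max_rounds,
                 n_reps = n_reps, seed = seed),
            class = "loop_config")
}

round_seed <- function(seed, round) {
  (as.numeric(seed) * 1009 + round * 1000003) %% 2147483647
}

#' Initial round state from a seed dataset
#'
#' @param data an [experiment_table()] with responses (e.g. screening +
#'   ascent runs).
#' @return A `round_state` at round 0 with empty improvement history.
#' @export
round_state <- function(data) {
  if (!nrow(data) || all(is.na(data$response)))
    stop("initial data must contain responses", call. = FALSE)
  bi <- best_trial(data)
  structure(list(round = 0L, data = data,
                 best = list(settings = as.list(table_settings(data)[bi$index, ]),
                             response = bi$response),
                 history = numeric(0), cv_report = NULL, batch = NULL),
            class = "round_state")
}

#' A responder backed by the synthetic oracle
#'
#' @param oracle an [make_oracle()] oracle.
#' @return A function `f(settings_df, n_reps)` returning the columns
#'   `response`, `replicate_sd`, `n_reps` — the signature [run_round()]
#'   expects. For real-lab ("lab sheet") use, supply your own function
#'   that writes the batch to CSV and blocks until the filled sheet is
#'   read back.
#' @export
oracle_responder <- function(oracle) {
  function(settings, n_reps = NULL) oracle_query(oracle, settings, n_reps)
}

#' Execute one active-learning round
#'
#' Trains the surrogate stack on the cumulative data (nested CV +
#' selection), proposes a validation batch, obtains responses from the
#' responder, appends them, and updates the best-so-far and improvement
#' history. All stage seeds derive from `(config$seed, round index)`, so
#' a round is reproducible in isolation (and a persisted state can be
#' resumed bit-identically).
#'
#' @param state a `round_state`.
#' @param config a [loop_config()].
#' @param responder function `(settings_df, n_reps) -> data frame` with
#'   `response`, `replicate_sd`, `n_reps` columns (see
#'   [oracle_responder()]). May return fewer rows than the batch; the
#'   round then proceeds with what returned, with a warning.
#' @return The new `round_state`.
#' @export
run_round <- function(state, config, responder) {
  rnd <- state$round + 1L
  rs <- round_seed(config$seed, rnd)
  report <- nested_cv(state$data, config$space, config$registry,
                      config$outer_folds, config$inner_folds, seed = rs)
  surr <- fit_surrogate(state$data, config$space, report, config$registry,
                        ensemble = config$ensemble, seed = rs)
  anchor <- to_coded(config$space, unlist(state$best$settings))
  batch <- propose_batch(surr, config$space,
                         n_iterations = config$n_iterations,
                         batch_size = config$batch_size,
                         min_distance = config$min_distance,
                         kappa = config$kappa, anchor = anchor, seed = rs)
  settings <- as.data.frame(batch)[, factor_names(config$space),
                                   drop = FALSE]
  resp <- responder(settings, config$n_reps)
  if (nrow(resp) < nrow(settings)) {
    warning(sprintf("responder answered %d of %d proposals; proceeding",
                    nrow(resp), nrow(settings)), call. = FALSE)
    settings <- settings[seq_len(nrow(resp)), , drop = FALSE]
  }
  new_rows <- experiment_table(
    settings, response = resp$response, replicate_sd = resp$replicate_sd,
    n_reps = resp$n_reps,
    run_id = sprintf("r%d_%02d", rnd, seq_len(nrow(settings))),
    round_id = rnd)
  data <- append_runs(state$data, new_rows)
  best_old <- state$best$response
  bi <- best_trial(new_rows)
  best <- state$best
  if (!is.na(bi$response) && bi$response > best_old)
    best <- list(settings = as.list(settings[bi$index, ]),
                 response = bi$response)
  improvement <- (best$response - best_old) / best_old
  structure(list(round = rnd, data = data, best = best,
                 history = c(state$history, improvement),
                 cv_report = report, batch = batch),
            class = "round_state")
}

#' Convergence rule for the loop
#'
#' Converged when the last `patience` relative improvements of the
#' best-so-far response are all strictly below `threshold`.
#'
#' @param history numeric vector of per-round relative improvements.
#' @param threshold relative improvement threshold (default 0.02).
#' @param patience consecutive quiet rounds required (default 2).
#' @return Logical flag.
#' @export
check_convergence <- function(history, threshold = 0.02, patience = 2) {
  if (length(history) < patience) return(FALSE)
  all(utils::tail(history, patience) < threshold)
}

#' Run the closed active-learning loop
#'
#' Iterates [run_round()] from an initial dataset until
#' [check_convergence()] fires or `max_rounds` is reached, optionally
#' persisting a JSON state snapshot per round.
#'
#' @param initial_data an [experiment_table()] with responses, or a
#'   `round_state`.
#' @param config a [loop_config()].
#' @param responder see [run_round()].
#' @param max_rounds overrides `config$max_rounds` when given.
#' @param outdir optional directory for per-round `state_<k>.json` files.
#' @return The final `round_state`, with an `audit` attribute: one entry
#'   per executed round recording the round index, selected model, batch
#'   size answered and best-so-far.
#' @export
run_loop <- function(initial_data, config, responder, max_rounds = NULL,
                     outdir = NULL) {
  if (is.null(max_rounds)) max_rounds <- config$max_rounds
  state <- if (inherits(initial_data, "round_state")) initial_data
           else round_state(initial_data)
  audit <- list()
  while (state$round < max_rounds &&
         !check_convergence(state$history, config$threshold,
                            config$patience)) {
    state <- run_round(state, config, responder)
    audit[[length(audit) + 1L]] <- list(
      round = state$round,
      selected_model = state$cv_report$selected,
      n_added = sum(state$data$round_id == state$round),
      best_response = state$best$response)
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      write_round_state(state,
                        file.path(outdir,
                                  sprintf("state_%d.json", state$round)))
    }
  }
  attr(state, "audit") <- audit
  state
}

#' Persist / restore a round state as JSON
#'
#' Serializes the cumulative experiment table, round index, best-so-far
#' and improvement history (the fields needed to resume the loop; the CV
#' report and batch of the persisted round are recomputable from the
#' per-round seed).
#'
#' @param state a `round_state`.
#' @param path JSON file path.
#' @return `read_round_state` returns a `round_state` equivalent for
#'   resumption.
#' @export
write_round_state <- function(state, path) {
  payload <- list(round = state$round,
                  factors = attr(state$data, "factors"),
                  data = as.data.frame(state$data),
                  best = state$best,
                  history = state$history)
  # 17 significant digits: doubles survive the JSON roundtrip exactly,
  # which crash-safe resume relies on
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname write_round_state
#' @export
read_round_state <- function(path) {
  p <- jsonlite::fromJSON(path)
  df <- as.data.frame(p$data)
  tab <- experiment_table(df[, p$factors, drop = FALSE],
                          response = df$response,
                          replicate_sd = df$replicate_sd,
                          n_reps = df$n_reps, run_id = df$run_id,
                          round_id = df$round_id)
  structure(list(round = as.integer(p$round), data = tab,
                 best = list(settings = as.list(p$best$settings),
                             response = as.numeric(p$best$response)),
                 history = as.numeric(p$history),
                 cv_report = NULL, batch = NULL),
            class = "round_state")
}

#' @export
print.round_state <- function(x, ...) {
  cat(sprintf(
    "Round %d: %d cumulative runs, best-so-far %.2f mg/L\n",
    x$round, nrow(x$data), x$best$response))
  invisible(x)
}

#' Synthetic-mode initial dataset
#'
#' Emulates the study's initialization: a 20-run two-level screen at the
#' screening levels plus the 5-trial ascent path, all measured by the
#' synthetic oracle. Ascent factors not on the path are held at the
#' screening center.
#'
#' @param oracle an oracle over [default_bounds_space()] factors.
#' @param screen_space [factor_space()] of screening low/high levels
#'   (default: the packaged 13-factor screen).
#' @param n_reps replicates per run.
#' @return An [experiment_table()] with 25 rows at `round_id = 0`.
#' @export
initial_synthetic_data <- function(oracle,
                                   screen_space = load_fixture("pb_factors"),
                                   n_reps = 3) {
  design <- pb_design(n_factors(screen_space), 20,
                      factor_names(screen_space))
  nat <- to_natural(screen_space, design_matrix(design))
  ascent <- load_fixture("ascent_trials")
  center <- stats::setNames((screen_space$low + screen_space$high) / 2,
                            factor_names(screen_space))
  am <- matrix(rep(center, each = nrow(ascent)), nrow(ascent),
               dimnames = list(NULL, names(center)))
  for (nm in attr(ascent, "factors")) am[, nm] <- ascent[[nm]]
  settings <- rbind(as.data.frame(nat), as.data.frame(am))
  resp <- oracle_query(oracle, settings, n_reps)
  experiment_table(settings, response = resp$response,
                   replicate_sd = resp$replicate_sd, n_reps = resp$n_reps,
                   run_id = c(sprintf("screen_%02d", 1:20),
                              sprintf("ascent_%02d", seq_len(nrow(ascent)))),
                   round_id = 0L)
}
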