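#' Direction of steepest ascent from a screening fit
#'
#' The first-order model's gradient in coded space is the coefficient
#' vector; restricted to the chosen factors and normalized to unit length
#' it gives the direction along which predicted response increases
#' fastest. Each component keeps the sign of its coefficient, so factors
#' with negative coefficients are walked downward.
#'
#' @param result a `pb_screening`.
#' @param factors character vector of factor names to move (typically
#'   [select_significant()]); others are held fixed.
#' @return Named unit-length numeric vector (coded units per step).
#' @export
ascent_direction <- function(result, factors = select_significant(result)) {
  unknown <- setdiff(factors, names(result$coefficients))
  if (length(unknown))
    stop("unknown factor(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  v <- result$coefficients[factors]
  nrm <- sqrt(sum(v^2))
  if (nrm == 0)
    stop("all selected coefficients are zero; ascent direction undefined",
         call. = FALSE)
  v / nrm
}

#' Natural-unit step sizes along an ascent direction
#'
#' Helper converting a coded-space direction into per-factor natural-unit
#' steps: `step_i = base_step * direction_i * halfrange_i`, optionally
#' rounded per factor. The published ascent tables used manually rounded
#' steps, so steps can always be supplied directly to [ascent_path()]
#' instead.
#'
#' @param space a [factor_space()] covering the direction's factors.
#' @param direction named coded-space direction (e.g. [ascent_direction()]).
#' @param base_step scalar multiplier in coded units per trial.
#' @param digits optional named integer vector of decimals per factor.
#' @return Named numeric vector of signed natural-unit steps.
#' @export
ascent_steps <- function(space, direction, base_step = 1, digits = NULL) {
  idx <- match(names(direction), factor_names(space))
  if (anyNA(idx))
    stop("direction names missing from factor space", call. = FALSE)
  halfrange <- (space$high - space$low)[idx] / 2
  st <- base_step * direction * halfrange
  if (!is.null(digits)) {
    d <- digits[names(direction)]
    st <- mapply(function(v, k) if (is.na(k)) v else round(v, k), st, d)
  }
  stats::setNames(as.numeric(st), names(direction))
}

#' Build a steepest-ascent trial path
#'
#' Trial i (i = 0 .. n_trials-1) sits at `center + i * step` in natural
#' units, with optional per-factor rounding applied after the affine
#' formula. Factors absent from `step` stay at their center value.
#'
#' @param center named numeric vector: starting settings (natural units).
#' @param step named numeric vector of signed per-trial increments; names
#'   must be a subset of `names(center)`.
#' @param n_trials number of trials (>= 1), including the center trial.
#' @param digits optional named integer vector of decimals per factor,
#'   applied last.
#' @return An [experiment_table()] with `n_trials` rows (responses `NA`,
#'   ready for the lab or for [oracle_query()]), `round_id = 0`.
#' @examples
#' ascent_path(c(ZmPAL = 2.25, GmCHS = 1.25),
#'             c(ZmPAL = 0.45, GmCHS = -0.25), n_trials = 5)
#' @export
ascent_path <- function(center, step, n_trials, digits = NULL) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  missing <- setdiff(names(step), names(center))
  if (length(missing))
    stop("step factor(s) not in center: ", paste(missing, collapse = ", "),
         call. = FALSE)
  full_step <- stats::setNames(numeric(length(center)), names(center))
  full_step[names(step)] <- step
  i <- seq_len(n_trials) - 1
  m <- outer(rep(1, n_trials), center) + outer(i, full_step)
  colnames(m) <- names(center)
  if (!is.null(digits)) {
    for (nm in intersect(names(digits), colnames(m)))
      m[, nm] <- round(m[, nm], digits[[nm]])
  }
  experiment_table(as.data.frame(m),
                   run_id = sprintf("trial_%02d", seq_len(n_trials)))
}

#' Best trial of an evaluated path
#'
#' @param path an [experiment_table()] (or data frame with a `response`
#'   column) where at least one response is present.
#' @return List with `index` (row number of the maximum response; ties go
#'   to the lowest index), `run_id` (if present) and `response`.
#' @export
best_trial <- function(path) {
  y <- path$response
  if (all(is.na(y)))
    stop("no responses present; cannot pick best trial", call. = FALSE)
  idx <- which.max(ifelse(is.na(y), -Inf, y))
  list(index = idx,
       run_id = if (!is.null(path$run_id)) path$run_id[idx] else NA,
       response = y[idx])
}
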