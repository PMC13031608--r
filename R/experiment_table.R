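#' Build an experiment table
#'
#' The experiment table is the common currency between pipeline stages: one
#' row per run, with the factor settings in natural units, the measured
#' mean response in mg/L (or `NA` while the run is pending), the replicate
#' standard deviation and the replicate count.
#'
#' @param settings data frame or matrix of factor settings (one column per
#'   factor, natural units).
#' @param response numeric vector of mean responses in mg/L; `NA` for runs
#'   not yet measured. Must be non-negative where present.
#' @param replicate_sd numeric vector of replicate standard deviations
#'   (mg/L); `NA` when unknown.
#' @param n_reps integer vector (or scalar) of replicate counts, >= 1.
#' @param run_id character vector of run identifiers; generated when `NULL`.
#' @param round_id integer vector (or scalar) >= 0 tagging the optimization
#'   round that produced each run (0 = initial data).
#' @param space optional [factor_space()]; when supplied, settings columns
#'   are checked against it and reordered to match.
#'
#' @return An object of class `experiment_table` (a data frame with columns
#'   `run_id`, `round_id`, one column per factor, `response`,
#'   `replicate_sd`, `n_reps`; factor columns listed in
#'   `attr(x, "factors")`).
#' @export
experiment_table <- function(settings, response = NA_real_,
                             replicate_sd = NA_real_, n_reps = 1L,
                             run_id = NULL, round_id = 0L, space = NULL) {
  settings <- as.data.frame(settings)
  if (!is.null(space)) {
    m <- settings_matrix(space, settings)
    settings <- as.data.frame(m)
  }
  n <- nrow(settings)
  response <- rep_len(as.numeric(response), n)
  replicate_sd <- rep_len(as.numeric(replicate_sd), n)
  n_reps <- rep_len(as.integer(n_reps), n)
  round_id <- rep_len(as.integer(round_id), n)
  if (is.null(run_id)) run_id <- sprintf("run_%03d", seq_len(n))
  run_id <- rep_len(as.character(run_id), n)
  if (any(!is.na(response) & response < 0))
    stop("responses must be >= 0 where present", call. = FALSE)
  if (any(n_reps < 1L)) stop("n_reps must be >= 1", call. = FALSE)
  if (any(round_id < 0L)) stop("round_id must be >= 0", call. = FALSE)
  out <- cbind(data.frame(run_id = run_id, round_id = round_id,
                          stringsAsFactors = FALSE),
               settings,
               data.frame(response = response, replicate_sd = replicate_sd,
                          n_reps = n_reps))
  attr(out, "factors") <- colnames(settings)
  class(out) <- c("experiment_table", "data.frame")
  out
}

#' @export
print.experiment_table <- function(x, ...) {
  fx <- attr(x, "factors")
  done <- sum(!is.na(x$response))
  cat(sprintf("Experiment table: %d run%s, %d factor%s, %d with responses\n",
              nrow(x), if (nrow(x) == 1) "" else "s",
              length(fx), if (length(fx) == 1) "" else "s", done))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract the factor-setting columns of an experiment table
#'
#' @param table an [experiment_table()].
#' @return Data frame of the factor columns only.
#' @export
table_settings <- function(table) {
  fx <- attr(table, "factors")
  if (is.null(fx))
    fx <- setdiff(colnames(table),
                  c("run_id", "round_id", "response", "replicate_sd",
                    "n_reps"))
  as.data.frame(table)[, fx, drop = FALSE]
}

#' Append runs to an experiment table
#'
#' @param table an [experiment_table()].
#' @param new an [experiment_table()] over the same factors.
#' @return The combined table; factor sets must match.
#' @export
append_runs <- function(table, new) {
  f1 <- attr(table, "factors"); f2 <- attr(new, "factors")
  if (!identical(f1, f2))
    stop("factor columns differ between tables", call. = FALSE)
  out <- rbind(as.data.frame(table), as.data.frame(new))
  rownames(out) <- NULL
  attr(out, "factors") <- f1
  class(out) <- c("experiment_table", "data.frame")
  out
}

#' Read and write experiment tables as CSV
#'
#' CSV dialect: comma separator, UTF-8, "." decimal, mandatory header,
#' missing values as empty cells. Columns: `run_id`, `round_id`, one column
#' per factor, `response`, `replicate_sd`, `n_reps`. The roundtrip
#' write-then-read is lossless, including missing responses.
#'
#' @param path CSV file path.
#' @param space optional [factor_space()] used to validate/order the factor
#'   columns.
#' @return `read_experiment_table` returns an [experiment_table()].
#' @export
read_experiment_table <- function(path, space = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  need <- c("run_id", "round_id", "response", "replicate_sd", "n_reps")
  miss <- setdiff(need, colnames(raw))
  if (length(miss))
    stop("experiment CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  fx <- setdiff(colnames(raw), need)
  numcols <- c(fx, "round_id", "response", "replicate_sd", "n_reps")
  conv <- raw
  for (cn in numcols) {
    v <- trimws(raw[[cn]])
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop(sprintf("malformed numeric value %s in row %d, column '%s' of %s",
                   dQuote(v[bad[1]]), bad[1], cn, path), call. = FALSE)
    conv[[cn]] <- num
  }
  experiment_table(settings = conv[, fx, drop = FALSE],
                   response = conv$response,
                   replicate_sd = conv$replicate_sd,
                   n_reps = ifelse(is.na(conv$n_reps), 1L,
                                   as.integer(conv$n_reps)),
                   run_id = raw$run_id,
                   round_id = as.integer(conv$round_id),
                   space = space)
}

#' @rdname read_experiment_table
#' @param table an [experiment_table()] to write.
#' @export
write_experiment_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}
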