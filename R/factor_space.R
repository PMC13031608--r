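#' Define a factor space for two-level experimental design
#'
#' A factor space is an ordered set of reaction factors, each with units and
#' a low/high level in natural units. The low and high levels carry the
#' two-level coding convention: coded -1 at `low`, coded +1 at `high`,
#' linearly extrapolated outside that interval.
#'
#' @param name character vector of unique factor names.
#' @param units character vector of unit labels (e.g. "mg/mL", "mM", "uL",
#'   "degC", "h", "pH", or "" for dimensionless).
#' @param low,high numeric vectors of the two levels in natural units;
#'   `low < high` elementwise.
#'
#' @return An object of class `factor_space`: a data frame with columns
#'   `name`, `units`, `low`, `high`, one row per factor. Row order is
#'   significant and preserved by all downstream operations.
#' @examples
#' fs <- factor_space(c("pH", "volume"), c("pH", "uL"), c(6, 50), c(8, 75))
#' to_coded(fs, c(pH = 7, volume = 75))
#' @export
factor_space <- function(name, units, low, high) {
  name <- as.character(name)
  units <- as.character(units)
  low <- as.numeric(low)
  high <- as.numeric(high)
  n <- length(name)
  if (length(units) != n || length(low) != n || length(high) != n)
    stop("factor_space: name, units, low, high must have equal length",
         call. = FALSE)
  if (n < 1L) stop("factor_space: at least one factor required", call. = FALSE)
  if (anyDuplicated(name))
    stop("factor_space: duplicate factor names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  if (any(!is.finite(low)) || any(!is.finite(high)))
    stop("factor_space: levels must be finite", call. = FALSE)
  bad <- which(low >= high)
  if (length(bad))
    stop("factor_space: low_level must be < high_level for: ",
         paste(name[bad], collapse = ", "), call. = FALSE)
  out <- data.frame(name = name, units = units, low = low, high = high,
                    stringsAsFactors = FALSE)
  class(out) <- c("factor_space", "data.frame")
  out
}

#' @export
print.factor_space <- function(x, ...) {
  cat(sprintf("Factor space with %d factor%s (coded -1 at low, +1 at high)\n",
              nrow(x), if (nrow(x) == 1) "" else "s"))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @rdname factor_space
#' @param space a `factor_space`.
#' @export
factor_names <- function(space) space$name

#' @rdname factor_space
#' @export
n_factors <- function(space) nrow(space)

# Coerce settings (named vector, list, data.frame/matrix with factor columns)
# to a runs x factors numeric matrix in the space's column order.
settings_matrix <- function(space, settings) {
  nm <- factor_names(space)
  if (is.null(dim(settings))) {
    settings <- as.list(settings)
    missing <- setdiff(nm, names(settings))
    unknown <- setdiff(names(settings), nm)
    if (length(unknown))
      stop("unknown factor name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (length(missing))
      stop("missing factor(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    m <- matrix(as.numeric(unlist(settings[nm])), nrow = 1,
                dimnames = list(NULL, nm))
  } else {
    settings <- as.data.frame(settings)
    unknown <- setdiff(colnames(settings), nm)
    keep <- intersect(colnames(settings), nm)
    missing <- setdiff(nm, keep)
    if (length(missing))
      stop("missing factor column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    m <- as.matrix(settings[, nm, drop = FALSE])
    storage.mode(m) <- "double"
  }
  m
}

#' Convert natural-unit settings to coded units
#'
#' Coded value = 2 * (v - center) / range with center = (low + high) / 2,
#' so the low level maps to -1 and the high level to +1. Values outside the
#' [low, high] interval extrapolate linearly beyond +/-1.
#'
#' @param space a [factor_space()].
#' @param settings a named numeric vector covering every factor, or a data
#'   frame / matrix with one column per factor (extra columns are ignored
#'   for data frames; unknown names in a vector are an error).
#' @return A numeric matrix (runs x factors) of coded values; a single
#'   named vector in gives a 1-row matrix.
#' @seealso [to_natural()] for the exact inverse.
#' @export
to_coded <- function(space, settings) {
  m <- settings_matrix(space, settings)
  center <- (space$low + space$high) / 2
  halfrange <- (space$high - space$low) / 2
  sweep(sweep(m, 2, center, "-"), 2, halfrange, "/")
}

#' Convert coded values back to natural units
#'
#' Exact inverse of [to_coded()]: v = center + coded * (high - low) / 2.
#'
#' @param space a [factor_space()].
#' @param coded numeric vector of length `n_factors(space)` (in factor
#'   order) or a matrix with that many columns.
#' @return A numeric matrix (runs x factors) of natural-unit values with
#'   factor names as columns.
#' @export
to_natural <- function(space, coded) {
  if (is.null(dim(coded))) {
    if (length(coded) != n_factors(space))
      stop("coded vector length ", length(coded), " != factor count ",
           n_factors(space), call. = FALSE)
    coded <- matrix(as.numeric(coded), nrow = 1)
  } else {
    coded <- as.matrix(coded)
    if (ncol(coded) != n_factors(space))
      stop("coded matrix has ", ncol(coded), " columns; expected ",
           n_factors(space), call. = FALSE)
    storage.mode(coded) <- "double"
  }
  center <- (space$low + space$high) / 2
  halfrange <- (space$high - space$low) / 2
  out <- sweep(sweep(coded, 2, halfrange, "*"), 2, center, "+")
  colnames(out) <- factor_names(space)
  out
}

#' Read or write a factor-space definition
#'
#' The on-disk format is a JSON (or YAML) array of objects with fields
#' `name`, `units`, `low`, `high`.
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_factor_space` returns a [factor_space()];
#'   `write_factor_space` invisibly returns `path`.
#' @export
read_factor_space <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rec <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML factor files", call. = FALSE)
    do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))
  } else {
    jsonlite::fromJSON(path)
  }
  need <- c("name", "units", "low", "high")
  if (!all(need %in% names(rec)))
    stop("factor file must provide fields: ", paste(need, collapse = ", "),
         call. = FALSE)
  factor_space(rec$name, rec$units, rec$low, rec$high)
}

#' @rdname read_factor_space
#' @param space a [factor_space()] to serialize.
#' @export
write_factor_space <- function(space, path) {
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(unclass(space), stringsAsFactors = FALSE)
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to write YAML factor files", call. = FALSE)
    yaml::write_yaml(lapply(seq_len(nrow(df)), function(i) as.list(df[i, ])),
                     path)
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
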