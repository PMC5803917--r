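#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom data.table data.table dcast
#' @importFrom stats median
NULL

# Classed conditions so callers (and the CLI) can map failures to exit codes.
abort_parse <- function(msg, ...) {
  abort(msg, class = c("skinora_parse_error", "skinora_error"), ...)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = c("skinora_validation_error", "skinora_error"), ...)
}

abort_config <- function(msg, ...) {
  abort(msg, class = c("skinora_config_error", "skinora_error"), ...)
}

abort_data <- function(msg, ...) {
  abort(msg, class = c("skinora_data_error", "skinora_error"), ...)
}

abort_design <- function(msg, ...) {
  abort(msg, class = c("skinora_design_error", "skinora_error"), ...)
}

abort_network <- function(msg, ...) {
  abort(msg, class = c("skinora_network_error", "skinora_error"), ...)
}

# Uniform integer draw on [lo, hi]; safe when lo == hi (unlike sample()).
runif_int <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Median with the even-count convention made explicit: arithmetic mean of the
# two central order statistics (stats::median's default, relied on throughout).
mid_median <- function(x) stats::median(x, na.rm = FALSE)

assert_fraction <- function(x, name, allow_zero = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || x > 1) {
    abort_config(sprintf("`%s` must be a single fraction in %s, got %s",
                         name, if (allow_zero) "[0, 1]" else "(0, 1]",
                         deparse(x)))
  }
  invisible(x)
}

sample_columns <- function(df, id_col) {
  setdiff(names(df), id_col)
}

check_wide_matrix <- function(df, id_col, what) {
  if (!is.data.frame(df)) {
    abort_data(sprintf("%s must be a data frame with a `%s` column", what, id_col))
  }
  if (!id_col %in% names(df)) {
    abort_data(sprintf("%s is missing the `%s` identifier column", what, id_col))
  }
  ids <- df[[id_col]]
  if (anyDuplicated(ids)) {
    abort_data(sprintf("%s has duplicated `%s` values (e.g. %s)", what, id_col,
                       ids[duplicated(ids)][1L]))
  }
  invisible(df)
}
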