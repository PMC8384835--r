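#' @importFrom rlang %||% .data
#' @importFrom dplyr %>%
NULL

# validate a data frame has the given columns, with a readable error
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

# run `expr` under a fixed seed when `seed` is given, otherwise use the
# current RNG stream (lets callers embed seeded pieces in a larger stream)
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
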