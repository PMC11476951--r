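# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` uses banker's rounding; reported percentages follow the
#' conventional half-up rule instead (12.95 -> 13.0).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))

assert_df_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_arg(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}
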