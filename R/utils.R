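`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if_not <- function(cond, ..., class = "bioagerisk_error") {
  if (!isTRUE(cond)) {
    stop(structure(
      class = c(class, "error", "condition"),
      list(message = paste0(...), call = sys.call(-1))
    ))
  }
  invisible(TRUE)
}

assert_finite <- function(x, what) {
  stop_if_not(all(is.finite(x)), what, " must be finite",
              class = "bioagerisk_config_error")
}

assert_cols <- function(data, cols, what = "cohort") {
  missing <- setdiff(cols, names(data))
  stop_if_not(length(missing) == 0L,
              what, " is missing required column(s): ",
              paste(missing, collapse = ", "),
              class = "bioagerisk_schema_error")
}

# sample quantiles under the declared convention (linear interpolation
# between order statistics, stats::quantile type 7)
panel_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = TRUE)
}
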