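# Input validation helpers shared across the package. All user-facing errors
# carry class "diatomccm_error" (plus "diatomccm_config_error" for config
# parsing) so callers and the CLI can catch them reliably.

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE,
                         scalar = FALSE) {
  if (!is.numeric(x) || length(x) == 0L) {
    abort_invalid(sprintf("`%s` must be numeric and non-empty.", name))
  }
  if (scalar && length(x) != 1L) {
    abort_invalid(sprintf("`%s` must be a single number.", name))
  }
  if (any(!is.finite(x))) {
    abort_invalid(sprintf("`%s` must be finite (got non-finite value).", name))
  }
  low_ok <- if (allow_lower) x >= lower else x > lower
  high_ok <- if (allow_upper) x <= upper else x < upper
  if (any(!low_ok) || any(!high_ok)) {
    abort_invalid(sprintf(
      "`%s` must be in %s%g, %g%s (got %g).",
      name,
      if (allow_lower) "[" else "(", lower, upper,
      if (allow_upper) "]" else ")",
      x[which(!(low_ok & high_ok))[1L]]
    ))
  }
  invisible(x)
}

abort_invalid <- function(msg) {
  rlang::abort(msg, class = "diatomccm_error")
}

# Recycle length-1 arguments against the longest one; error on ragged lengths.
recycle_args <- function(...) {
  args <- list(...)
  lens <- lengths(args)
  n <- max(lens)
  if (any(lens != 1L & lens != n)) {
    abort_invalid(sprintf(
      "Arguments must have length 1 or a common length (got lengths %s).",
      paste(lens, collapse = ", ")
    ))
  }
  lapply(args, rep_len, n)
}

# Pull a column from `data` if present, otherwise fall back to the default.
col_or_default <- function(data, name, default) {
  if (!is.null(data) && name %in% names(data)) data[[name]] else default
}
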