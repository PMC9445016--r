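# Internal helpers shared across modules.

# Classed errors so callers can distinguish bad input from degenerate data.
mvh_stop <- function(message, class = "mvh_input_error", call. = FALSE) {
  stop(errorCondition(message, class = c(class, "mvh_error")))
}

mvh_check_numeric <- function(x, name) {
  if (!is.numeric(x)) {
    mvh_stop(sprintf("'%s' must be numeric", name))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    mvh_stop(sprintf("'%s' contains missing or non-finite values", name))
  }
  invisible(x)
}

# Deterministic sub-seed derivation; keeps every draw traceable to one cohort
# seed while staying inside 32-bit integer range.
derive_seed <- function(base, offset) {
  as.integer((as.numeric(base) + as.numeric(offset)) %% 2147483629)
}

# %.17g survives a text round trip bit-exactly for doubles.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# write a data.frame as CSV with full-precision numerics and stable ordering
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}
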