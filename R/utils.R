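# Shared internal helpers.

# Round half away from zero (printed tables use half-up, base round() is
# half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic per-patient seed derived from (master seed, patient id),
# so the draws for one patient never depend on how many other patients
# are simulated or in what order.  Knuth multiplicative hash kept inside
# the 32-bit integer range R's set.seed() accepts.
patient_seed <- function(seed, id) {
  as.integer((as.numeric(seed) + as.numeric(id) * 2654435761) %% 2147483647)
}

# column-presence contract shared by all table-consuming functions
check_columns <- function(df, cols, table_name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("table `%s` is missing required column(s): %s",
                  table_name, paste(missing, collapse = ", ")),
          class = "dx_schema_error")
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
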