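# Internal helpers shared across modules.

# Monday of the ISO week containing `date`.
week_start <- function(date) {
  date <- as.Date(date)
  date - (as.integer(format(date, "%u")) - 1L)
}

# Normalise a `risks` column to a list of character vectors.  Accepts a
# list-column, a character vector with ";"-separated names, or NA/"" for none.
as_risk_list <- function(risks) {
  if (is.list(risks)) {
    return(lapply(risks, function(r) {
      if (length(r) == 0 || all(is.na(r))) character(0) else as.character(r)
    }))
  }
  lapply(as.character(risks), function(r) {
    if (is.na(r) || !nzchar(trimws(r))) return(character(0))
    trimws(strsplit(r, ";", fixed = TRUE)[[1]])
  })
}

# ";"-joined representation for CSV output.
risk_string <- function(risks) {
  vapply(as_risk_list(risks), paste, character(1), collapse = ";")
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Evaluate `expr` under a fixed seed when one is given, without touching the
# caller's RNG stream; with seed = NULL the current stream is used.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# Integer day difference to - from.
days_between <- function(from, to) {
  as.integer(round(as.numeric(difftime(as.Date(to), as.Date(from), units = "days"))))
}
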