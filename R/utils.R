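# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_cols <- function(df, cols, what) {
  if (!is.data.frame(df)) stop(what, " must be a data frame")
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

# phenotype term sets travel as ";"-separated strings in tabular files
split_terms <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    unique(trimws(strsplit(s, ";", fixed = TRUE)[[1L]]))
  })
}

join_terms <- function(terms) {
  vapply(terms, function(t) paste(t, collapse = ";"), character(1))
}

# derive a bounded child seed from a user seed (keeps within 32-bit range)
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
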