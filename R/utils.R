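# Account tables print integers rounded half-away-from-zero (commercial
# rounding), not banker's rounding as in base round().
round_half_away <- function(x) {
  ifelse(is.na(x), NA_real_, sign(x) * floor(abs(x) + 0.5))
}

# NA -> empty cell in serialized accounts (absent/unknown, never 0)
fmt_cell <- function(x) {
  ifelse(is.na(x), "", format(x, scientific = FALSE, trim = TRUE))
}

write_csv_commented <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

# evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched, so generators are pure functions of their seed
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
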