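`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a temporarily-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# canonical junction identity used for all set operations
junction_key <- function(x, stranded = TRUE) {
  if (stranded) paste(x$contig, x$start, x$end, x$strand, sep = ":")
  else paste(x$contig, x$start, x$end, sep = ":")
}

stopifnot_cols <- function(df, cols, what = "junction table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}
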