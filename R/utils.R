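# Internal helpers.

# Run `expr` under a given RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Case-insensitive channel lookup; returns indices into `have`, errors on
# labels that are absent.
matchChannels <- function(want, have) {
  idx <- match(tolower(want), tolower(have))
  if (anyNA(idx))
    stop("unknown channel label(s): ", paste(want[is.na(idx)], collapse = ", "))
  idx
}

# Round half up to a multiple of `unit` (floor(x/unit + 0.5) * unit), with a
# tiny epsilon so that binary representations of decimal inputs do not fall
# on the wrong side of an exact half.
roundHalfUp <- function(x, unit) {
  floor(x / unit + 0.5 + 1e-9) * unit
}

`%||%` <- function(a, b) if (is.null(a)) b else a
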