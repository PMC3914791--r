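#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Used to give every synthetic output its own
# reproducible stream derived from a master seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

# Derive a sub-stream seed from a master seed; keeps results stable when new
# streams are added (stream index, not call order, defines the seed).
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9973L) %% 2147483647L
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Collapse a character vector of flags into the single comma-separated flag
# field carried on record tibbles ("" when none).
flag_string <- function(flags) {
  flags <- flags[nzchar(flags)]
  if (length(flags) == 0) "" else paste(unique(flags), collapse = ",")
}

add_flag <- function(existing, flag) {
  parts <- unlist(strsplit(existing %||% "", ",", fixed = TRUE))
  flag_string(c(parts, flag))
}

has_flag <- function(flags, flag) {
  vapply(strsplit(flags, ",", fixed = TRUE), function(p) flag %in% p, logical(1))
}
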