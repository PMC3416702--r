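# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Check a scalar is a single finite number satisfying a predicate; used by the
# configuration validators so errors name the offending field.
check_field <- function(value, field, ok, what) {
  if (!ok) stopf("invalid '%s': must be %s (got %s)", field, what,
                 paste(format(value), collapse = ", "))
  invisible(value)
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
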