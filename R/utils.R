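# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single number", name)
  if (strict_lower && x <= lower)
    stopf("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stopf("'%s' must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stopf("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stopf("%s: missing mandatory column '%s'", what, missing[1L])
  invisible(df)
}

# standard 20-letter amino-acid alphabet
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# random CDR3 amino-acid strings, length 8-20; uses the current RNG stream
random_cdr3 <- function(n, min_len = 8L, max_len = 20L) {
  lens <- sample.int(max_len - min_len + 1L, n, replace = TRUE) + min_len - 1L
  vapply(lens, function(l) paste(sample(AA20, l, replace = TRUE), collapse = ""),
         character(1))
}

# unique random CDR3 strings, optionally avoiding an existing set
random_cdr3_unique <- function(n, avoid = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_cdr3(n - length(out))
    cand <- setdiff(unique(cand), c(avoid, out))
    out <- c(out, cand)
  }
  out
}
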