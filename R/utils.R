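`%||%` <- function(a, b) if (is.null(a)) b else a

.assertFlag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", what), call. = FALSE)
  }
  invisible(x)
}

.assertNumber <- function(x, what, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", what, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# deterministic sub-seed derivation; keeps results < 2^31
.deriveSeed <- function(seed, salt) {
  (as.integer(seed) * 1103L + as.integer(salt) * 12347L) %% 2147483629L
}
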