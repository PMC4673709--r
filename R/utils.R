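# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state; seed = NULL leaves the current stream untouched.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Derive a reproducible per-stage seed from a root seed. Keeps results
# below 2^31 - 1 so they remain valid R integers.
substream_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + index) %% 2147483647)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}

assert_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s", name,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Two-sided normal p-value from a z statistic.
z_pvalue <- function(z) 2 * pnorm(-abs(z))
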