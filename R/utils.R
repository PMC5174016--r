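## Internal helpers shared across modules.

# Column of the gene-record table holding the category at a hierarchy level.
level_column <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level != as.integer(level) || level < 1L || level > 4L) {
    stop("`level` must be a single integer in 1..4", call. = FALSE)
  }
  c("h1", "h2", "h3", "fun")[as.integer(level)]
}

assert_positive_int <- function(x, name, allow_zero = FALSE) {
  lo <- if (allow_zero) 0 else 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < lo) {
    stop(sprintf("`%s` must be a single integer >= %d", name, lo), call. = FALSE)
  }
  as.integer(x)
}

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a proportion in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

# Deterministic child seed for a named sub-stream, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() misreads a length-1 numeric vector as 1:n; always index.
draw1 <- function(x) x[sample.int(length(x), 1L)]
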