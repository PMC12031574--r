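# Internal helpers shared across modules.

# Byte-wise (C-locale) lexicographic comparison, independent of the session
# locale so canonical attribute codes are identical across platforms.
lex_gt <- function(a, b) {
  if (a == b) return(FALSE)
  order(c(a, b), method = "radix")[1L] == 2L
}

lex_sort <- function(x) {
  if (length(x) == 0L) return(character(0))
  sort(x, method = "radix")
}

# Pearson correlation that is 0 (not NA) when either side is constant.
safe_cor <- function(x, y) {
  if (length(x) < 2L) return(0)
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(0)
  stats::cor(x, y)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed, kept within 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
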