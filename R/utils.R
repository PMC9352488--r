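# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ps <- function(...) stop(..., call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stop_ps(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_ps(sprintf("'%s' must lie in [0, 1]", name))
  }
  invisible(x)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_ps(sprintf("%s is missing required column(s): %s",
                    what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Derive a reproducible stage seed from a base seed, staying within 32-bit
# integer range.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
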