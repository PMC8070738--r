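# Shared validation helpers and the seed-expansion scheme.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

assert_cols <- function(data, cols, name = deparse(substitute(data))) {
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame", name))
  }
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# One global seed is expanded into independent per-generator child seeds by
# fixed small offsets, so that each generator draws from its own stream while
# the whole run stays reproducible from one integer.  Offsets keep every
# child seed below 2^31.
child_seed <- function(seed, stream) {
  offsets <- c(counts = 11L, go = 23L, ppi = 37L, histone = 41L,
               meiosis = 53L, pipeline = 67L)
  if (!stream %in% names(offsets)) {
    abort(sprintf("unknown seed stream '%s'", stream))
  }
  (as.integer(seed) %% 2000000000L) + offsets[[stream]]
}

# Evaluate `expr` under a local RNG state seeded with `seed` (NULL leaves the
# global stream untouched).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

new_result_tibble <- function(x, class, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- c(class, class(x))
  x
}
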