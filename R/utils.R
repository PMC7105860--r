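# Internal helpers shared across modules.

# Deterministic per-stage seed derived from a global seed. Keeps stages
# statistically independent while fully reproducible; result is always a
# valid 32-bit integer seed.
derive_seed <- function(global_seed, stage) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L)
  chars <- utf8ToInt(as.character(stage))
  h <- as.double(global_seed) %% 2147483647
  for (ch in chars) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# scalar checks used in argument validation
assert_scalar_int <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min))
  }
  as.integer(x)
}

assert_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    if (open) x > 0 && x < 1 else x >= 0 && x < 1
  if (!ok) {
    abort(sprintf("`%s` must be a probability %s.", name,
                  if (open) "in (0, 1)" else "in [0, 1)"))
  }
  as.double(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
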