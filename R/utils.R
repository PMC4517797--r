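# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never disturbs user RNG.
with_preserved_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic integer stream derived from (seed, ...) components, kept below
# 2^31 so it is always a valid set.seed() argument.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    # multiplier small enough that h * 69069 + p stays exact in doubles
    h <- (h * 69069 + (as.numeric(p) %% 2147483647) + 12345) %% 2147483647
  }
  as.integer(h)
}

stop_ebclust <- function(msg, class) {
  abort(msg, class = c(class, "ebclust_error"))
}

check_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop_ebclust(
      sprintf("`%s` must be a single integer >= %d.", name, min),
      "ebclust_bad_argument"
    )
  }
  as.integer(x)
}
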