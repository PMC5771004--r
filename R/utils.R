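# Internal helpers shared across the pipeline.

#' @useDynLib seedscore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so package functions never disturb user-level randomness.
with_rng <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit stream seed from an integer seed plus string parts.
# Polynomial rolling hash mod a prime below 2^31; all intermediates stay well
# below 2^53 so double arithmetic is exact.
stream_seed <- function(seed, ...) {
  p <- 2147483563
  h <- as.numeric(seed) %% p
  for (part in as.character(c(...))) {
    for (v in utf8ToInt(part)) h <- (h * 131 + v) %% p
    h <- (h * 131 + 7) %% p  # separator so c("ab","c") != c("a","bc")
  }
  as.integer(h)
}

# key string used to order and join (seed_id, time_index) pairs
image_key <- function(seed_id, time_index) {
  paste0(seed_id, "#t", time_index)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
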