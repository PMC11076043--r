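# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so simulators are deterministic without mutating global state.
#' `seed = NULL` leaves the RNG alone.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Deterministic per-stage seed derived from a global seed and a stage name
#'
#' Uses a multiplicative congruential mix of the global seed with a polynomial
#' string hash so that adding pipeline stages never shifts the randomness of
#' existing ones. Result is in [1, 2^31 - 2].
#' @noRd
derive_seed <- function(global_seed, stage_name) {
  m <- 2147483647  # 2^31 - 1 (prime)
  h <- 0
  for (b in utf8ToInt(stage_name)) h <- (h * 31 + b) %% m
  s <- (as.numeric(global_seed) %% m) * 48271 %% m
  as.integer((s + h) %% (m - 1) + 1)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  x
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (if (strict) x <= 0 else x < 0))
    stop(sprintf("`%s` must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  x
}
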