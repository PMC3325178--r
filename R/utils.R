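# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stopf("'%s' must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ","))
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stopf("'%s' must be a single finite number in [%s, %s]", name,
          format(min), format(max))
  as.numeric(x)
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a small integer offset to a new
#' seed below 2^31, so that every stage of a study draws from its own stream
#' while the whole analysis is reproduced by a single integer.
#'
#' @param seed Master integer seed.
#' @param stage Non-negative integer offset identifying the stage.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage = 0L) {
  seed <- check_count(seed, "seed", min = 0L)
  stage <- check_count(stage, "stage", min = 0L)
  # Lehmer-style mix in double precision (exact below 2^53); prime modulus 2^31 - 1
  mixed <- ((as.double(seed) %% 2147483646 + 1) * 48271 +
              104729 * as.double(stage)) %% 2147483647
  as.integer(mixed)
}

# deterministic ordering helper: radix sort is locale-independent
order_det <- function(...) order(..., method = "radix")
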