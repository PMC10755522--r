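# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `code`,
#' and restores the previous state, so seeded package functions never disturb
#' the session RNG stream.
#' @noRd
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Polynomial rolling hash over integer bytes; exact in double arithmetic
# (intermediate values stay far below 2^53), so identical on every platform.
roll_hash <- function(bytes) {
  h <- 2166136261 %% 2147483647
  for (b in as.integer(bytes)) {
    h <- (h * 31 + b) %% 2147483647
  }
  h
}

#' Derive a stage seed from a global seed and a label
#'
#' Deterministically maps `(seed, tag)` to an integer in `[1, 2^31 - 2]` so
#' every stochastic stage of a run gets its own reproducible stream.
#' @param seed integer global seed.
#' @param tag character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  bytes <- utf8ToInt(paste0(format(seed, scientific = FALSE), "/", tag))
  as.integer(roll_hash(bytes) %% (2^31 - 2) + 1)
}

# Content fingerprint of an R object (serialization-based FNV-1a, hex string).
object_fingerprint <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  # fold to 32 bits over at most 64k bytes for speed; prefix with length
  raw <- raw[seq_len(min(length(raw), 65536L))]
  sprintf("%08x", roll_hash(as.integer(raw)))
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a probability in [0, 1]")
  invisible(x)
}

check_finite <- function(x, field) {
  if (!all(is.finite(x))) stop_field(field, "must be finite")
  invisible(x)
}
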