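# Internal helpers shared across modules.

#' Evaluate code with a temporarily seeded RNG
#'
#' Saves and restores `.Random.seed` so that seeded operations inside the
#' package do not disturb the caller's RNG stream. A `NULL` seed leaves the
#' current stream untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation so one user-facing seed can drive
# independent generator components (sequence, responses, network, noise).
# Values stay below 2^31 - 1.
derive_seed <- function(seed, ...) {
  if (is.null(seed)) {
    return(NULL)
  }
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + (as.numeric(p) %% 2147483647)) %% 2147483647
  }
  as.integer(h %% .Machine$integer.max) + 1L
}

# FNV-1a hash of a character representation; used to stamp outputs with a
# short configuration fingerprint without an external digest dependency.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  x
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a whole number >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  as.numeric(x)
}
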