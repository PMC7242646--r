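# Internal helpers shared across modules.

DEG <- 180 / pi

deg2rad <- function(x) x / DEG
rad2deg <- function(x) x * DEG

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Unsigned angle between two vectors, in degrees, in [0, 180].
angle_between_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  rad2deg(acos(clamp(ca, -1, 1)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-unit seed derived from a base seed; stays inside the
# 32-bit signed integer range R requires of set.seed().
derive_seed <- function(base, offset) {
  s <- (as.double(base) * 48271 + as.double(offset) * 7919) %% 2147483587
  as.integer(s) + 1L
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
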