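# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed without disturbing the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and one or more indices, kept inside
# the 32-bit signed range. Deterministic and collision-sparse for the small
# index ranges used here.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  }
  as.integer(s)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# round-half-up to `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x == as.integer(x) && x >= 0

is_fraction <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 0 && x <= 1

# Quantize [0,1] intensities to the 8-bit grid. Rendering quantizes its
# output so that in-memory frames and PNG round trips are bit-identical.
quantize8 <- function(x) round(x * 255) / 255

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
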