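# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Truncated normal draws via inverse-CDF
#'
#' Exact truncation (no rejection loop), so the number of uniforms consumed
#' is always `n` and RNG streams stay aligned across configurations.
#' @noRd
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Stable fingerprint of a configuration
#'
#' Polynomial rolling hash over the canonical JSON serialization; used to
#' stamp every pipeline artifact so outputs can be traced to the exact
#' configuration that produced them. Not cryptographic.
#' @noRd
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(strip_classes(x), auto_unbox = TRUE,
                                     digits = NA))
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Recursively drop S3 classes so any config nests serialize as plain lists
#' @noRd
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, strip_classes)
  }
  x
}

#' Derive a child seed from a base seed (kept within 32-bit integer range)
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483629)
}

#' @noRd
is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
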