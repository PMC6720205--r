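# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages here use the
#' conventional half-up rule (96.25 -> 96.3).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic 31-bit seed derived from a base seed and integer tags, so
# per-image / per-component RNG streams are independently reproducible.
derive_seed <- function(base_seed, ...) {
  m <- 2147483647
  h <- as.double(base_seed %% m)
  for (tag in c(...)) {
    h <- (h * 48271 + as.double(tag) + 1) %% m
  }
  as.integer(h)
}

# Timestamped, level-tagged logging to stderr.
log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  paste0(..., collapse = "")))
}

is_square <- function(m) nrow(m) == ncol(m)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
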