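# Internal helpers shared across modules.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a child seed from a parent seed
#'
#' The synthetic cohort generator uses a hierarchical seed stream: one global
#' integer seed drives per-patient seeds, which in turn drive per-frame seeds,
#' so any single frame can be regenerated in isolation. Child seeds are
#' produced by a multiplicative-congruential step modulo the Mersenne prime
#' 2^31 - 1, which keeps every seed a valid 32-bit R integer.
#'
#' @param seed parent integer seed
#' @param index non-negative integer stream index
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, index) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m + 1) * 48271 + 7919 * (as.numeric(index) + 1)
  as.integer(x %% m)
}

stop_if_not <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

# Pixel matrices are integer matrices in [0, 255], row 1 at the skin surface
# (top of the B-mode display).
assert_pixels <- function(px) {
  stop_if_not(is.matrix(px) && length(px) > 0, "pixel data must be a non-empty matrix")
  stop_if_not(all(is.finite(px)), "pixel data contains non-finite values")
  stop_if_not(all(px >= 0 & px <= 255), "pixel values must lie in [0, 255]")
  invisible(px)
}
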