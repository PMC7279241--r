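#' Deterministic 31-bit string hash
#'
#' Polynomial rolling hash over the UTF-8 bytes of `x`, reduced modulo
#' 2^31 - 1. Used to derive independent, reproducible RNG streams for
#' per-compound and per-target operations: the same (seed, key) always maps
#' to the same stream, regardless of how many other compounds or targets are
#' processed, so any target or compound can be re-derived in isolation.
#'
#' @param x character vector to hash.
#' @return integer vector in `[0, 2^31 - 2]`.
#' @keywords internal
#' @noRd
hash31 <- function(x) {
  m <- 2147483647  # 2^31 - 1; 31 * h + byte stays far below 2^53 in doubles
  vapply(x, function(s) {
    h <- 7
    for (b in utf8ToInt(enc2utf8(s))) h <- (h * 31 + b) %% m
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

#' Derive a child seed from a global seed and a string key
#' @keywords internal
#' @noRd
derive_seed <- function(seed, key) {
  hash31(paste(as.integer(seed), key, sep = "\r"))
}

#' Run code with a local, seed-derived RNG state
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# assert helper: stop with a consistent message prefix
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}
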