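# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
derive_seed <- function(seed, ...) {
  # Mix a base seed with stage/id integers into a new 31-bit seed.
  parts <- c(seed, ...)
  h <- 2166136261
  for (p in parts) {
    for (byte in c(p %% 256L, (p %/% 256L) %% 256L, (p %/% 65536L) %% 256L)) {
      h <- bitwXor(as.integer(h %% 2147483647), as.integer(byte))
      h <- (h * 16777619) %% 2147483647
    }
  }
  as.integer(h %% 2147483646L) + 1L
}

#' FNV-1a hash of an R object (hex string)
#'
#' Used to stamp output tables with a configuration fingerprint.
#' @keywords internal
#' @noRd
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967291
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
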