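`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed
#'
#' Deterministically maps a (master seed, index) pair to a new 32-bit seed, so
#' that independent simulation units (virtual mice, grid cells, sessions) each
#' get their own random stream. Adding units never reshuffles existing ones.
#'
#' @param seed Master seed (integer).
#' @param index Non-negative unit index (integer; may be a vector).
#' @return Integer seed(s) in \[0, 2^31 - 2\].
#' @export
substream_seed <- function(seed, index) {
  m <- 2147483647
  as.integer(((seed %% m) * 48271 + index * 104729) %% m)
}

# scalar numeric validation helper
.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    stop(sprintf("`%s` = %g is outside its valid range", name, x),
         call. = FALSE)
  }
  invisible(x)
}
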