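# Internal helpers shared across modules.

N_POINTS <- 1220L

#' Derive a reproducible child seed
#'
#' Folds an index into a base seed so that per-session / per-fold random
#' draws are reproducible yet distinct. Result stays inside 32-bit integer
#' range.
#'
#' @param seed base integer seed.
#' @param index non-negative integer stream index.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 1) %% 2147483629)
}

# Trapezoidal integral of y over t (both numeric, same length, t increasing).
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_meshpain <- function(..., class = "meshpain_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
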