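# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and index words
#'
#' A fixed integer hash (multiply-accumulate with prime constants, modulo
#' 2^31 - 1) so that every (session, lead, purpose) tuple gets its own
#' named random stream. Adding leads or sessions never perturbs the
#' streams of existing ones.
#'
#' @param master integer master seed.
#' @param ... further integer or character index words.
#' @return an integer in [1, 2^31 - 2] usable with [set.seed()].
#' @keywords internal
stream_seed <- function(master, ...) {
  words <- list(...)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (w in words) {
    if (is.character(w)) {
      w <- sum(utf8ToInt(w) * seq_along(utf8ToInt(w)))
    }
    h <- (h * 48271 + as.numeric(w) * 16807 + 12345) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Linear interpolation of a sampled series onto new times
#' @keywords internal
interp_series <- function(t, v, t_out) {
  stats::approx(t, v, xout = t_out, rule = 2)$y
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}
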