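#' Convert between relaxation times and rates
#'
#' Relaxation times are expressed in milliseconds at the user-facing API and
#' as rates in s^-1 internally. These two helpers own all factor-of-1000
#' logic so no other function converts units by hand. The conversion is an
#' involution: `ms_to_rate(rate_to_ms(x)) == x` to machine precision.
#'
#' @param t_ms Relaxation time(s) in milliseconds; must be finite and > 0.
#' @param rate Relaxation rate(s) in s^-1; must be finite and > 0.
#' @return `ms_to_rate` returns rates in s^-1; `rate_to_ms` returns times in
#'   milliseconds.
#' @examples
#' ms_to_rate(1000)  # 1 s^-1
#' rate_to_ms(0.5)   # 2000 ms
#' @export
ms_to_rate <- function(t_ms) {
  stopifnot(is.numeric(t_ms), all(is.finite(t_ms)), all(t_ms > 0))
  1000 / t_ms
}

#' @rdname ms_to_rate
#' @export
rate_to_ms <- function(rate) {
  stopifnot(is.numeric(rate), all(is.finite(rate)), all(rate > 0))
  1000 / rate
}

# single scalar finite check used by constructors
.check_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  ok <- if (strict) x > min else x >= min
  if (!ok) {
    stop(sprintf("'%s' must be %s %s (got %g)", name,
                 if (strict) ">" else ">=", format(min), x), call. = FALSE)
  }
  as.numeric(x)
}
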