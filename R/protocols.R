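#' Acquisition protocols for the synthetic scanner
#'
#' Constructors for the three acquisition schemes the simulator emulates:
#' an inversion-recovery turbo-spin-echo (IR-TSE) T1 protocol, a multi-echo
#' CPMG T2 protocol and a diffusion-weighted (DWI) protocol.
#'
#' Defaults: nine inversion times log-spaced from 25 to 6400 ms (a factor
#' of 2 per step) with TR 10000 ms and TE 9.9 ms; 32 equally spaced echo
#' times from 10 to 320 ms with TR 5000 ms; b-values 0, 50, 500,
#' 1000 s/mm^2 with TE 48 ms.
#'
#' @param inversion_times Strictly increasing inversion times, ms; all
#'   below `tr`.
#' @param tr Repetition time, ms.
#' @param te Echo time of the readout, ms (metadata; readout decay is not
#'   simulated).
#' @return A protocol object of class `ir_protocol`, `cpmg_protocol` or
#'   `dwi_protocol` (all also of class `mr_protocol`).
#' @export
ir_protocol <- function(inversion_times = 25 * 2^(0:8), tr = 10000, te = 9.9) {
  stopifnot(is.numeric(inversion_times), length(inversion_times) >= 3,
            all(inversion_times > 0), all(diff(inversion_times) > 0))
  tr <- .check_scalar(tr, "tr", min = 0, strict = TRUE)
  if (any(inversion_times >= tr)) {
    stop("all inversion times must be below the repetition time", call. = FALSE)
  }
  structure(list(kind = "ir", inversion_times = as.numeric(inversion_times),
                 tr = tr, te = .check_scalar(te, "te", min = 0, strict = TRUE)),
            class = c("ir_protocol", "mr_protocol"))
}

#' @param echo_times Strictly increasing echo times, ms.
#' @rdname ir_protocol
#' @export
cpmg_protocol <- function(echo_times = seq(10, 320, length.out = 32), tr = 5000) {
  stopifnot(is.numeric(echo_times), length(echo_times) >= 3,
            all(echo_times > 0), all(diff(echo_times) > 0))
  structure(list(kind = "cpmg", echo_times = as.numeric(echo_times),
                 tr = .check_scalar(tr, "tr", min = 0, strict = TRUE)),
            class = c("cpmg_protocol", "mr_protocol"))
}

#' @param b_values Strictly increasing diffusion weightings, s/mm^2; the
#'   first must be 0.
#' @rdname ir_protocol
#' @export
dwi_protocol <- function(b_values = c(0, 50, 500, 1000), te = 48) {
  stopifnot(is.numeric(b_values), length(b_values) >= 2,
            all(b_values >= 0), all(diff(b_values) > 0))
  if (b_values[1] != 0) stop("the first b-value must be 0", call. = FALSE)
  structure(list(kind = "dwi", b_values = as.numeric(b_values),
                 te = .check_scalar(te, "te", min = 0, strict = TRUE)),
            class = c("dwi_protocol", "mr_protocol"))
}

#' @export
print.mr_protocol <- function(x, ...) {
  pts <- switch(x$kind, ir = x$inversion_times, cpmg = x$echo_times,
                dwi = x$b_values)
  lab <- switch(x$kind, ir = "TI [ms]", cpmg = "TE [ms]", dwi = "b [s/mm^2]")
  cat(sprintf("<%s_protocol> %d points, %s: %s\n", x$kind, length(pts), lab,
              paste(format(pts, trim = TRUE), collapse = ", ")))
  invisible(x)
}

# sampling axis of a protocol (TI, TE, or b)
protocol_points <- function(protocol) {
  switch(protocol$kind,
         ir = protocol$inversion_times,
         cpmg = protocol$echo_times,
         dwi = protocol$b_values,
         stop("unknown protocol kind"))
}
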