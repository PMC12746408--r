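#' Analytic MR signal models
#'
#' The three signal equations the simulator and the voxel-wise fitters
#' share. `ir_signal` is the magnitude inversion-recovery signal with the
#' finite-TR recovery term,
#' \eqn{|M_0 (1 - 2 e^{-TI/T_1} + e^{-TR/T_1})|}; `cpmg_signal` is the
#' mono-exponential spin-echo decay \eqn{M_0 e^{-TE/T_2}}; `dwi_signal` is
#' the mono-exponential diffusion decay \eqn{S_0 e^{-b \cdot ADC \cdot 10^{-3}}}
#' (ADC supplied in 10^-3 mm^2/s, b in s/mm^2). All are vectorized over
#' their sampling argument.
#'
#' @param t1,t2 Relaxation times, ms (> 0).
#' @param ti,te Inversion/echo times, ms (> 0).
#' @param tr Repetition time, ms (> 0).
#' @param m0,s0 Equilibrium signal amplitude, arbitrary units.
#' @param adc Apparent diffusion coefficient, 10^-3 mm^2/s (> 0).
#' @param b Diffusion weighting, s/mm^2 (>= 0).
#' @return Signal magnitude(s), arbitrary units.
#' @examples
#' ir_signal(812, 812 * log(2), tr = 1e6)  # null point: ~0
#' cpmg_signal(42, 42)                     # m0 / e
#' dwi_signal(1.0, 1000)                   # s0 / e
#' @export
ir_signal <- function(t1, ti, tr, m0 = 1) {
  if (any(t1 <= 0)) stop("'t1' must be > 0", call. = FALSE)
  stopifnot(all(ti > 0), all(tr > 0))
  abs(m0 * (1 - 2 * exp(-ti / t1) + exp(-tr / t1)))
}

#' @rdname ir_signal
#' @export
cpmg_signal <- function(t2, te, m0 = 1) {
  if (any(t2 <= 0)) stop("'t2' must be > 0", call. = FALSE)
  stopifnot(all(te > 0))
  m0 * exp(-te / t2)
}

#' @rdname ir_signal
#' @export
dwi_signal <- function(adc, b, s0 = 1) {
  if (any(adc <= 0)) stop("'adc' must be > 0", call. = FALSE)
  if (any(b < 0)) stop("'b' must be >= 0", call. = FALSE)
  s0 * exp(-b * adc * 1e-3)
}

#' Apply Rician noise to magnitude signals
#'
#' Magnitude MR noise: with independent zero-mean Gaussian components
#' \eqn{n_1, n_2} of standard deviation `sigma`, the noisy magnitude is
#' \eqn{\sqrt{(x + n_1)^2 + n_2^2}}. `sigma = 0` returns the input
#' unchanged. When a seed is given the caller's RNG stream is left intact.
#'
#' @param values Noise-free magnitudes (any numeric shape; shape is
#'   preserved).
#' @param sigma Gaussian component standard deviation (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @return Noisy magnitudes with the same dimensions as `values`.
#' @export
add_rician_noise <- function(values, sigma, seed = NULL) {
  stopifnot(is.numeric(values))
  sigma <- .check_scalar(sigma, "sigma", min = 0)
  if (sigma == 0) return(values)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  n <- length(values)
  out <- sqrt((values + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  dim(out) <- dim(values)
  out
}

#' Noise level for a target signal-to-noise ratio
#'
#' Convenience: the Gaussian component sigma giving `SNR = s0 / sigma` at a
#' reference amplitude `s0` (by convention the unit proton density, i.e.
#' the b = 0 / fully recovered signal).
#'
#' @param snr Target signal-to-noise ratio (> 0); `Inf` gives sigma 0.
#' @param s0 Reference signal amplitude.
#' @return Noise sigma in the same units as `s0`.
#' @export
sigma_from_snr <- function(snr, s0 = 1) {
  stopifnot(is.numeric(snr), length(snr) == 1L, snr > 0)
  if (is.infinite(snr)) return(0)
  s0 / snr
}
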