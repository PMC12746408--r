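#' Forward ADC model: lecithin concentration to ADC
#'
#' Evaluates the biexponential lecithin-to-ADC relationship
#' \eqn{ADC(C) = a_f e^{-k_f C} + a_s e^{-k_s C}} (ADC in 10^-3 mm^2/s).
#' The function is strictly decreasing in the lecithin concentration, which
#' is what makes the later recipe inversion unique.
#'
#' @param c_lec Soy lecithin concentration(s), % wt/vol (>= 0); vectorized.
#' @param params An [adc_model_params()]; defaults to the shipped calibration.
#' @return ADC value(s) in 10^-3 mm^2/s.
#' @examples
#' adc_forward(0)    # water limit: a_fast + a_slow = 1.96
#' adc_forward(5)    # ~0.835
#' @export
adc_forward <- function(c_lec, params = adc_model_params()) {
  stopifnot(inherits(params, "adc_model_params"))
  if (!is.numeric(c_lec) || any(!is.finite(c_lec))) {
    stop("'c_lec' must be finite numeric", call. = FALSE)
  }
  if (any(c_lec < 0)) stop("'c_lec' must be >= 0", call. = FALSE)
  params$a_fast * exp(-params$k_fast * c_lec) +
    params$a_slow * exp(-params$k_slow * c_lec)
}

#' Forward relaxation-rate models
#'
#' Affine models for the composite-gel relaxation rates:
#' \deqn{R_1 = R_{1w} + r_{1,Gd} C_{Gd} + r_{1,lec} C_{lec}}
#' \deqn{R_2 = R_{2w} + r_{2,Gd} C_{Gd} + r_{2,lec} C_{lec} + r_{2,a} C_a}
#' Agarose does not appear in R1: its longitudinal contribution is
#' negligible in the composite gel. Rates are in s^-1.
#'
#' @param conc A [concentration_triple()].
#' @param relax A [relaxivity_table()].
#' @param solvent A [solvent_baseline()].
#' @return Relaxation rate in s^-1.
#' @export
r1_forward <- function(conc, relax = relaxivity_table(),
                       solvent = solvent_baseline()) {
  stopifnot(inherits(conc, "concentration_triple"),
            inherits(relax, "relaxivity_table"),
            inherits(solvent, "solvent_baseline"))
  solvent$r1w + relax$r1_gd * conc$gd + relax$r1_lec * conc$lecithin
}

#' @rdname r1_forward
#' @export
r2_forward <- function(conc, relax = relaxivity_table(),
                       solvent = solvent_baseline()) {
  stopifnot(inherits(conc, "concentration_triple"),
            inherits(relax, "relaxivity_table"),
            inherits(solvent, "solvent_baseline"))
  solvent$r2w + relax$r2_gd * conc$gd + relax$r2_lec * conc$lecithin +
    relax$r2_agar * conc$agarose
}

#' Predict the (T1, T2, ADC) triple of a gel recipe
#'
#' Composes the three forward models and converts rates to times:
#' T1 = 1000/R1 ms, T2 = 1000/R2 ms, plus the biexponential ADC.
#' Concentrations outside the calibrated ranges (Gd-DTPA > 0.2 mM,
#' lecithin > 5 %, agarose > 4 %) trigger an extrapolation warning of
#' condition class `gelphantom_extrapolation`; lecithin loads >= 3 %
#' additionally warn about reduced ADC accuracy.
#'
#' @param conc A [concentration_triple()].
#' @param calib A [calibration_set()].
#' @return A [tissue_target()] with the predicted T1 (ms), T2 (ms) and ADC
#'   (10^-3 mm^2/s).
#' @examples
#' predict_triple(concentration_triple())  # pure-water baseline
#' @export
predict_triple <- function(conc, calib = default_calibration()) {
  stopifnot(inherits(conc, "concentration_triple"),
            inherits(calib, "calibration_set"))
  flags <- extrapolation_flags(conc)
  if (length(flags)) {
    warning(warningCondition(paste(flags, collapse = "; "),
                             class = "gelphantom_extrapolation"))
  }
  r1 <- r1_forward(conc, calib$relaxivity, calib$solvent)
  r2 <- r2_forward(conc, calib$relaxivity, calib$solvent)
  tissue_target(t1 = rate_to_ms(r1), t2 = rate_to_ms(r2),
                adc = adc_forward(conc$lecithin, calib$adc_params))
}
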