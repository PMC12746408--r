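#' Ingredient concentrations for one hydrogel
#'
#' A `concentration_triple` holds the three ingredient concentrations that
#' define a gel: Gd-DTPA (the T1 modifier, in mM), soy lecithin (the ADC
#' modifier, in % wt/vol) and agarose (the dominant T2 modifier, in
#' % wt/vol). All concentrations must be finite and non-negative.
#'
#' @param gd Gd-DTPA concentration in mM.
#' @param lecithin Soy lecithin concentration in % wt/vol.
#' @param agarose Agarose concentration in % wt/vol.
#' @return An object of class `concentration_triple`.
#' @examples
#' concentration_triple(gd = 0.1, lecithin = 1, agarose = 2)
#' @export
concentration_triple <- function(gd = 0, lecithin = 0, agarose = 0) {
  out <- list(
    gd = .check_scalar(gd, "gd", min = 0),
    lecithin = .check_scalar(lecithin, "lecithin", min = 0),
    agarose = .check_scalar(agarose, "agarose", min = 0)
  )
  structure(out, class = "concentration_triple")
}

#' @export
print.concentration_triple <- function(x, ...) {
  cat(sprintf(
    "<concentration_triple> Gd-DTPA %.4g mM | lecithin %.4g %% wt/vol | agarose %.4g %% wt/vol\n",
    x$gd, x$lecithin, x$agarose))
  invisible(x)
}

#' Biexponential lecithin-to-ADC model parameters
#'
#' The ADC of the composite gel depends (to good approximation) only on the
#' soy lecithin concentration, through a biexponential decay
#' \deqn{ADC(C) = a_f e^{-k_f C} + a_s e^{-k_s C}}
#' with ADC in 10^-3 mm^2/s and C in % wt/vol. The default parameters are
#' the shipped 3 T / 20 degree C calibration. The fast and slow components
#' are identified by the ordering convention `k_fast > k_slow`.
#'
#' @param a_fast Fast-component amplitude, 10^-3 mm^2/s (> 0).
#' @param k_fast Fast decay constant, (% wt/vol)^-1 (> 0).
#' @param a_slow Slow-component amplitude, 10^-3 mm^2/s (> 0).
#' @param k_slow Slow decay constant, (% wt/vol)^-1 (> 0, < `k_fast`).
#' @return An object of class `adc_model_params`.
#' @export
adc_model_params <- function(a_fast = 0.36, k_fast = 2.79,
                             a_slow = 1.60, k_slow = 0.13) {
  out <- list(
    a_fast = .check_scalar(a_fast, "a_fast", min = 0, strict = TRUE),
    k_fast = .check_scalar(k_fast, "k_fast", min = 0, strict = TRUE),
    a_slow = .check_scalar(a_slow, "a_slow", min = 0, strict = TRUE),
    k_slow = .check_scalar(k_slow, "k_slow", min = 0, strict = TRUE)
  )
  if (!(out$k_fast > out$k_slow)) {
    stop("'k_fast' must exceed 'k_slow' (component ordering convention)",
         call. = FALSE)
  }
  structure(out, class = "adc_model_params")
}

#' @export
print.adc_model_params <- function(x, ...) {
  cat(sprintf("<adc_model_params> ADC(C) = %.4g*exp(-%.4g C) + %.4g*exp(-%.4g C)  [10^-3 mm^2/s]\n",
              x$a_fast, x$k_fast, x$a_slow, x$k_slow))
  invisible(x)
}

#' Relaxivities of the three gel ingredients
#'
#' Per-concentration increments of the longitudinal (R1 = 1/T1) and
#' transverse (R2 = 1/T2) relaxation rates. The longitudinal relaxivity of
#' agarose is intentionally absent: its contribution to T1 is negligible in
#' the composite gel, so R1 depends only on Gd-DTPA and lecithin. Defaults
#' are the shipped 3 T / 20 degree C values.
#'
#' @param r1_gd,r2_gd Gd-DTPA relaxivities, s^-1 mM^-1.
#' @param r1_lec,r2_lec Soy lecithin relaxivities, s^-1 (% wt/vol)^-1.
#' @param r2_agar Agarose transverse relaxivity, s^-1 (% wt/vol)^-1.
#' @return An object of class `relaxivity_table`.
#' @export
relaxivity_table <- function(r1_gd = 3.78, r2_gd = 4.24,
                             r1_lec = 0.10, r2_lec = 0.69,
                             r2_agar = 6.62) {
  out <- list(
    r1_gd = .check_scalar(r1_gd, "r1_gd", min = 0),
    r2_gd = .check_scalar(r2_gd, "r2_gd", min = 0),
    r1_lec = .check_scalar(r1_lec, "r1_lec", min = 0),
    r2_lec = .check_scalar(r2_lec, "r2_lec", min = 0),
    r2_agar = .check_scalar(r2_agar, "r2_agar", min = 0)
  )
  structure(out, class = "relaxivity_table")
}

#' @export
print.relaxivity_table <- function(x, ...) {
  cat("<relaxivity_table> (s^-1 per concentration unit)\n")
  cat(sprintf("  Gd-DTPA : r1 = %.3g, r2 = %.3g  [mM^-1]\n", x$r1_gd, x$r2_gd))
  cat(sprintf("  lecithin: r1 = %.3g, r2 = %.3g  [(%% wt/vol)^-1]\n", x$r1_lec, x$r2_lec))
  cat(sprintf("  agarose : r1 = (negligible), r2 = %.3g  [(%% wt/vol)^-1]\n", x$r2_agar))
  invisible(x)
}

#' Solvent (pure water) baseline relaxation rates
#'
#' The affine relaxation-rate models are anchored at the rates of the pure
#' solvent. Defaults correspond to T1w = 3000 ms and T2w = 2000 ms,
#' literature-typical values for deionized water near 20 degrees C at 3 T;
#' every feasibility number produced downstream is reported together with
#' this baseline.
#'
#' @param t1w_ms Longitudinal relaxation time of pure water, ms.
#' @param t2w_ms Transverse relaxation time of pure water, ms (<= `t1w_ms`).
#' @param temperature Sample temperature, degrees C (metadata only).
#' @param field Field strength, Tesla (metadata only).
#' @return An object of class `solvent_baseline` with rates `r1w`, `r2w`
#'   in s^-1.
#' @export
solvent_baseline <- function(t1w_ms = 3000, t2w_ms = 2000,
                             temperature = 20, field = 3) {
  t1w_ms <- .check_scalar(t1w_ms, "t1w_ms", min = 0, strict = TRUE)
  t2w_ms <- .check_scalar(t2w_ms, "t2w_ms", min = 0, strict = TRUE)
  r1w <- ms_to_rate(t1w_ms)
  r2w <- ms_to_rate(t2w_ms)
  if (!(r2w >= r1w)) {
    stop("solvent baseline must satisfy R2w >= R1w (i.e. T2w <= T1w)", call. = FALSE)
  }
  structure(list(r1w = r1w, r2w = r2w,
                 temperature = .check_scalar(temperature, "temperature"),
                 field = .check_scalar(field, "field", min = 0, strict = TRUE)),
            class = "solvent_baseline")
}

#' @export
print.solvent_baseline <- function(x, ...) {
  cat(sprintf("<solvent_baseline> T1w = %.4g ms, T2w = %.4g ms (%.3g T, %.3g degC)\n",
              rate_to_ms(x$r1w), rate_to_ms(x$r2w), x$field, x$temperature))
  invisible(x)
}

#' Target MR properties for a gel
#'
#' A desired (T1, T2, ADC) triple, e.g. the properties of a tissue the gel
#' should mimic. Physical ordering T1 > T2 > 0 is enforced.
#'
#' @param t1 Target longitudinal relaxation time, ms.
#' @param t2 Target transverse relaxation time, ms.
#' @param adc Target apparent diffusion coefficient, 10^-3 mm^2/s.
#' @return An object of class `tissue_target`.
#' @examples
#' tissue_target(812, 42, 1.40)  # liver-like
#' @export
tissue_target <- function(t1, t2, adc) {
  t1 <- .check_scalar(t1, "t1", min = 0, strict = TRUE)
  t2 <- .check_scalar(t2, "t2", min = 0, strict = TRUE)
  adc <- .check_scalar(adc, "adc", min = 0, strict = TRUE)
  if (!(t1 > t2)) stop("'t1' must exceed 't2'", call. = FALSE)
  structure(list(t1 = t1, t2 = t2, adc = adc), class = "tissue_target")
}

#' @export
print.tissue_target <- function(x, ...) {
  cat(sprintf("<tissue_target> T1 = %.4g ms | T2 = %.4g ms | ADC = %.4g x10^-3 mm^2/s\n",
              x$t1, x$t2, x$adc))
  invisible(x)
}

#' Assemble a calibration set
#'
#' A `calibration_set` bundles everything the forward and inverse models
#' need: the relaxivity table, the biexponential lecithin-to-ADC parameters
#' and the solvent baseline rates.
#'
#' @param relaxivity A [relaxivity_table()].
#' @param adc_params An [adc_model_params()].
#' @param solvent A [solvent_baseline()].
#' @return An object of class `calibration_set`.
#' @seealso [default_calibration()], [read_calibration()]
#' @export
calibration_set <- function(relaxivity = relaxivity_table(),
                            adc_params = adc_model_params(),
                            solvent = solvent_baseline()) {
  stopifnot(inherits(relaxivity, "relaxivity_table"),
            inherits(adc_params, "adc_model_params"),
            inherits(solvent, "solvent_baseline"))
  structure(list(relaxivity = relaxivity, adc_params = adc_params,
                 solvent = solvent),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat("<calibration_set>\n")
  print(x$relaxivity); print(x$adc_params); print(x$solvent)
  invisible(x)
}

#' The shipped default calibration
#'
#' Relaxivities, ADC model coefficients and solvent baselines for the
#' Gd-DTPA / agarose / soy lecithin system at 3 T and 20 degrees C. The
#' same values are shipped as an editable config file; see
#' `system.file("extdata", "calibration_default.yaml", package = "gelphantom")`.
#'
#' Note: the ingredients are natural products, so relaxivities and ADC
#' coefficients are specific to the characterized product sources; other
#' sources should be re-characterized with the [calibration][fit_relaxivity]
#' tools.
#'
#' @return A `calibration_set`.
#' @export
default_calibration <- function() {
  calibration_set()
}

# calibrated concentration ranges; beyond these, forward predictions are
# extrapolations of the affine/biexponential fits
.calibrated_max <- c(gd = 0.2, lecithin = 5, agarose = 4)
# above this lecithin load the measured ADC shows markedly higher
# variability, so the targeted ADC is less accurate
.lecithin_high_variability <- 3

# character flags for a concentration triple; empty if fully calibrated
extrapolation_flags <- function(conc) {
  stopifnot(inherits(conc, "concentration_triple"))
  flags <- character(0)
  if (conc$gd > .calibrated_max[["gd"]]) {
    flags <- c(flags, sprintf("extrapolation: Gd-DTPA %.4g mM exceeds calibrated 0.2 mM", conc$gd))
  }
  if (conc$lecithin > .calibrated_max[["lecithin"]]) {
    flags <- c(flags, sprintf("extrapolation: lecithin %.4g %% exceeds calibrated 5 %%", conc$lecithin))
  }
  if (conc$agarose > .calibrated_max[["agarose"]]) {
    flags <- c(flags, sprintf("extrapolation: agarose %.4g %% exceeds calibrated 4 %%", conc$agarose))
  }
  if (conc$lecithin >= .lecithin_high_variability &&
      conc$lecithin <= .calibrated_max[["lecithin"]]) {
    flags <- c(flags, sprintf("reduced ADC accuracy: lecithin %.4g %% is in the high-variability regime (>= 3 %%)", conc$lecithin))
  }
  flags
}
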