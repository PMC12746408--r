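#' Step 1: lecithin concentration for a target ADC
#'
#' Inverts the biexponential ADC model by bisection on `[0, c_max]`.
#' Because the forward model is strictly decreasing, the root is unique.
#' The iteration stops when the ADC residual is below `tol`
#' (default 1e-10 in 10^-3 mm^2/s).
#'
#' @param target_adc Target ADC, 10^-3 mm^2/s.
#' @param params An [adc_model_params()].
#' @param c_max Upper bracket for the lecithin concentration, % wt/vol
#'   (default 10).
#' @param tol ADC residual tolerance.
#' @return Lecithin concentration, % wt/vol.
#' @section Infeasibility: a target above the zero-concentration (water)
#'   ADC raises an error of class `gelphantom_infeasible` with
#'   `reason = "infeasible-high"`; a target below `adc_forward(c_max)`
#'   raises `reason = "infeasible-low"`.
#' @examples
#' solve_lecithin(1.96)  # water ADC -> 0 % lecithin
#' solve_lecithin(0.98)  # ~3.77 %
#' @export
solve_lecithin <- function(target_adc, params = adc_model_params(),
                           c_max = 10, tol = 1e-10) {
  target_adc <- .check_scalar(target_adc, "target_adc", min = 0, strict = TRUE)
  adc0 <- adc_forward(0, params)
  adc_hi <- adc_forward(c_max, params)
  if (target_adc > adc0) {
    .infeasible(sprintf("target ADC %.4g exceeds the water-limit ADC %.4g (no lecithin can raise ADC)",
                        target_adc, adc0),
                step = "lecithin", reason = "infeasible-high")
  }
  if (target_adc < adc_hi) {
    .infeasible(sprintf("target ADC %.4g is below ADC at the %.3g %% bracket (%.4g)",
                        target_adc, c_max, adc_hi),
                step = "lecithin", reason = "infeasible-low")
  }
  if (target_adc == adc0) return(0)
  lo <- 0; hi <- c_max
  for (iter in seq_len(200)) {
    mid <- (lo + hi) / 2
    val <- adc_forward(mid, params)
    if (abs(val - target_adc) < tol) return(mid)
    if (val > target_adc) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Step 2: Gd-DTPA concentration for a target T1
#'
#' Closed-form inversion of the affine R1 model at a given lecithin load:
#' \eqn{C_{Gd} = (1000/T_1 - R_{1w} - r_{1,lec} C_{lec}) / r_{1,Gd}}.
#' A negative numerator means the requested T1 exceeds the baseline T1
#' achievable at this lecithin concentration (the upper feasibility
#' boundary); this raises a `gelphantom_infeasible` error.
#'
#' @param target_t1 Target T1, ms.
#' @param c_lec Lecithin concentration from step 1, % wt/vol.
#' @param calib A [calibration_set()].
#' @return Gd-DTPA concentration, mM (>= 0).
#' @export
solve_gd <- function(target_t1, c_lec, calib = default_calibration()) {
  target_t1 <- .check_scalar(target_t1, "target_t1", min = 0, strict = TRUE)
  c_lec <- .check_scalar(c_lec, "c_lec", min = 0)
  r <- calib$relaxivity; s <- calib$solvent
  num <- ms_to_rate(target_t1) - s$r1w - r$r1_lec * c_lec
  if (num < 0) {
    .infeasible(sprintf(
      "target T1 %.4g ms exceeds the baseline T1 %.4g ms achievable at %.4g %% lecithin",
      target_t1, rate_to_ms(s$r1w + r$r1_lec * c_lec), c_lec),
      step = "gd", reason = "t1-above-baseline")
  }
  num / r$r1_gd
}

#' Step 3: agarose concentration for a target T2
#'
#' Closed-form inversion of the affine R2 model given the lecithin and
#' Gd-DTPA concentrations fixed by steps 1 and 2:
#' \eqn{C_a = (1000/T_2 - R_{2w} - r_{2,Gd} C_{Gd} - r_{2,lec} C_{lec}) / r_{2,a}}.
#' A negative numerator means the target T2 is longer than the baseline T2
#' of the agarose-free mixture; this raises `gelphantom_infeasible`.
#'
#' @param target_t2 Target T2, ms.
#' @param c_lec Lecithin concentration, % wt/vol.
#' @param c_gd Gd-DTPA concentration, mM.
#' @param calib A [calibration_set()].
#' @return Agarose concentration, % wt/vol (>= 0).
#' @export
solve_agarose <- function(target_t2, c_lec, c_gd, calib = default_calibration()) {
  target_t2 <- .check_scalar(target_t2, "target_t2", min = 0, strict = TRUE)
  c_lec <- .check_scalar(c_lec, "c_lec", min = 0)
  c_gd <- .check_scalar(c_gd, "c_gd", min = 0)
  r <- calib$relaxivity; s <- calib$solvent
  base_r2 <- s$r2w + r$r2_gd * c_gd + r$r2_lec * c_lec
  num <- ms_to_rate(target_t2) - base_r2
  if (num < 0) {
    .infeasible(sprintf(
      "target T2 %.4g ms exceeds the baseline T2 %.4g ms of the agarose-free mixture",
      target_t2, rate_to_ms(base_r2)),
      step = "agarose", reason = "t2-above-baseline")
  }
  num / r$r2_agar
}

#' Solve a gel recipe for a target (T1, T2, ADC) triple
#'
#' The three-step inversion: (1) lecithin from the target ADC, (2) Gd-DTPA
#' from the target T1 at that lecithin load, (3) agarose from the target T2
#' given both. Each step can fail on its own feasibility boundary; in that
#' case the result is marked infeasible, names the failing step, and the
#' remaining concentrations are `NA`.
#'
#' @param target A [tissue_target()].
#' @param calib A [calibration_set()].
#' @param c_max Lecithin bisection bracket passed to [solve_lecithin()].
#' @return An object of class `recipe_result` with fields
#'   `concentrations` ([concentration_triple()] or `NULL`), `predicted`
#'   ([tissue_target()] from [predict_triple()]), `target`, `feasible`,
#'   `failed_step`, `reason` and `warnings` (extrapolation / accuracy
#'   flags).
#' @examples
#' solve_recipe(tissue_target(725, 43, 0.98))   # pancreas-like: feasible
#' solve_recipe(tissue_target(1600, 80, 0.9))   # gray-matter-like: infeasible
#' @export
solve_recipe <- function(target, calib = default_calibration(), c_max = 10) {
  stopifnot(inherits(target, "tissue_target"),
            inherits(calib, "calibration_set"))
  fail <- function(e) {
    structure(list(concentrations = NULL, predicted = NULL, target = target,
                   feasible = FALSE, failed_step = e$step, reason = e$reason,
                   message = conditionMessage(e), warnings = character(0)),
              class = "recipe_result")
  }
  c_lec <- tryCatch(solve_lecithin(target$adc, calib$adc_params, c_max = c_max),
                    gelphantom_infeasible = fail)
  if (inherits(c_lec, "recipe_result")) return(c_lec)
  c_gd <- tryCatch(solve_gd(target$t1, c_lec, calib),
                   gelphantom_infeasible = fail)
  if (inherits(c_gd, "recipe_result")) return(c_gd)
  c_agar <- tryCatch(solve_agarose(target$t2, c_lec, c_gd, calib),
                     gelphantom_infeasible = fail)
  if (inherits(c_agar, "recipe_result")) return(c_agar)
  conc <- concentration_triple(gd = c_gd, lecithin = c_lec, agarose = c_agar)
  flags <- extrapolation_flags(conc)
  if (any(c(c_gd, c_lec, c_agar) == 0)) {
    flags <- c(flags, "near-boundary: at least one concentration is exactly 0 (feasibility boundary)")
  }
  predicted <- suppressWarnings(predict_triple(conc, calib))
  structure(list(concentrations = conc, predicted = predicted, target = target,
                 feasible = TRUE, failed_step = NA_character_,
                 reason = NA_character_, message = NULL, warnings = flags),
            class = "recipe_result")
}

#' @export
print.recipe_result <- function(x, ...) {
  if (x$feasible) {
    cat("<recipe_result> FEASIBLE\n  ")
    print(x$concentrations)
    cat("  predicted: ")
    print(x$predicted)
    if (length(x$warnings)) cat("  flags:", paste(x$warnings, collapse = "; "), "\n")
  } else {
    cat(sprintf("<recipe_result> INFEASIBLE at step '%s' (%s)\n  %s\n",
                x$failed_step, x$reason, x$message))
  }
  invisible(x)
}

#' Upper T1 feasibility boundary at a given ADC
#'
#' The lecithin needed to reach a low ADC also shortens T1, so the longest
#' achievable T1 at a given ADC is the Gd-free baseline
#' \eqn{T_{1,max} = 1000 / (R_{1w} + r_{1,lec} C_{lec}(ADC))}. The lower
#' the ADC, the shorter this bound.
#'
#' @param target_adc Target ADC, 10^-3 mm^2/s.
#' @param calib A [calibration_set()].
#' @return Maximum achievable T1 in ms.
#' @export
max_t1_at_adc <- function(target_adc, calib = default_calibration()) {
  c_lec <- solve_lecithin(target_adc, calib$adc_params)
  rate_to_ms(calib$solvent$r1w + calib$relaxivity$r1_lec * c_lec)
}

#' Baseline T2 before agarose addition
#'
#' After steps 1 and 2 fix the lecithin and Gd-DTPA loads, the mixture
#' already has a reduced T2; agarose can only shorten it further. This
#' baseline bounds the achievable T2 from above for a chosen (ADC, T1).
#'
#' @param target_adc Target ADC, 10^-3 mm^2/s.
#' @param target_t1 Target T1, ms.
#' @param calib A [calibration_set()].
#' @return Baseline T2 in ms.
#' @export
baseline_t2 <- function(target_adc, target_t1, calib = default_calibration()) {
  c_lec <- solve_lecithin(target_adc, calib$adc_params)
  c_gd <- solve_gd(target_t1, c_lec, calib)
  r <- calib$relaxivity
  rate_to_ms(calib$solvent$r2w + r$r2_gd * c_gd + r$r2_lec * c_lec)
}

#' Map the achievable (ADC, T1) region and its baseline T2
#'
#' Evaluates, on a rectangular grid, whether each (ADC, T1) pair is
#' achievable (T1 at or below [max_t1_at_adc()] and ADC within the model
#' range) and, where achievable, the [baseline_t2()]. The default grid is
#' 121 x 131 cells over ADC 0.8-2.0 x 10^-3 mm^2/s and T1 700-2000 ms.
#'
#' @param adc_range Length-2 numeric, ADC range in 10^-3 mm^2/s.
#' @param t1_range Length-2 numeric, T1 range in ms.
#' @param resolution Length-2 integer: number of grid points along ADC and
#'   T1.
#' @param calib A [calibration_set()].
#' @return An object of class `feasibility_grid` with fields `adc_axis`,
#'   `t1_axis`, `achievable` (logical matrix, ADC x T1) and `baseline_t2`
#'   (ms; `NA` where not achievable), plus the solvent baseline used.
#' @export
feasibility_grid <- function(adc_range = c(0.8, 2.0), t1_range = c(700, 2000),
                             resolution = c(121, 131),
                             calib = default_calibration()) {
  stopifnot(length(adc_range) == 2, length(t1_range) == 2,
            length(resolution) == 2)
  if (any(resolution < 2) || diff(adc_range) <= 0 || diff(t1_range) <= 0) {
    stop("ranges must be increasing and resolution at least 2 per axis", call. = FALSE)
  }
  adc_axis <- seq(adc_range[1], adc_range[2], length.out = resolution[1])
  t1_axis <- seq(t1_range[1], t1_range[2], length.out = resolution[2])
  r <- calib$relaxivity; s <- calib$solvent
  na <- length(adc_axis); nt <- length(t1_axis)
  achievable <- matrix(FALSE, na, nt)
  bt2 <- matrix(NA_real_, na, nt)
  for (i in seq_len(na)) {
    c_lec <- tryCatch(solve_lecithin(adc_axis[i], calib$adc_params),
                      gelphantom_infeasible = function(e) NA_real_)
    if (is.na(c_lec)) next
    r1_base <- s$r1w + r$r1_lec * c_lec
    t1_max <- rate_to_ms(r1_base)
    ok <- t1_axis <= t1_max  # boundary equality counts as feasible
    achievable[i, ok] <- TRUE
    c_gd <- (ms_to_rate(t1_axis[ok]) - r1_base) / r$r1_gd
    bt2[i, ok] <- rate_to_ms(s$r2w + r$r2_gd * c_gd + r$r2_lec * c_lec)
  }
  structure(list(adc_axis = adc_axis, t1_axis = t1_axis,
                 achievable = achievable, baseline_t2 = bt2,
                 solvent = calib$solvent),
            class = "feasibility_grid")
}

#' @export
print.feasibility_grid <- function(x, ...) {
  cat(sprintf("<feasibility_grid> %d x %d cells, ADC %.3g-%.3g x10^-3 mm^2/s, T1 %.4g-%.4g ms\n",
              length(x$adc_axis), length(x$t1_axis),
              min(x$adc_axis), max(x$adc_axis), min(x$t1_axis), max(x$t1_axis)))
  cat(sprintf("  achievable: %.1f %% of cells; baseline T2 range %.4g-%.4g ms\n",
              100 * mean(x$achievable),
              min(x$baseline_t2, na.rm = TRUE), max(x$baseline_t2, na.rm = TRUE)))
  cat(sprintf("  solvent baseline: T1w = %.4g ms, T2w = %.4g ms\n",
              rate_to_ms(x$solvent$r1w), rate_to_ms(x$solvent$r2w)))
  invisible(x)
}

#' @param x A `feasibility_grid`.
#' @param what `"achievable"` or `"baseline_t2"`.
#' @param ... Passed to [graphics::image()].
#' @rdname feasibility_grid
#' @export
plot.feasibility_grid <- function(x, what = c("achievable", "baseline_t2"), ...) {
  what <- match.arg(what)
  z <- if (what == "achievable") x$achievable + 0 else x$baseline_t2
  graphics::image(x$adc_axis, x$t1_axis, z,
                  xlab = "ADC [10^-3 mm^2/s]", ylab = "T1 [ms]",
                  main = if (what == "achievable") "Achievable (ADC, T1) region"
                         else "Baseline T2 before agarose [ms]", ...)
  invisible(x)
}

#' Export a feasibility grid as a long table
#'
#' @param grid A [feasibility_grid()].
#' @return A data.frame with columns `adc`, `t1`, `achievable`,
#'   `baseline_t2_ms`.
#' @export
feasibility_table <- function(grid) {
  stopifnot(inherits(grid, "feasibility_grid"))
  data.frame(
    adc = rep(grid$adc_axis, times = length(grid$t1_axis)),
    t1 = rep(grid$t1_axis, each = length(grid$adc_axis)),
    achievable = as.vector(grid$achievable),
    baseline_t2_ms = as.vector(grid$baseline_t2))
}

.infeasible <- function(msg, step, reason) {
  stop(errorCondition(msg, step = step, reason = reason,
                      class = "gelphantom_infeasible"))
}
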