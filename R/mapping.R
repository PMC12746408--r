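# Voxel-wise parameter estimation.
#
# All exponential fits share one scheme: the amplitude is profiled out
# analytically (for fixed decay time the model is linear in m0), a coarse
# log-spaced grid locates the SSE basin, and a Levenberg-Marquardt polish
# (minpack.lm) finishes at tight tolerance so noiseless data are inverted
# to machine precision.

.profile_sse <- function(s, f) {
  # SSE minimized over amplitude: |s|^2 - (s.f)^2 / |f|^2
  num <- sum(s * f)
  denom <- sum(f * f)
  list(sse = sum(s * s) - num^2 / denom, m0 = num / denom)
}

.lm_polish <- function(par, fn) {
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par, fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 300, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  fit
}

#' Voxel-wise T1 estimation from magnitude inversion-recovery data
#'
#' Fits \eqn{|M_0 (1 - 2 e^{-TI/T_1} + e^{-TR/T_1})|} to a magnitude
#' signal-vs-TI series. Magnitude data lose the sign of the recovery curve,
#' so polarity is restored exhaustively: for each candidate null index k
#' the first k points are sign-flipped, the signed model is fitted, and the
#' minimum-SSE solution wins.
#'
#' @param signals Magnitude signals, one per inversion time.
#' @param tis Inversion times, ms (>= 3).
#' @param tr Repetition time, ms.
#' @return A list with `t1` (ms), `m0`, `residual` (residual norm) and
#'   `n_flip` (number of sign-flipped points); all-`NA` values (with
#'   `ok = FALSE`) for degenerate input.
#' @examples
#' p <- ir_protocol()
#' s <- ir_signal(812, p$inversion_times, p$tr)
#' fit_t1_ir(s, p$inversion_times, p$tr)$t1  # 812
#' @export
fit_t1_ir <- function(signals, tis, tr) {
  stopifnot(is.numeric(signals), is.numeric(tis), length(tis) >= 3,
            length(signals) == length(tis))
  bad <- list(t1 = NA_real_, m0 = NA_real_, residual = NA_real_,
              n_flip = NA_integer_, ok = FALSE)
  if (any(!is.finite(signals)) || max(abs(signals)) == 0 ||
      stats::sd(signals) == 0) {
    return(bad)
  }
  n <- length(tis)
  grid <- exp(seq(log(10), log(12000), length.out = 60))
  shape <- function(t1) 1 - 2 * exp(-tis / t1) + exp(-tr / t1)
  F <- vapply(grid, shape, numeric(n))
  best <- list(sse = Inf)
  for (k in 0:n) {
    sk <- signals * c(rep(-1, k), rep(1, n - k))
    sk2 <- sum(sk * sk)
    num <- drop(crossprod(F, sk))
    denom <- colSums(F * F)
    sse <- sk2 - num^2 / denom
    g <- which.min(sse)
    if (sse[g] < best$sse) {
      best <- list(sse = sse[g], k = k, t1 = grid[g], m0 = num[g] / denom[g],
                   sk = sk)
    }
  }
  fn <- function(p) best$sk - p[1] * (1 - 2 * exp(-tis / p[2]) + exp(-tr / p[2]))
  fit <- .lm_polish(c(best$m0, best$t1), fn)
  if (is.null(fit) || fit$par[2] <= 0 || fit$par[1] <= 0) return(bad)
  list(t1 = fit$par[2], m0 = fit$par[1],
       residual = sqrt(fit$deviance), n_flip = best$k, ok = TRUE)
}

#' Voxel-wise T2 estimation from multi-echo CPMG data
#'
#' Unweighted nonlinear least squares of \eqn{M_0 e^{-TE/T_2}} in natural
#' signal space. Echoes whose measured magnitude falls below
#' `floor_factor * noise_sigma` are excluded from the fit: at those echoes
#' the Rician noise floor, not the decay, dominates the magnitude and would
#' bias T2 upward. With `noise_sigma = 0` every echo is used, so noiseless
#' data are inverted exactly.
#'
#' @param signals Magnitude signals, one per echo.
#' @param tes Echo times, ms (>= 3).
#' @param noise_sigma Estimated Rician component sigma (default 0).
#' @param floor_factor Noise-floor multiple below which echoes are dropped.
#' @return A list with `t2` (ms), `m0`, `residual`, `n_used` and `ok`.
#' @export
fit_t2_cpmg <- function(signals, tes, noise_sigma = 0, floor_factor = 2.5) {
  stopifnot(is.numeric(signals), is.numeric(tes), length(tes) >= 3,
            length(signals) == length(tes))
  bad <- list(t2 = NA_real_, m0 = NA_real_, residual = NA_real_,
              n_used = NA_integer_, ok = FALSE)
  keep <- is.finite(signals) & signals > floor_factor * noise_sigma
  if (sum(keep) < 3) return(bad)
  s <- signals[keep]; te <- tes[keep]
  if (stats::sd(s) == 0 && length(unique(te)) > 1) return(bad)
  grid <- exp(seq(log(min(te) / 4), log(max(te) * 10), length.out = 80))
  s2 <- sum(s * s)
  F <- exp(-outer(te, grid, function(a, b) a / b))
  num <- drop(crossprod(F, s))
  denom <- colSums(F * F)
  sse <- s2 - num^2 / denom
  g <- which.min(sse)
  fn <- function(p) s - p[1] * exp(-te / p[2])
  fit <- .lm_polish(c(num[g] / denom[g], grid[g]), fn)
  if (is.null(fit) || fit$par[2] <= 0 || fit$par[1] <= 0) return(bad)
  list(t2 = fit$par[2], m0 = fit$par[1],
       residual = sqrt(fit$deviance), n_used = sum(keep), ok = TRUE)
}

#' Voxel-wise ADC estimation by log-linear fitting
#'
#' Ordinary least squares of \eqn{\ln S} on the b-value across all supplied
#' b-values; the ADC is the negated slope expressed in 10^-3 mm^2/s. With
#' exactly two b-values this reduces to the closed-form two-point slope.
#'
#' @param signals Magnitude signals, one per b-value; all must be > 0.
#' @param bvals b-values, s/mm^2 (>= 2 values).
#' @return A list with `adc` (10^-3 mm^2/s), `s0`, `residual` (log-space
#'   residual norm) and `ok`. Non-positive signals flag the voxel
#'   (`ok = FALSE`).
#' @export
fit_adc_loglinear <- function(signals, bvals) {
  stopifnot(is.numeric(signals), is.numeric(bvals), length(bvals) >= 2,
            length(signals) == length(bvals))
  bad <- list(adc = NA_real_, s0 = NA_real_, residual = NA_real_, ok = FALSE)
  if (any(!is.finite(signals)) || any(signals <= 0)) return(bad)
  y <- log(signals)
  bbar <- mean(bvals); ybar <- mean(y)
  slope <- sum((bvals - bbar) * (y - ybar)) / sum((bvals - bbar)^2)
  intercept <- ybar - slope * bbar
  resid <- y - (intercept + slope * bvals)
  list(adc = -slope * 1000, s0 = exp(intercept),
       residual = sqrt(sum(resid^2)), ok = TRUE)
}

#' Compute a parametric map from an image series
#'
#' Applies the matching voxel-wise fitter (T1 for IR, T2 for CPMG, ADC for
#' DWI) inside a signal mask. The mask keeps voxels whose first-point
#' signal reaches at least `mask_threshold` (default 5 %) of the series
#' maximum; for CPMG fitting the Rician noise sigma is estimated from the
#' excluded (background) voxels of the first frame (Rayleigh mean
#' \eqn{\sigma\sqrt{\pi/2}}), falling back to the sigma recorded in the
#' series metadata when there is no background.
#'
#' @param series An [render_phantom()] / [read_image_series()] result.
#' @param mask_threshold Fraction of the series maximum below which voxels
#'   are excluded.
#' @return An object of class `parametric_map`: `values` (ms or
#'   10^-3 mm^2/s), `m0`, `fit_error`, `mask` (logical), `kind`, `units`,
#'   `noise_sigma_est`, `matrix_size`, `fov`.
#' @export
compute_maps <- function(series, mask_threshold = 0.05) {
  stopifnot(inherits(series, "image_series"))
  pts <- protocol_points(series$protocol)
  if (dim(series$data)[3] != length(pts)) {
    stop("series data and protocol sampling points disagree", call. = FALSE)
  }
  n <- series$matrix_size
  first <- series$data[, , 1]
  mask <- first >= mask_threshold * max(series$data)
  bg <- first[!mask]
  sigma_est <- if (length(bg) >= 50) mean(bg) / sqrt(pi / 2) else series$noise_sigma
  if (!is.finite(sigma_est)) sigma_est <- 0
  values <- m0 <- fit_error <- matrix(NA_real_, n, n)
  idx <- which(mask)
  S <- matrix(series$data, n * n, length(pts))[idx, , drop = FALSE]
  if (series$kind == "dwi") {
    # fully vectorized log-linear fit
    ok <- rowSums(S <= 0) == 0
    Y <- log(pmax(S, .Machine$double.xmin))
    bbar <- mean(pts)
    bc <- pts - bbar
    slope <- drop(Y %*% bc) / sum(bc^2)
    intercept <- rowMeans(Y) - slope * bbar
    R <- Y - outer(intercept, rep(1, length(pts))) - outer(slope, pts)
    values[idx] <- ifelse(ok, -slope * 1000, NA_real_)
    m0[idx] <- ifelse(ok, exp(intercept), NA_real_)
    fit_error[idx] <- ifelse(ok, sqrt(rowSums(R^2)), NA_real_)
  } else if (series$kind == "cpmg") {
    for (j in seq_along(idx)) {
      f <- fit_t2_cpmg(S[j, ], pts, noise_sigma = sigma_est)
      if (f$ok) {
        values[idx[j]] <- f$t2; m0[idx[j]] <- f$m0
        fit_error[idx[j]] <- f$residual
      }
    }
  } else if (series$kind == "ir") {
    for (j in seq_along(idx)) {
      f <- fit_t1_ir(S[j, ], pts, series$protocol$tr)
      if (f$ok) {
        values[idx[j]] <- f$t1; m0[idx[j]] <- f$m0
        fit_error[idx[j]] <- f$residual
      }
    }
  } else {
    stop("unknown series kind", call. = FALSE)
  }
  mask <- mask & is.finite(values)  # drop flagged voxels
  structure(list(values = values, m0 = m0, fit_error = fit_error,
                 mask = mask, kind = series$kind,
                 units = if (series$kind == "dwi") "10^-3 mm^2/s" else "ms",
                 noise_sigma_est = sigma_est,
                 matrix_size = n, fov = series$fov),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<parametric_map> %s [%s]: %d masked voxels, range %.4g-%.4g\n",
              x$kind, x$units, sum(x$mask), min(v), max(v)))
  invisible(x)
}

#' Circular region-of-interest statistics on a parametric map
#'
#' Mean and standard deviation over masked voxels whose centers fall
#' inside the circle.
#'
#' @param map A [compute_maps()] result.
#' @param center Length-2 numeric, ROI center in mm (image-centered
#'   coordinates).
#' @param radius ROI radius, mm.
#' @return A list with `mean`, `sd` and `n` (voxel count).
#' @export
roi_mean <- function(map, center, radius) {
  stopifnot(inherits(map, "parametric_map"), length(center) == 2,
            is.numeric(radius), radius > 0)
  if (any(abs(center) + radius > map$fov / 2)) {
    stop("ROI extends beyond the image", call. = FALSE)
  }
  xs <- voxel_centers(map$matrix_size, map$fov)
  X <- matrix(xs, map$matrix_size, map$matrix_size)
  Y <- matrix(xs, map$matrix_size, map$matrix_size, byrow = TRUE)
  inside <- (X - center[1])^2 + (Y - center[2])^2 <= radius^2
  sel <- inside & map$mask
  if (!any(sel)) stop("ROI contains no masked voxels", call. = FALSE)
  v <- map$values[sel]
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' Build one ROI report row set for a named target
#'
#' @param name ROI / gel label.
#' @param target A [tissue_target()].
#' @param t1,t2,adc Each a list with `mean` and `sd` (e.g. from
#'   [roi_mean()]), or `NULL` when that parameter was not measured.
#' @return A data.frame in the long format consumed by
#'   [validate_against_targets()].
#' @export
roi_report <- function(name, target, t1 = NULL, t2 = NULL, adc = NULL) {
  stopifnot(inherits(target, "tissue_target"))
  row <- function(parameter, tgt, meas) {
    if (is.null(meas)) return(NULL)
    data.frame(name = name, parameter = parameter, target = tgt,
               measured_mean = meas$mean, measured_sd = meas$sd)
  }
  out <- rbind(row("t1", target$t1, t1), row("t2", target$t2, t2),
               row("adc", target$adc, adc))
  if (is.null(out)) stop("at least one measured parameter is required", call. = FALSE)
  out
}

#' Target-versus-measured deviation table
#'
#' Collates ROI reports into a validation table with the percent deviation
#' \eqn{100 |measured - target| / target} per parameter, plus the maximum
#' deviation per parameter as an attribute.
#'
#' @param reports A data.frame from [roi_report()] (or several rbind-ed /
#'   given as a list).
#' @return A `deviation_table` data.frame with columns `name`, `parameter`,
#'   `target`, `measured_mean`, `measured_sd`, `deviation_pct`; attribute
#'   `max_deviation` is a named numeric (per parameter).
#' @export
validate_against_targets <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) {
    reports <- do.call(rbind, reports)
  }
  stopifnot(is.data.frame(reports))
  need <- c("name", "parameter", "target", "measured_mean", "measured_sd")
  missing_cols <- setdiff(need, names(reports))
  if (length(missing_cols)) {
    stop(sprintf("reports are missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(reports$target))) {
    stop("every ROI must be paired with a finite target value", call. = FALSE)
  }
  reports$deviation_pct <-
    100 * abs(reports$measured_mean - reports$target) / reports$target
  maxdev <- tapply(reports$deviation_pct, reports$parameter, max)
  attr(reports, "max_deviation") <- maxdev
  class(reports) <- c("deviation_table", "data.frame")
  reports
}

#' @export
print.deviation_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$target <- signif(df$target, 5)
  df$measured_mean <- signif(df$measured_mean, 5)
  df$measured_sd <- signif(df$measured_sd, 3)
  df$deviation_pct <- round(df$deviation_pct, 2)
  print.data.frame(df, row.names = FALSE)
  md <- attr(x, "max_deviation")
  cat("max deviation [%]:",
      paste(sprintf("%s = %.2f", names(md), md), collapse = ", "), "\n")
  invisible(x)
}

#' Write a parametric map as NIfTI plus a JSON sidecar
#'
#' @param map A [compute_maps()] result.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_parametric_map <- function(map, stem) {
  stopifnot(inherits(map, "parametric_map"))
  pixdim <- map$fov / map$matrix_size
  vals <- map$values
  vals[!map$mask] <- 0
  RNifti::writeNifti(RNifti::asNifti(vals, pixdim = c(pixdim, pixdim)),
                     paste0(stem, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(map$mask + 0, pixdim = c(pixdim, pixdim)),
                     paste0(stem, "_mask.nii.gz"))
  jsonlite::write_json(
    list(kind = map$kind, units = map$units,
         noise_sigma_est = map$noise_sigma_est,
         matrix_size = map$matrix_size, fov = map$fov,
         data_file = basename(paste0(stem, ".nii.gz")),
         mask_file = basename(paste0(stem, "_mask.nii.gz"))),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}
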