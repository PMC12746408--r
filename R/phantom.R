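#' Define a gel tube within a phantom
#'
#' @param center_x,center_y Tube center in mm, relative to the image
#'   center.
#' @param radius Tube radius, mm.
#' @param truth A [tissue_target()]: the ground-truth (T1, T2, ADC) of the
#'   gel filling the tube.
#' @param proton_density Relative equilibrium signal, arbitrary units.
#' @param name Optional label.
#' @return An object of class `phantom_tube`.
#' @export
phantom_tube <- function(center_x, center_y, radius, truth,
                         proton_density = 1, name = NULL) {
  stopifnot(inherits(truth, "tissue_target"))
  structure(list(center_x = .check_scalar(center_x, "center_x"),
                 center_y = .check_scalar(center_y, "center_y"),
                 radius = .check_scalar(radius, "radius", min = 0, strict = TRUE),
                 truth = truth,
                 proton_density = .check_scalar(proton_density, "proton_density",
                                                min = 0, strict = TRUE),
                 name = if (is.null(name)) NA_character_ else as.character(name)),
            class = "phantom_tube")
}

#' A tube-in-housing phantom layout
#'
#' The imaging geometry of the synthetic scanner: a square field of view
#' sampled on a regular matrix, with gel-filled tubes inside an optional
#' circular water housing. Tubes must lie fully inside the field of view
#' and must not overlap.
#'
#' @param tubes List of [phantom_tube()] objects.
#' @param matrix_size Image matrix (one side), voxels. Default 128.
#' @param fov Field of view (one side), mm. Default 200.
#' @param background `NULL` for empty (air) background, or a list with
#'   `truth` (a [tissue_target()]), `radius` (mm) and optionally
#'   `proton_density` describing a water-filled housing disc.
#' @return An object of class `phantom_layout`.
#' @seealso [default_phantom_layout()]
#' @export
phantom_layout <- function(tubes, matrix_size = 128, fov = 200,
                           background = NULL) {
  stopifnot(is.list(tubes), length(tubes) >= 1,
            all(vapply(tubes, inherits, TRUE, "phantom_tube")))
  matrix_size <- as.integer(.check_scalar(matrix_size, "matrix_size", min = 8))
  fov <- .check_scalar(fov, "fov", min = 0, strict = TRUE)
  half <- fov / 2
  for (tb in tubes) {
    if (abs(tb$center_x) + tb$radius > half || abs(tb$center_y) + tb$radius > half) {
      stop(sprintf("tube '%s' extends beyond the field of view", tb$name), call. = FALSE)
    }
  }
  if (length(tubes) > 1) {
    for (i in seq_len(length(tubes) - 1)) for (j in seq(i + 1, length(tubes))) {
      d <- sqrt((tubes[[i]]$center_x - tubes[[j]]$center_x)^2 +
                (tubes[[i]]$center_y - tubes[[j]]$center_y)^2)
      if (d < tubes[[i]]$radius + tubes[[j]]$radius) {
        stop(sprintf("tubes %d and %d overlap", i, j), call. = FALSE)
      }
    }
  }
  if (!is.null(background)) {
    stopifnot(is.list(background), inherits(background$truth, "tissue_target"),
              is.numeric(background$radius), background$radius > 0)
    if (is.null(background$proton_density)) background$proton_density <- 1
  }
  structure(list(tubes = tubes, matrix_size = matrix_size, fov = fov,
                 background = background),
            class = "phantom_layout")
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat(sprintf("<phantom_layout> %d x %d voxels over %g mm FOV; %d tube(s)%s\n",
              x$matrix_size, x$matrix_size, x$fov, length(x$tubes),
              if (is.null(x$background)) ", empty background"
              else sprintf(", water housing r = %g mm", x$background$radius)))
  for (tb in x$tubes) {
    cat(sprintf("  %-14s at (%+6.1f, %+6.1f) mm, r = %4.1f mm: T1 %.4g / T2 %.4g / ADC %.4g\n",
                ifelse(is.na(tb$name), "(unnamed)", tb$name), tb$center_x,
                tb$center_y, tb$radius, tb$truth$t1, tb$truth$t2, tb$truth$adc))
  }
  invisible(x)
}

#' Water ground truth for the background housing
#'
#' The (T1, T2, ADC) of the pure solvent under a calibration: the solvent
#' baseline times plus the zero-lecithin ADC.
#'
#' @param calib A [calibration_set()].
#' @return A [tissue_target()].
#' @export
water_target <- function(calib = default_calibration()) {
  tissue_target(t1 = rate_to_ms(calib$solvent$r1w),
                t2 = rate_to_ms(calib$solvent$r2w),
                adc = adc_forward(0, calib$adc_params))
}

#' The default five-tube validation layout
#'
#' Five tubes of radius 14 mm on a circle of radius 60 mm inside a
#' water-filled housing disc (radius 80 mm), one tube per shipped tissue
#' target (see [tissue_targets()]), on a 128 x 128 matrix over a 200 mm
#' field of view.
#'
#' @param targets A data.frame like [tissue_targets()].
#' @param calib Calibration used for the water background truth.
#' @param matrix_size,fov Grid geometry.
#' @param tube_radius,ring_radius Tube and mounting-circle radii, mm.
#' @param background Include the water housing? Default `TRUE`.
#' @return A [phantom_layout()].
#' @export
default_phantom_layout <- function(targets = tissue_targets(),
                                   calib = default_calibration(),
                                   matrix_size = 128, fov = 200,
                                   tube_radius = 14, ring_radius = 60,
                                   background = TRUE) {
  stopifnot(is.data.frame(targets), nrow(targets) >= 1)
  n <- nrow(targets)
  angles <- pi / 2 + 2 * pi * (seq_len(n) - 1) / n
  tubes <- lapply(seq_len(n), function(i) {
    phantom_tube(center_x = ring_radius * cos(angles[i]),
                 center_y = ring_radius * sin(angles[i]),
                 radius = tube_radius,
                 truth = tissue_target(targets$t1[i], targets$t2[i], targets$adc[i]),
                 name = targets$name[i])
  })
  bg <- if (background) {
    list(truth = water_target(calib), radius = ring_radius + tube_radius + 6,
         proton_density = 1)
  } else NULL
  phantom_layout(tubes, matrix_size = matrix_size, fov = fov, background = bg)
}

# voxel center coordinates (mm) along one axis
voxel_centers <- function(matrix_size, fov) {
  fov * ((seq_len(matrix_size) - 0.5) / matrix_size) - fov / 2
}

# per-voxel ground truth maps for a layout; NA outside any compartment
layout_truth_maps <- function(layout) {
  n <- layout$matrix_size
  xs <- voxel_centers(n, layout$fov)
  X <- matrix(xs, n, n)            # x varies along rows
  Y <- matrix(xs, n, n, byrow = TRUE)
  t1 <- t2 <- adc <- pd <- matrix(NA_real_, n, n)
  tube_id <- matrix(0L, n, n)
  if (!is.null(layout$background)) {
    inside <- X^2 + Y^2 <= layout$background$radius^2
    t1[inside] <- layout$background$truth$t1
    t2[inside] <- layout$background$truth$t2
    adc[inside] <- layout$background$truth$adc
    pd[inside] <- layout$background$proton_density
  }
  for (k in seq_along(layout$tubes)) {
    tb <- layout$tubes[[k]]
    inside <- (X - tb$center_x)^2 + (Y - tb$center_y)^2 <= tb$radius^2
    t1[inside] <- tb$truth$t1
    t2[inside] <- tb$truth$t2
    adc[inside] <- tb$truth$adc
    pd[inside] <- tb$proton_density
    tube_id[inside] <- k
  }
  list(t1 = t1, t2 = t2, adc = adc, pd = pd, tube_id = tube_id)
}
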