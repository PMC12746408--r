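#' Render a synthetic image series over a phantom layout
#'
#' Voxelizes the layout on its matrix (a voxel belongs to a tube when its
#' center falls inside the tube circle), evaluates the analytic signal of
#' the given protocol from the per-voxel ground truth, and applies Rician
#' noise. Voxels outside every compartment have zero noise-free signal
#' (air). The returned series carries the ground-truth maps, so noiseless
#' renders can be checked against the analytic formulas voxel by voxel.
#'
#' @param layout A [phantom_layout()].
#' @param protocol An [ir_protocol()], [cpmg_protocol()] or
#'   [dwi_protocol()].
#' @param noise_sigma Rician component sigma, in the units of the proton
#'   density (default 0: noise-free).
#' @param seed Integer seed for the noise (required when
#'   `noise_sigma > 0`).
#' @return An object of class `image_series`: `data` (array
#'   matrix x matrix x points), `kind`, `protocol`, `truth` (list of T1,
#'   T2, ADC, proton density and tube-id maps), `noise_sigma`, `seed`,
#'   `matrix_size`, `fov`.
#' @export
render_phantom <- function(layout, protocol, noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(layout, "phantom_layout"),
            inherits(protocol, "mr_protocol"))
  noise_sigma <- .check_scalar(noise_sigma, "noise_sigma", min = 0)
  if (noise_sigma > 0 && is.null(seed)) {
    stop("a seed is required when noise_sigma > 0", call. = FALSE)
  }
  truth <- layout_truth_maps(layout)
  pts <- protocol_points(protocol)
  n <- layout$matrix_size
  data <- array(0, dim = c(n, n, length(pts)))
  inside <- !is.na(truth$pd)
  pd <- truth$pd[inside]
  for (p in seq_along(pts)) {
    sig <- switch(protocol$kind,
      ir = ir_signal(truth$t1[inside], pts[p], protocol$tr, pd),
      cpmg = cpmg_signal(truth$t2[inside], pts[p], pd),
      dwi = if (pts[p] == 0) pd else dwi_signal(truth$adc[inside], pts[p], pd))
    frame <- matrix(0, n, n)
    frame[inside] <- sig
    data[, , p] <- frame
  }
  if (noise_sigma > 0) {
    data <- add_rician_noise(data, noise_sigma, seed = seed)
  }
  structure(list(data = data, kind = protocol$kind, protocol = protocol,
                 truth = truth, noise_sigma = noise_sigma,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 matrix_size = n, fov = layout$fov),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  cat(sprintf("<image_series> %s: %d x %d x %d (sigma = %.4g, seed = %s)\n",
              x$kind, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$noise_sigma, ifelse(is.na(x$seed), "none", x$seed)))
  invisible(x)
}

#' Write / read an image series as NIfTI plus a JSON sidecar
#'
#' The signal stack goes to `<stem>.nii.gz` (one 3-D volume, acquisition
#' points along the third axis), the ground-truth maps to
#' `<stem>_truth_{t1,t2,adc,pd}.nii.gz`, and the protocol, noise sigma,
#' seed and file references to `<stem>.json`. `read_image_series(stem)`
#' reconstructs an identical `image_series`.
#'
#' @param series An [render_phantom()] result.
#' @param stem Output path stem (no extension).
#' @return `write_image_series` returns `stem` invisibly;
#'   `read_image_series` returns an `image_series`.
#' @export
write_image_series <- function(series, stem) {
  stopifnot(inherits(series, "image_series"))
  pixdim <- series$fov / series$matrix_size
  wr <- function(arr, path) {
    img <- RNifti::asNifti(arr, pixdim = rep(pixdim, length(dim(arr))))
    RNifti::writeNifti(img, path)
  }
  wr(series$data, paste0(stem, ".nii.gz"))
  truth_files <- list()
  for (nm in c("t1", "t2", "adc", "pd")) {
    f <- paste0(stem, "_truth_", nm, ".nii.gz")
    wr(series$truth[[nm]], f)
    truth_files[[nm]] <- basename(f)
  }
  proto <- series$protocol
  meta <- list(
    kind = series$kind,
    protocol = proto[setdiff(names(proto), "kind")],
    noise_sigma = series$noise_sigma,
    seed = if (is.na(series$seed)) NULL else series$seed,
    matrix_size = series$matrix_size,
    fov = series$fov,
    data_file = basename(paste0(stem, ".nii.gz")),
    truth_files = truth_files)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}

#' @rdname write_image_series
#' @export
read_image_series <- function(stem) {
  meta_path <- paste0(stem, ".json")
  if (!file.exists(meta_path)) stop(sprintf("no sidecar found at %s", meta_path), call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  dirn <- dirname(stem)
  data <- array(as.numeric(RNifti::readNifti(file.path(dirn, meta$data_file))),
                dim = c(meta$matrix_size, meta$matrix_size,
                        length(RNifti::readNifti(file.path(dirn, meta$data_file))) /
                          meta$matrix_size^2))
  truth <- lapply(meta$truth_files, function(f) {
    m <- as.numeric(RNifti::readNifti(file.path(dirn, f)))
    matrix(m, meta$matrix_size, meta$matrix_size)
  })
  # NIfTI has no native NA; zero proton density outside compartments maps
  # back to NA to restore the original truth encoding
  outside <- !is.finite(truth$pd) | truth$pd == 0
  for (nm in c("t1", "t2", "adc", "pd")) truth[[nm]][outside] <- NA_real_
  protocol <- switch(meta$kind,
    ir = ir_protocol(meta$protocol$inversion_times, tr = meta$protocol$tr,
                     te = meta$protocol$te),
    cpmg = cpmg_protocol(meta$protocol$echo_times, tr = meta$protocol$tr),
    dwi = dwi_protocol(meta$protocol$b_values, te = meta$protocol$te))
  truth$tube_id <- NULL
  structure(list(data = data, kind = meta$kind, protocol = protocol,
                 truth = truth, noise_sigma = meta$noise_sigma,
                 seed = if (is.null(meta$seed)) NA_integer_ else as.integer(meta$seed),
                 matrix_size = meta$matrix_size, fov = meta$fov),
            class = "image_series")
}
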