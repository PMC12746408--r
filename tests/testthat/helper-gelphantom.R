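# Shared fixtures, built in code at test time.

# independent inversion oracle: exhaustive grid scan of the forward ADC
# model at a fixed step (default 1e-4 % wt/vol)
grid_scan_lecithin <- function(target_adc, params = adc_model_params(),
                               step = 1e-4, c_max = 10) {
  grid <- seq(0, c_max, by = step)
  adc <- params$a_fast * exp(-params$k_fast * grid) +
    params$a_slow * exp(-params$k_slow * grid)
  grid[which.min(abs(adc - target_adc))]
}

# one gel tube centered in a small empty-background field of view
single_tube_layout <- function(truth, matrix_size = 64, fov = 100,
                               radius = 14) {
  phantom_layout(
    list(phantom_tube(0, 0, radius, truth, name = "tube")),
    matrix_size = matrix_size, fov = fov, background = NULL)
}

# a bare parametric_map with given values, for ROI geometry tests
manual_map <- function(values, fov = 100) {
  structure(list(values = values, m0 = values * 0 + 1,
                 fit_error = values * 0,
                 mask = is.finite(values), kind = "cpmg", units = "ms",
                 noise_sigma_est = 0, matrix_size = nrow(values), fov = fov),
            class = "parametric_map")
}
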