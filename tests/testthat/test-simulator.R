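test_that("analytic signal models evaluate and bound correctly", {
  # IR null point and full recovery
  expect_lt(ir_signal(812, 812 * log(2), tr = 1e7), 1e-6)
  expect_equal(ir_signal(100, 5000, tr = 1e7, m0 = 2.5), 2.5, tolerance = 1e-9)
  expect_equal(ir_signal(812, 25, 10000), 0.939357420681, tolerance = 1e-10)
  # CPMG decay
  expect_equal(cpmg_signal(42, 42), exp(-1))
  expect_equal(cpmg_signal(42, 320), 0.000491009236348, tolerance = 1e-10)
  expect_true(all(diff(cpmg_signal(54, seq(10, 320, 10))) < 0))
  # DWI decay
  expect_equal(dwi_signal(1.0, 0, s0 = 3), 3)
  expect_equal(dwi_signal(1.0, 1000), exp(-1))
  expect_equal(dwi_signal(0.98, 500), 0.612626394184, tolerance = 1e-10)
  expect_true(all(diff(dwi_signal(1.2, c(0, 50, 500, 1000))) < 0))
  expect_error(ir_signal(-1, 25, 1000), "> 0")
  expect_error(cpmg_signal(0, 10), "> 0")
  expect_error(dwi_signal(1, -5), ">= 0")
})

test_that("protocol constructors enforce their sampling invariants", {
  p <- ir_protocol()
  expect_equal(p$inversion_times, c(25, 50, 100, 200, 400, 800, 1600, 3200, 6400))
  expect_error(ir_protocol(inversion_times = c(25, 400, 12000), tr = 10000),
               "below the repetition time")
  q <- cpmg_protocol()
  expect_equal(length(q$echo_times), 32)
  expect_equal(diff(q$echo_times), rep(10, 31))
  expect_error(dwi_protocol(b_values = c(50, 500)), "first b-value")
})

test_that("Rician noise is reproducible and statistically correct", {
  x <- matrix(runif(100), 10, 10)
  expect_identical(add_rician_noise(x, 0), x)
  expect_identical(add_rician_noise(x, 0.1, seed = 3),
                   add_rician_noise(x, 0.1, seed = 3))
  expect_error(add_rician_noise(x, -0.1), ">=")
  # zero-signal magnitude is Rayleigh: mean sigma*sqrt(pi/2)
  sig <- 0.05
  z <- add_rician_noise(rep(0, 1e5), sig, seed = 8)
  expect_equal(mean(z), sig * sqrt(pi / 2), tolerance = 0.02)
  ks <- suppressWarnings(
    stats::ks.test(z, function(q) 1 - exp(-q^2 / (2 * sig^2))))
  expect_gt(ks$p.value, 0.01)
  # high-SNR limit: bias below the asymptotic sigma^2/(2x) envelope
  xb <- 5
  zb <- add_rician_noise(rep(xb, 1e5), sig, seed = 9)
  expect_lt(abs(mean(zb) - xb), sig^2 / (2 * xb) + 3 * sig / sqrt(1e5))
})

test_that("noiseless renders equal the analytic signals at every voxel", {
  lay <- single_tube_layout(tissue_target(812, 42, 0.98), matrix_size = 32)
  for (proto in list(ir_protocol(), cpmg_protocol(), dwi_protocol())) {
    ser <- render_phantom(lay, proto)
    pts <- switch(proto$kind, ir = proto$inversion_times,
                  cpmg = proto$echo_times, dwi = proto$b_values)
    inside <- !is.na(ser$truth$pd)
    expect_gt(sum(inside), 50)
    for (p in seq_along(pts)) {
      frame <- ser$data[, , p]
      expected <- switch(proto$kind,
        ir = ir_signal(812, pts[p], proto$tr),
        cpmg = cpmg_signal(42, pts[p]),
        dwi = dwi_signal(0.98, pts[p]))
      expect_equal(unique(frame[inside]), expected, tolerance = 1e-12)
      expect_true(all(frame[!inside] == 0))
    }
    # truth maps and rendered data are mutually consistent
    expect_true(all(ser$truth$t1[inside] == 812))
  }
})

test_that("layout validation and noisy-render statistics", {
  tt <- tissue_target(1000, 80, 1.2)
  expect_error(phantom_layout(list(
    phantom_tube(0, 0, 10, tt), phantom_tube(5, 5, 10, tt)),
    matrix_size = 32, fov = 100), "overlap")
  expect_error(phantom_layout(list(phantom_tube(45, 45, 10, tt)),
                              matrix_size = 32, fov = 100), "field of view")
  # same seed renders identically; different seeds differ
  lay <- single_tube_layout(tt, matrix_size = 32)
  a <- render_phantom(lay, dwi_protocol(), noise_sigma = 0.02, seed = 4)
  b <- render_phantom(lay, dwi_protocol(), noise_sigma = 0.02, seed = 4)
  d <- render_phantom(lay, dwi_protocol(), noise_sigma = 0.02, seed = 5)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, d$data))
  expect_error(render_phantom(lay, dwi_protocol(), noise_sigma = 0.02),
               "seed")
  # at SNR 50 the in-tube mean of the b = 0 frame stays within 2 %
  inside <- !is.na(a$truth$pd)
  expect_equal(mean(a$data[, , 1][inside]), 1, tolerance = 0.02)
})

test_that("image series round-trip through NIfTI plus sidecar", {
  lay <- single_tube_layout(tissue_target(725, 43, 0.98), matrix_size = 24)
  ser <- render_phantom(lay, dwi_protocol(), noise_sigma = 0.01, seed = 21)
  stem <- file.path(tempdir(), "series_rt")
  write_image_series(ser, stem)
  back <- read_image_series(stem)
  expect_equal(back$data, ser$data, tolerance = 1e-12)
  expect_equal(back$truth$t1, ser$truth$t1)
  expect_equal(back$truth$adc, ser$truth$adc)
  expect_equal(back$protocol$b_values, ser$protocol$b_values)
  expect_equal(back$noise_sigma, 0.01)
  expect_equal(back$seed, 21L)
  unlink(paste0(stem, c(".nii.gz", ".json")), force = TRUE)
  unlink(paste0(stem, "_truth_", c("t1", "t2", "adc", "pd"), ".nii.gz"), force = TRUE)
})
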