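test_that("relaxivity regression is exact on noiseless affine data", {
  conc <- c(0, 0.05, 0.1, 0.15, 0.2)
  rates <- 1 / 3 + 3.78 * conc
  fit <- fit_relaxivity(titration_series("gd", conc, rates, "R1"))
  expect_equal(fit$slope, 3.78, tolerance = 1e-10)
  expect_equal(fit$intercept, 1 / 3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # closed-form OLS oracle on three points
  c3 <- c(0, 1, 3); y3 <- c(0.52, 0.9, 1.1)
  slope_oracle <- sum((c3 - mean(c3)) * (y3 - mean(y3))) / sum((c3 - mean(c3))^2)
  f3 <- fit_relaxivity(titration_series("agarose", c3, y3, "R2"))
  expect_equal(f3$slope, slope_oracle, tolerance = 1e-12)
  # flat responses give slope 0
  flat <- fit_relaxivity(titration_series("lecithin", c(0, 1, 2), rep(0.5, 3), "R2"))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(fit_relaxivity(titration_series("gd", conc,
                                               adc_forward(conc), "ADC")),
               "rate responses")
})

test_that("noisy relaxivity estimates are unbiased and tighten with n", {
  conc <- c(0, 0.05, 0.1, 0.15, 0.2)
  truth <- 1 / 3 + 3.78 * conc
  set.seed(421)
  fits <- lapply(1:200, function(i) {
    fit_relaxivity(titration_series("gd", conc, truth + rnorm(5, 0, 0.02), "R1"))
  })
  slopes <- vapply(fits, `[[`, 0, "slope")
  ses <- vapply(fits, `[[`, 0, "slope_se")
  expect_lt(abs(mean(slopes) - 3.78), 2 * mean(ses))
  # slope_se shrinks roughly as 1/sqrt(n) on a replicated design
  conc4 <- rep(conc, 4) + rep(c(0, 1e-6, 2e-6, 3e-6), each = 5)  # keep strictly increasing after sort
  conc4 <- sort(conc4)
  truth4 <- 1 / 3 + 3.78 * conc4
  set.seed(422)
  ses4 <- replicate(200, fit_relaxivity(
    titration_series("gd", conc4, truth4 + rnorm(20, 0, 0.02), "R1"))$slope_se)
  ratio <- mean(ses4) / mean(ses)
  expect_equal(ratio, 0.5, tolerance = 0.15)
})

test_that("biexponential ADC fit recovers generating parameters", {
  cl <- c(0, 0.5, 1, 2, 3, 4, 5)
  fit <- fit_adc_model(cl, adc_forward(cl))
  truth <- c(0.36, 2.79, 1.60, 0.13)
  est <- c(fit$a_fast, fit$k_fast, fit$a_slow, fit$k_slow)
  expect_equal(est, truth, tolerance = 1e-4)
  expect_false(attr(fit, "degenerate"))
  # self-consistency for random well-separated parameter sets (noiseless)
  set.seed(77)
  cl_dense <- seq(0, 5, by = 0.25)
  for (i in 1:10) {
    p <- adc_model_params(a_fast = runif(1, 0.2, 1), k_fast = runif(1, 2, 6),
                          a_slow = runif(1, 0.8, 2), k_slow = runif(1, 0.05, 0.4))
    y <- adc_forward(cl_dense, p)
    f <- suppressWarnings(fit_adc_model(cl_dense, y))
    expect_equal(c(f$a_fast, f$k_fast, f$a_slow, f$k_slow),
                 c(p$a_fast, p$k_fast, p$a_slow, p$k_slow),
                 tolerance = 1e-3)
  }
})

test_that("degenerate and noisy ADC data are handled", {
  cl <- seq(0, 5, by = 0.5)
  # single-exponential data: degenerate flag, slow component recovered
  y1 <- 1.60 * exp(-0.13 * cl)
  expect_warning(f1 <- fit_adc_model(cl, y1),
                 class = "gelphantom_degenerate_fit")
  expect_true(attr(f1, "degenerate"))
  expect_equal(f1$a_slow, 1.60, tolerance = 1e-6)
  expect_equal(f1$k_slow, 0.13, tolerance = 1e-6)
  # 1 % multiplicative noise, Monte-Carlo over seeds: the typical run
  # recovers all four parameters within ~15 % relative, and the dominant
  # slow component within 5 % (the small fast component is the weakly
  # determined one)
  cl7 <- c(0, 0.5, 1, 2, 3, 4, 5)
  truth <- c(0.36, 2.79, 1.60, 0.13)
  set.seed(31)
  errs <- replicate(40, {
    y2 <- adc_forward(cl7) * (1 + rnorm(length(cl7), 0, 0.01))
    f2 <- suppressWarnings(fit_adc_model(cl7, y2))
    e <- abs(c(f2$a_fast, f2$k_fast, f2$a_slow, f2$k_slow) - truth) / truth
    c(all = max(e), slow = max(e[3:4]))
  })
  expect_lt(median(errs["all", ]), 0.16)
  expect_lt(median(errs["slow", ]), 0.05)
  expect_error(fit_adc_model(c(0, 1, 2), c(1.9, 1.5, 1.2)), "at least 5")
})

test_that("build_calibration validates components and names missing fields", {
  ap <- adc_model_params()
  cal <- build_calibration(3.78, 4.24, 0.10, 0.69, 6.62, ap)
  expect_s3_class(cal, "calibration_set")
  expect_equal(cal$relaxivity$r2_agar, 6.62)
  # relaxivity_fit objects are accepted
  conc <- c(0, 0.05, 0.1, 0.15, 0.2)
  gdfit <- fit_relaxivity(titration_series("gd", conc, 1 / 3 + 3.78 * conc, "R1"))
  cal2 <- build_calibration(gdfit, 4.24, 0.10, 0.69, 6.62, ap)
  expect_equal(cal2$relaxivity$r1_gd, 3.78, tolerance = 1e-10)
  expect_error(build_calibration(3.78, 4.24, 0.10, 0.69, NULL, ap), "r2_agar")
  expect_error(build_calibration(-1, 4.24, 0.10, 0.69, 6.62, ap), "negative")
  expect_error(build_calibration(3.78, 4.24, 0.10, 0.69, 6.62, NULL),
               "adc_params")
})

test_that("calibration round-trips through YAML and JSON config files", {
  cal <- default_calibration()
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("calib.", ext))
    write_calibration(cal, path)
    back <- read_calibration(path)
    expect_equal(back, cal)
    unlink(path)
  }
  # the shipped default file encodes the same calibration
  shipped <- system.file("extdata", "calibration_default.yaml",
                         package = "gelphantom")
  expect_true(nzchar(shipped))
  expect_equal(read_calibration(shipped), cal)
})

test_that("titration design and simulated responses feed the fitters", {
  design <- titration_design()
  expect_equal(nrow(design), 51)
  expect_equal(attr(design, "n_mixtures"), 45)
  expect_true(all(design$gd <= 0.2 & design$lecithin <= 5 & design$agarose <= 4))
  long <- simulate_titration(design)
  # noiseless gd/R1 sweep at zero background recovers the gd r1
  s <- extract_series(long, "gd", "R1", "zero")
  expect_equal(fit_relaxivity(s)$slope, 3.78, tolerance = 1e-10)
  # lecithin/ADC sweep recovers the biexponential coefficients
  sl <- extract_series(long, "lecithin", "ADC", "zero")
  f <- fit_adc_model(sl$concentrations, sl$responses)
  expect_equal(c(f$a_fast, f$k_fast, f$a_slow, f$k_slow),
               c(0.36, 2.79, 1.60, 0.13), tolerance = 1e-4)
  # CSV round trip
  path <- file.path(tempdir(), "titration.csv")
  write_titration(long, path)
  back <- read_titration(path)
  expect_equal(back$response, long$response, tolerance = 1e-12)
  unlink(path)
})
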