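test_that("fitters invert the simulators exactly on noiseless data", {
  p <- ir_protocol(); q <- cpmg_protocol(); d <- dwi_protocol()
  for (t1 in c(812, 1000, 1444, 3000)) {
    s <- ir_signal(t1, p$inversion_times, p$tr, m0 = 1.3)
    f <- fit_t1_ir(s, p$inversion_times, p$tr)
    expect_lt(f$residual / sqrt(sum(s^2)), 1e-8)
    expect_equal(f$t1, t1, tolerance = 1e-3)
    expect_equal(f$m0, 1.3, tolerance = 1e-6)
  }
  for (t2 in c(42, 80, 54)) {
    s <- cpmg_signal(t2, q$echo_times, m0 = 0.7)
    f <- fit_t2_cpmg(s, q$echo_times)
    expect_lt(f$residual / sqrt(sum(s^2)), 1e-8)
    expect_equal(f$t2, t2, tolerance = 1e-6)
  }
  for (adc in c(0.84, 1.25, 1.75)) {
    s <- dwi_signal(adc, d$b_values, s0 = 2)
    f <- fit_adc_loglinear(s, d$b_values)
    expect_equal(f$adc, adc, tolerance = 1e-12)
    expect_equal(f$s0, 2, tolerance = 1e-12)
  }
})

test_that("estimates are invariant to uniform signal scaling", {
  p <- ir_protocol()
  s <- ir_signal(1084, p$inversion_times, p$tr)
  expect_equal(fit_t1_ir(37 * s, p$inversion_times, p$tr)$t1,
               fit_t1_ir(s, p$inversion_times, p$tr)$t1, tolerance = 1e-9)
  te <- seq(10, 320, 10)
  s2 <- cpmg_signal(69, te)
  expect_equal(fit_t2_cpmg(37 * s2, te)$t2, fit_t2_cpmg(s2, te)$t2,
               tolerance = 1e-9)
  bv <- c(0, 50, 500, 1000)
  s3 <- dwi_signal(0.9, bv)
  expect_equal(fit_adc_loglinear(37 * s3, bv)$adc,
               fit_adc_loglinear(s3, bv)$adc, tolerance = 1e-12)
})

test_that("two-b-value ADC fit equals the closed-form two-point slope", {
  s <- dwi_signal(1.11, c(0, 1000), s0 = 1.4)
  f <- fit_adc_loglinear(s, c(0, 1000))
  expect_equal(f$adc, (log(s[1]) - log(s[2])) / 1000 * 1000, tolerance = 1e-12)
  expect_false(fit_adc_loglinear(c(1, -0.1, 0.5, 0.2), c(0, 50, 500, 1000))$ok)
})

test_that("voxel-wise estimates recover truth at SNR 50", {
  p <- ir_protocol()
  set.seed(501)
  s0 <- ir_signal(1444, p$inversion_times, p$tr)
  t1e <- replicate(500, fit_t1_ir(add_rician_noise(s0, 0.02),
                                  p$inversion_times, p$tr)$t1)
  expect_equal(median(t1e), 1444, tolerance = 0.02)
  te <- seq(10, 320, 10)
  s2 <- cpmg_signal(54, te)
  t2e <- replicate(500, fit_t2_cpmg(add_rician_noise(s2, 0.02), te,
                                    noise_sigma = 0.02)$t2)
  expect_equal(median(t2e), 54, tolerance = 0.03)
  bv <- c(0, 50, 500, 1000)
  s3 <- dwi_signal(1.75, bv)
  adce <- replicate(500, fit_adc_loglinear(add_rician_noise(s3, 0.02), bv)$adc)
  expect_equal(median(adce), 1.75, tolerance = 0.02)
})

test_that("estimator bias shrinks as SNR grows", {
  te <- seq(10, 320, 10)
  bv <- c(0, 50, 500, 1000)
  s2 <- cpmg_signal(54, te)
  s3 <- dwi_signal(1.75, bv)
  snrs <- c(10, 25, 50, 100)
  set.seed(1234)
  t2_bias <- adc_bias <- adc_se <- numeric(length(snrs))
  for (i in seq_along(snrs)) {
    sig <- 1 / snrs[i]
    t2e <- replicate(400, fit_t2_cpmg(add_rician_noise(s2, sig), te,
                                      noise_sigma = sig)$t2)
    ae <- replicate(400, fit_adc_loglinear(add_rician_noise(s3, sig), bv)$adc)
    t2_bias[i] <- abs(mean(t2e, na.rm = TRUE) - 54) / 54
    adc_bias[i] <- abs(mean(ae) - 1.75) / 1.75
    adc_se[i] <- sd(ae) / sqrt(400) / 1.75
  }
  expect_true(all(diff(t2_bias) < 0))
  # ADC bias falls below Monte-Carlo resolution above SNR ~25; require
  # non-increase up to the sampling envelope of the estimate
  expect_true(all(diff(adc_bias) < 2 * (adc_se[-1] + adc_se[-length(adc_se)])))
  expect_gt(adc_bias[1], adc_bias[4])
})

test_that("compute_maps reproduces truth maps and masks background", {
  lay <- single_tube_layout(tissue_target(1084, 69, 0.84), matrix_size = 32)
  inside <- !is.na(layout_truth <- render_phantom(lay, dwi_protocol())$truth$pd)
  for (proto in list(ir_protocol(), cpmg_protocol(), dwi_protocol())) {
    ser <- render_phantom(lay, proto)
    map <- compute_maps(ser)
    truth_map <- switch(proto$kind, ir = ser$truth$t1, cpmg = ser$truth$t2,
                        dwi = ser$truth$adc)
    expect_true(all(map$mask == inside))
    expect_equal(map$values[map$mask], truth_map[inside], tolerance = 1e-6)
    expect_true(all(is.na(map$values[!map$mask])))
  }
  # protocol/series mismatch is rejected
  ser <- render_phantom(lay, dwi_protocol())
  ser$protocol <- cpmg_protocol()
  expect_error(compute_maps(ser), "disagree")
})

test_that("ROI statistics follow the voxel geometry", {
  n <- 40; fov <- 100
  vals <- matrix(500, n, n)
  map <- manual_map(vals, fov)
  r <- roi_mean(map, c(0, 0), 20)
  expect_equal(r$mean, 500)
  expect_equal(r$sd, 0)
  # two-valued map split at x = 0: ROI mean is the voxel-count-weighted mean
  vals2 <- matrix(100, n, n)
  xs <- fov * ((seq_len(n) - 0.5) / n) - fov / 2
  vals2[xs > 0, ] <- 300
  map2 <- manual_map(vals2, fov)
  X <- matrix(xs, n, n); Y <- matrix(xs, n, n, byrow = TRUE)
  inside <- X^2 + Y^2 <= 15^2
  expected <- (100 * sum(inside & X <= 0) + 300 * sum(inside & X > 0)) /
    sum(inside)
  expect_equal(roi_mean(map2, c(0, 0), 15)$mean, expected)
  expect_error(roi_mean(map, c(49, 0), 10), "beyond")
  empty <- manual_map(matrix(NA_real_, n, n), fov)
  expect_error(roi_mean(empty, c(0, 0), 10), "no masked voxels")
})

test_that("deviation tables compare measured values against targets", {
  tgt <- tissue_target(725, 43, 0.98)
  rep0 <- roi_report("pancreas", tgt,
                     t1 = list(mean = 725, sd = 0),
                     t2 = list(mean = 43, sd = 0),
                     adc = list(mean = 0.98, sd = 0))
  tab0 <- validate_against_targets(rep0)
  expect_true(all(tab0$deviation_pct == 0))
  # a 757 ms measurement against a 725 ms target deviates by ~4.4 %
  rep1 <- roi_report("pancreas", tgt, t1 = list(mean = 757, sd = 16))
  tab1 <- validate_against_targets(rep1)
  expect_equal(tab1$deviation_pct, 100 * 32 / 725, tolerance = 1e-12)
  expect_equal(round(tab1$deviation_pct, 1), 4.4)
  md <- attr(validate_against_targets(list(rep0, rep1)), "max_deviation")
  expect_equal(unname(md["t1"]), 100 * 32 / 725)
  bad <- rep1; bad$target <- NA_real_
  expect_error(validate_against_targets(bad), "paired")
})
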