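test_that("lecithin inversion matches an exhaustive grid scan", {
  # frozen oracle values from a 1e-4-step scan of the forward model
  expect_equal(solve_lecithin(0.98), 3.7709, tolerance = 1e-4)
  expect_equal(solve_lecithin(1.40), 1.1157, tolerance = 1e-4)
  expect_equal(solve_lecithin(1.96), 0)
  set.seed(11)
  targets <- runif(100, adc_forward(10) + 0.01, 1.95)
  for (tg in targets) {
    expect_lt(abs(solve_lecithin(tg) - grid_scan_lecithin(tg)), 1e-4)
  }
  # the returned concentration reproduces the ADC to the solver tolerance
  expect_lt(abs(adc_forward(solve_lecithin(1.1)) - 1.1), 1e-9)
  expect_error(solve_lecithin(2.0), class = "gelphantom_infeasible")
  expect_error(solve_lecithin(0.2), class = "gelphantom_infeasible")
})

test_that("Gd and agarose steps match their closed forms and detect infeasibility", {
  calib <- default_calibration()
  # boundary: target T1 equal to the lecithin-loaded baseline needs no Gd
  c_lec <- 2
  t1_boundary <- 1000 / (calib$solvent$r1w + 0.10 * c_lec)
  expect_equal(solve_gd(t1_boundary, c_lec), 0, tolerance = 1e-12)
  # liver-like worked values (frozen closed-form evaluations)
  c_lec_liver <- solve_lecithin(1.40)
  c_gd_liver <- solve_gd(812, c_lec_liver)
  expect_equal(c_gd_liver, 0.2081015, tolerance = 1e-4)
  expect_gt(c_gd_liver, 0.2)  # outside the calibrated Gd range
  expect_equal(solve_agarose(42, c_lec_liver, c_gd_liver),
               3.2715016, tolerance = 1e-4)
  # long T1 at heavy lecithin load is unreachable
  expect_error(solve_gd(2500, 4.43), class = "gelphantom_infeasible")
  # T2 longer than the lecithin+Gd baseline is unreachable
  expect_error(solve_agarose(300, 5, 0.2), class = "gelphantom_infeasible")
  # boundary: target T2 equal to the agarose-free baseline needs no agarose
  base_t2 <- 1000 / (calib$solvent$r2w + 4.24 * 0.1 + 0.69 * 2)
  expect_equal(solve_agarose(base_t2, 2, 0.1), 0, tolerance = 1e-12)
})

test_that("the three-step recipe round-trips through the forward models", {
  calib <- default_calibration()
  tt <- tissue_targets()
  for (i in seq_len(nrow(tt))) {
    res <- solve_recipe(tissue_target(tt$t1[i], tt$t2[i], tt$adc[i]), calib)
    expect_true(res$feasible)
    expect_equal(res$predicted$t1, tt$t1[i], tolerance = 1e-9)
    expect_equal(res$predicted$t2, tt$t2[i], tolerance = 1e-9)
    expect_equal(res$predicted$adc, tt$adc[i], tolerance = 1e-9)
  }
  # random feasible targets: predict_triple(solve_recipe(t)) == t
  set.seed(99)
  n_ok <- 0
  while (n_ok < 1000) {
    adc <- runif(1, 0.82, 1.95)
    t1max <- max_t1_at_adc(adc)
    t1 <- runif(1, 400, t1max)
    t2max <- baseline_t2(adc, t1)
    t2 <- runif(1, 30, min(t2max, t1 * 0.9))
    res <- solve_recipe(tissue_target(t1, t2, adc), calib)
    expect_true(res$feasible)
    expect_equal(res$predicted$t1, t1, tolerance = 1e-9)
    expect_equal(res$predicted$t2, t2, tolerance = 1e-9)
    expect_equal(res$predicted$adc, adc, tolerance = 1e-9)
    n_ok <- n_ok + 1
  }
})

test_that("infeasible targets name exactly one failing step", {
  # gray-matter-like: low ADC plus long T1 fails at the Gd step
  gm <- solve_recipe(tissue_target(1600, 80, 0.9))
  expect_false(gm$feasible)
  expect_equal(gm$failed_step, "gd")
  # ADC above the water limit fails at the lecithin step
  hi <- solve_recipe(tissue_target(1000, 80, 2.5))
  expect_false(hi$feasible)
  expect_equal(hi$failed_step, "lecithin")
  # T2 above the mixture baseline fails at the agarose step
  t2hi <- solve_recipe(tissue_target(900, 600, 0.9))
  expect_false(t2hi$feasible)
  expect_equal(t2hi$failed_step, "agarose")
  # the pure-water triple needs no ingredients at all
  w <- solve_recipe(tissue_target(3000, 2000, 1.96))
  expect_true(w$feasible)
  expect_equal(w$concentrations$gd, 0, tolerance = 1e-9)
  expect_lt(w$concentrations$lecithin, 1e-6)
  expect_equal(w$concentrations$agarose, 0, tolerance = 1e-9)
  expect_true(any(grepl("near-boundary", w$warnings)))
})

test_that("feasibility boundaries behave as the forward models dictate", {
  # frozen closed-form values at the default water baselines
  expect_equal(max_t1_at_adc(0.9), 1288.787, tolerance = 1e-4)
  expect_lte(max_t1_at_adc(0.9), 1400)
  expect_equal(max_t1_at_adc(1.96), 3000)
  expect_lt(max_t1_at_adc(0.9), max_t1_at_adc(1.5))
  expect_equal(baseline_t2(1.96, 3000), 2000)
  expect_equal(baseline_t2(0.8, 700), 207.9237, tolerance = 1e-4)
  # baseline T2 stays above 200 ms over the working domain
  g <- feasibility_grid()
  expect_equal(dim(g$achievable), c(121, 131))
  expect_gt(min(g$baseline_t2, na.rm = TRUE), 200)
  expect_true(all(is.na(g$baseline_t2[!g$achievable])))
  expect_true(all(is.finite(g$baseline_t2[g$achievable])))
})

test_that("the feasibility grid agrees with the pointwise boundary", {
  g <- feasibility_grid(resolution = c(25, 27))
  for (i in seq_along(g$adc_axis)) {
    t1max <- tryCatch(max_t1_at_adc(g$adc_axis[i]),
                      gelphantom_infeasible = function(e) NA_real_)
    expected <- if (is.na(t1max)) rep(FALSE, length(g$t1_axis))
                else g$t1_axis <= t1max
    expect_equal(g$achievable[i, ], expected)
  }
  # feasibility is monotone: anything below a feasible T1 is feasible
  for (i in seq_along(g$adc_axis)) {
    col <- g$achievable[i, ]
    expect_true(all(diff(as.integer(col)) <= 0))  # TRUEs form a prefix
  }
  # tissue targets sit inside the region, gray matter partly outside
  tt <- tissue_targets()
  for (j in seq_len(nrow(tt))) {
    expect_lte(tt$t1[j], max_t1_at_adc(tt$adc[j]))
  }
  gm_box <- expand.grid(adc = c(0.8, 0.9, 1.0), t1 = c(1500, 1700, 1850))
  infeasible_gm <- mapply(function(a, t) t > max_t1_at_adc(a),
                          gm_box$adc, gm_box$t1)
  expect_true(any(infeasible_gm))
  expect_error(feasibility_grid(adc_range = c(1, 1)), "increasing")
})
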