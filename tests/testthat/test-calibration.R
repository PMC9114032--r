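test_that("reference lumps match the brute-force grid-refinement oracle", {
  case <- make_reference_case()
  cal <- calibrate_reference_resistances(case)
  r <- cal$resistances
  # independent grid-refinement search over the three balance equations
  ref <- oracle_calibrate_lumps(P_in = 20.837, R_art = 24.138,
                                Rb = 0.330, Rc = 3970,
                                Qb = 1.645, Qnb = 1.168, Qc = 0.511)
  expect_equal(unname(r), unname(ref), tolerance = 1e-4)
  expect_equal(r[["R_feed"]], 1.0235, tolerance = 1e-3)
  expect_equal(r[["R_AO"]], 16.016, tolerance = 1e-3)
  expect_equal(r[["R_ven"]], 16.068, tolerance = 1e-3)
  expect_lt(cal$residual, 1e-10)
  expect_equal(cal$alpha, 220, tolerance = 1e-3)
  # the calibrated network reproduces all three targets through solve_flow
  base <- summarise_stage(solve_flow(build_stage_network(case, r, 0.330)))
  comp <- summarise_stage(solve_flow(build_stage_network(case, r, 3970)))
  expect_equal(base$Q_inlet, 1.645, tolerance = 1e-9)
  expect_equal(base$Q_nidus, 1.168, tolerance = 1e-9)
  expect_equal(comp$Q_inlet, 0.511, tolerance = 1e-9)
})

test_that("calibration recovers known lumps from synthetic ground truth", {
  worst <- 0
  for (seed in 1:50) {
    synth <- make_synthetic_avm(seed)
    cal <- calibrate_reference_resistances(synth$case)
    dev <- abs(cal$resistances - synth$truth$resistances) /
      synth$truth$resistances
    worst <- max(worst, dev)
    expect_equal(cal$alpha, synth$truth$alpha, tolerance = 5e-3)
  }
  expect_lt(worst, 5e-3)
})

test_that("infeasible calibration targets raise informative errors", {
  case <- make_reference_case()
  # baseline nidus flow above the inlet flow is impossible
  case$stages$Q_nidus_target[1] <- 2.0
  expect_error(calibrate_reference_resistances(case), "infeasible")
  case <- make_reference_case()
  # completion target above the attainable range
  case$stages$Q_target[nrow(case$stages)] <- 3.0
  expect_error(calibrate_reference_resistances(case), "attainable")
})

test_that("stage permeability calibration hits the flow target", {
  case <- make_reference_case()
  cal <- calibrate_reference_resistances(case)
  fit <- calibrate_stage_permeability(case, cal, 1.011)
  expect_equal(fit$Q_inlet, 1.011, tolerance = 1e-6 / 1.011)
  expect_equal(fit$R_nidus, 22.17, tolerance = 1e-3)
  expect_equal(fit$K, 2.98e-10, tolerance = 5e-3)
  # closed-form junction-balance oracle: back out the nidus branch
  # resistance from the target flow and the known lumps
  r <- cal$resistances
  PJ <- 20.837 - 1.011 * r[["R_feed"]]
  Q_art <- PJ / (r[["R_AO"]] + 24.138)
  R_expected <- PJ / (1.011 - Q_art) - r[["R_ven"]]
  expect_equal(fit$R_nidus, unname(R_expected), tolerance = 1e-8)
  # round trip: baseline target recovers baseline K
  rt <- calibrate_stage_permeability(case, cal, 1.645)
  expect_equal(rt$K, 2e-8, tolerance = 5e-3)
  # invariant to the initial bracket as long as it contains the root
  alt <- calibrate_stage_permeability(case, cal, 1.011,
                                      log10K_bracket = c(-12, -6))
  expect_equal(alt$K, fit$K, tolerance = 1e-9)
  # out-of-range target reports the attainable bounds
  expect_error(calibrate_stage_permeability(case, cal, 5), "attainable range")
  expect_error(calibrate_stage_permeability(case, cal, 0.1),
               "attainable range")
})

test_that("quadratic interpolation of a missing stage works in log10 K", {
  # collinear knots reduce to linear interpolation
  st <- data.frame(index = c(1, 3, 5), K = 10^c(-8, -10, -12))
  expect_equal(log10(interpolate_missing_stage(st, 4)), -11,
               tolerance = 1e-12)
  # general case agrees with an independent Lagrange oracle
  st2 <- data.frame(index = c(1, 2, 4), K = 10^c(-8, -8.6, -11))
  got <- log10(interpolate_missing_stage(st2, 3))
  expect_equal(got, oracle_lagrange3(3, st2$index, log10(st2$K)),
               tolerance = 1e-12)
  # knot order is irrelevant
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(interpolate_missing_stage(st2[perm, ], 3),
                 interpolate_missing_stage(st2, 3), tolerance = 1e-12)
  }
  # the interpolant reproduces its knots exactly
  for (i in 1:3) {
    expect_equal(interpolate_missing_stage(st2, st2$index[i]), st2$K[i],
                 tolerance = 1e-10)
  }
  expect_error(interpolate_missing_stage(st2[c(1, 1, 2), ], 3), "duplicate")
  expect_error(interpolate_missing_stage(st2[1:2, ], 3), "three")
  expect_warning(interpolate_missing_stage(st2, 6), "extrapolating")
})

test_that("shape factor reproduces the printed stage anchors", {
  expect_equal(nidus_shape_factor(2e-8, 0.330, 4e-3), 220, tolerance = 1e-3)
  # completion pair deviates ~10% from constant alpha (3D geometry effect)
  a_comp <- nidus_shape_factor(1.5e-12, 3970, 4e-3)
  expect_equal(a_comp, 198.5, tolerance = 1e-3)
  expect_gt(abs(a_comp - 220) / 220, 0.05)
  expect_error(nidus_shape_factor(-1, 1, 1), "positive")
})
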