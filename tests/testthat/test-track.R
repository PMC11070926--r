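test_that("energy-LET conversion is consistent both ways", {
  # formula and embedded table agree (the table was frozen from the
  # formula; interpolation error only)
  tab <- o16_let_table()
  expect_equal(energy_to_let(tab$energy_mev_u), tab$let_kev_um,
               tolerance = 1e-3)
  for (lv in c(26, 66, 98, 141)) {
    e <- let_to_energy(lv)
    expect_equal(energy_to_let(e), lv, tolerance = 0.02)
  }
  # plateau regime: ~300 MeV/u oxygen sits near 22 keV/um
  expect_equal(energy_to_let(300), 22, tolerance = 0.1)
  b <- ion_beam(let_value = 98)
  expect_true(b$beta_v > 0 && b$beta_v < 1)
})

test_that("radial dose obeys the 1/r^2 law and the LET normalisation", {
  params <- lem_params()
  for (lv in c(26, 98, 200)) {
    beam <- ion_beam(let_value = lv)
    r_max <- params$track_coeff * beam$energy^params$track_exp
    # adaptive quadrature recovers 0.1602 * LET within 0.5%
    core <- integrate(function(r) radial_dose(r, beam, params) * 2 * pi * r,
                      0, params$r_min, rel.tol = 1e-9)$value
    pen <- integrate(function(r) radial_dose(r, beam, params) * 2 * pi * r,
                     params$r_min, r_max, rel.tol = 1e-9)$value
    expect_equal(core + pen, 0.1602 * lv, tolerance = 0.005)
  }
  beam <- ion_beam(let_value = 98)
  rmin <- params$r_min
  # constant core, then exact 1/r^2 fall-off
  expect_equal(radial_dose(rmin / 3, beam, params),
               radial_dose(rmin, beam, params))
  expect_equal(radial_dose(rmin * 1.5, beam, params) * (rmin * 1.5)^2,
               radial_dose(rmin * 3, beam, params) * (rmin * 3)^2,
               tolerance = 1e-12)
  # doubling LET at fixed energy doubles the local dose everywhere
  b1 <- ion_beam(energy = 100, let_value = 50)
  b2 <- ion_beam(energy = 100, let_value = 100)
  r <- c(0.1, 0.5, 2, 10)
  expect_equal(radial_dose(r, b2, params), 2 * radial_dose(r, b1, params))
})

test_that("LEM I low-dose coefficients behave in the photon and overkill limits", {
  ph <- photon_lq(0.1, 2, 30)
  expect_equal(ph$s_max, 3.1)
  # vanishing LET at high energy: local doses are photon-like and the
  # low-dose slope approaches alpha_x from above
  thin <- lem1_alpha_beta(ion_beam(energy = 300, let_value = 0.1), ph)
  expect_equal(thin$alpha_ion, 0.1, tolerance = 0.2)
  expect_gte(thin$alpha_ion, 0.1)
  # alpha + beta consistency: beta_ion = (s_max - alpha)/2 d_t
  res <- lem1_alpha_beta(ion_beam(let_value = 98), ph)
  expect_equal(res$beta_ion, (3.1 - res$alpha_ion) / 60)
  # analytic oracle for the unsaturated penumbra integral
  params <- lem_params()
  beam <- ion_beam(let_value = 66)
  r_max <- params$track_coeff * beam$energy^params$track_exp
  k <- 0.1602 * 66 / (pi * (1 + 2 * log(r_max / params$r_min)))
  analytic <- pi * params$r_min^2 *
    (ph$alpha_x * k / params$r_min^2 + ph$beta_x * (k / params$r_min^2)^2) +
    2 * pi * ph$alpha_x * k * log(r_max / params$r_min) +
    pi * ph$beta_x * k^2 * (params$r_min^-2 - r_max^-2)
  res66 <- lem1_alpha_beta(beam, ph)
  expect_false(res66$saturated)
  expect_equal(res66$alpha_ion, analytic / (0.1602 * 66), tolerance = 1e-6)
})

test_that("mMKM specific energy saturates correctly", {
  params <- mkm_params()
  # z0 convention: sphere mean chord with the 0.1602 constant
  expect_equal(params$z_0, 0.1602 * 150 / (pi * 0.3^2), tolerance = 1e-10)
  expect_equal(params$beta_m, 0.0015)

  beam <- ion_beam(let_value = 98)
  z1d <- mkm_zstar(beam, params, saturation = FALSE)
  zs <- mkm_zstar(beam, params)
  expect_lte(zs, z1d)
  # z0 -> Inf removes the correction entirely
  expect_equal(mkm_zstar(beam, mkm_params(z_0 = Inf)), z1d)

  # z*1D <= z1D across a LET scan, growth sub-linear at high LET
  lets <- c(20, 60, 100, 140, 200)
  zsat <- vapply(lets, function(l) mkm_zstar(ion_beam(let_value = l)), 0)
  zraw <- vapply(lets, function(l)
    mkm_zstar(ion_beam(let_value = l), saturation = FALSE), 0)
  expect_true(all(zsat <= zraw + 1e-12))
  expect_true(all(diff(zsat) > 0))
  # saturation bites harder at high LET
  expect_gt((zraw - zsat)[5] / zraw[5], (zraw - zsat)[1] / zraw[1])

  # linear alpha law
  ab0 <- mkm_alpha_beta(0, params)
  expect_equal(ab0$alpha_ion, 0.003)
  expect_equal(ab0$beta_ion, 0.0015)
  expect_equal(mkm_alpha_beta(20, params)$alpha_ion - 0.003,
               2 * (mkm_alpha_beta(10, params)$alpha_ion - 0.003))
})

test_that("mixed-field averaging is exact on its invariants", {
  one <- mixed_field(1, 0.2, 0.03)
  expect_equal(one$alpha_mix, 0.2)
  expect_equal(one$beta_mix, 0.03)
  same <- mixed_field(c(0.5, 0.5), c(0.2, 0.2), c(0.03, 0.03))
  expect_equal(same$alpha_mix, 0.2)
  expect_equal(same$beta_mix, 0.03)
  mix <- mixed_field(c(0.3, 0.7), c(0.1, 0.5), c(0.01, 0.05))
  expect_gte(mix$alpha_mix, 0.1)
  expect_lte(mix$alpha_mix, 0.5)
  expect_error(mixed_field(c(0.5, 0.6), c(1, 1), c(1, 1)),
               class = "ionrbe_bad_argument")
})

test_that("predicted RBE has the right identity, low-dose and monotone limits", {
  ph <- photon_lq(0.1, 2, 30)
  # ion LQ identical to photon LQ: RBE exactly 1 at any dose
  for (d in c(0.5, 2, 13.5)) {
    expect_equal(predict_rbe(ph$alpha_x, ph$beta_x, ph, d)$rbe, 1,
                 tolerance = 1e-12)
  }
  # low-dose limit is the alpha ratio
  expect_equal(predict_rbe(0.2, ph$beta_x, ph, 1e-7)$rbe, 2,
               tolerance = 1e-4)
  # decreasing in dose when alpha ratio exceeds sqrt(beta ratio)
  d <- seq(0.5, 20, 0.5)
  rb <- predict_rbe(0.3, 0.05, ph, d)$rbe
  expect_true(all(diff(rb) < 0))
})

test_that("model comparison table flags and summarises deviations", {
  meas <- data.frame(let_value = c(26, 66, 98), n_fractions = 1L,
                     rbe = c(1.4, 1.7, 1.8),
                     cl_low = c(1.3, 1.6, 1.7), cl_high = c(1.5, 1.8, 1.9),
                     in_sobp = c(FALSE, TRUE, TRUE))
  pred <- data.frame(model_name = "toy", let_value = c(26, 66, 98),
                     n_fractions = 1L, dose_per_fraction = 10,
                     alpha_ion = 0.1, beta_ion = 0.05,
                     rbe = c(1.4, 1.75, 1.2))
  cmp <- model_comparison(meas, pred)
  expect_equal(cmp$table$deviation[cmp$table$let_value == 26], 0)
  expect_false(cmp$table$significant[cmp$table$let_value == 66])
  expect_true(cmp$table$significant[cmp$table$let_value == 98])  # below CL
  # SOBP mean +/- SD by hand: deviations 0.05 and -0.6
  expect_equal(cmp$summary$plateau_deviation, 0)
  expect_equal(cmp$summary$sobp_mean, mean(c(0.05, -0.6)))
  expect_equal(cmp$summary$sobp_sd, sd(c(0.05, -0.6)))
  # identical predictions: all deviations zero, nothing significant
  pred0 <- pred
  pred0$rbe <- meas$rbe
  cmp0 <- model_comparison(meas, pred0)
  expect_true(all(cmp0$table$deviation == 0))
  expect_equal(cmp0$summary$n_significant, 0)
  # unmatched keys halt
  expect_error(model_comparison(meas[1:2, ], pred),
               class = "ionrbe_unmatched")
})
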