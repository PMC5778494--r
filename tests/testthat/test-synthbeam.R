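test_that("range-energy relations are mutually consistent", {
  m <- range_energy_model()
  expect_equal(residual_energy(m, 155, 0), 155)
  R155 <- proton_range(m, 155)
  ## direct power-law arithmetic: 10 * 0.0022 * 155^1.77 mm
  expect_equal(R155, 10 * 0.0022 * 155^1.77, tolerance = 1e-12)
  expect_equal(R155 / 10, 16.6, tolerance = 0.01)      # ~16.6 cm in water
  expect_equal(residual_energy(m, 155, R155), 0)
  E <- residual_energy(m, 155, seq(0, 150, by = 10))
  expect_true(all(diff(E) < 0))

  ## stopping power equals the depth derivative of residual energy
  ## (1 keV/um = 1 MeV/mm, so the numbers compare one-to-one)
  z <- c(10, 60, 120); h <- 1e-4
  fd <- -(residual_energy(m, 155, z + h) - residual_energy(m, 155, z - h)) /
    (2 * h)
  expect_equal(stopping_power(m, residual_energy(m, 155, z)), fd,
               tolerance = 1e-3)

  ## scaling and monotonicity
  m2 <- range_energy_model(bk_alpha = 0.0044)
  expect_equal(stopping_power(m2, 100), stopping_power(m, 100) / 2)
  expect_gt(stopping_power(m, 10), stopping_power(m, 100))
  expect_error(stopping_power(m, 0), class = "mkm_error_invalid_parameter")
})

test_that("pristine Bragg curves peak at the range and vanish beyond it", {
  ## construction oracle without the depth-dependent fluence attenuation,
  ## which pulls the argmax slightly shallower
  cfg <- beam_config(depth_grid = seq(0, 180, by = 0.5),
                     nuclear_attenuation = 0)
  m <- range_energy_model()
  pb <- pristine_bragg(cfg, m)
  R <- attr(pb, "range_mm"); sig <- attr(pb, "sigma_mm")
  peak_z <- pb$depth_mm[which.max(pb$physical_dose_Gy)]
  expect_lt(abs(peak_z - R), 1.5 * sig)
  expect_true(all(pb$physical_dose_Gy >= 0))
  expect_lt(max(pb$physical_dose_Gy[pb$depth_mm > R + 4 * sig]),
            1e-4 * max(pb$physical_dose_Gy))
  expect_gt(max(pb$physical_dose_Gy) / pb$physical_dose_Gy[1], 2)

  ## higher energy -> deeper peak, monotonically
  peaks <- sapply(c(100, 120, 136.7), function(E) {
    p <- pristine_bragg(cfg, m, E)
    p$depth_mm[which.max(p$physical_dose_Gy)]
  })
  expect_true(all(diff(peaks) > 0))

  ## resolution guards
  expect_error(pristine_bragg(beam_config(depth_grid = seq(0, 180, by = 10))),
               class = "mkm_error_grid_too_coarse")
  expect_error(pristine_bragg(beam_config(depth_grid = seq(0, 100, by = 0.5))),
               class = "mkm_error_grid_too_short")
})

test_that("integrated dose tracks the beam energy (attenuation off)", {
  m <- range_energy_model()
  ratio <- sapply(c(110, 136.7, 160), function(E) {
    cfg <- beam_config(entrance_energy = E, nuclear_attenuation = 0,
                       depth_grid = seq(0, 1.1 * proton_range(m, E), by = 0.5))
    pb <- pristine_bragg(cfg, m, E)
    pracma::trapz(pb$depth_mm, pb$physical_dose_Gy) / E
  })
  expect_lt(diff(range(ratio)) / mean(ratio), 0.02)
  ## nuclear attenuation removes dose
  cfgA <- beam_config(depth_grid = seq(0, 180, by = 0.5))
  cfg0 <- beam_config(nuclear_attenuation = 0,
                      depth_grid = seq(0, 180, by = 0.5))
  dA <- pristine_bragg(cfgA, m)$physical_dose_Gy
  d0 <- pristine_bragg(cfg0, m)$physical_dose_Gy
  expect_lt(pracma::trapz(cfgA$depth_grid, dA),
            pracma::trapz(cfg0$depth_grid, d0))
})

test_that("SOBP weighting flattens the modulation or reports infeasibility", {
  m <- range_energy_model()
  cfg <- beam_config(depth_grid = seq(0, 150, by = 0.5))
  Rmax <- proton_range(m, cfg$entrance_energy)

  ## two identical peaks get equal weights (flatness check disabled: the
  ## single-peak shape is the best achievable here)
  p1 <- pristine_bragg(cfg, m)
  w2 <- sobp_weights(list(p1, p1), c(Rmax - 6, Rmax - 3), flat_tol = Inf)
  expect_equal(w2[1], w2[2], tolerance = 1e-3)

  ## a single peak over a degenerate region at its maximum: weight 1
  w1 <- sobp_weights(list(p1), rep(p1$depth_mm[which.max(p1$physical_dose_Gy)], 2))
  expect_equal(as.numeric(w1), 1)

  ## 9 peaks over 60 mm cannot reach the 2% target: structured error
  Rs <- seq(Rmax, Rmax - 60, length.out = 9)
  Es <- (Rs / (10 * m$bk_alpha))^(1 / m$bk_p)
  nine <- lapply(Es, function(E) pristine_bragg(cfg, m, E))
  err <- tryCatch(sobp_weights(nine, c(Rmax - 57, Rmax - 3)),
                  mkm_error_flatness_infeasible = function(e) e)
  expect_s3_class(err, "mkm_error_flatness_infeasible")
  expect_gt(err$achieved_dev, 0.02)
  expect_match(conditionMessage(err), "achieved")
})

test_that("synthetic spectra sit at the local stopping power and harden with depth", {
  m <- range_energy_model()
  ## near-degenerate width, no tail: y_D collapses onto the stopping power
  cfg <- beam_config(spectrum_width = 0.02, tail_fraction = 0,
                     depth_grid = seq(0, 150, by = 0.5))
  sp22 <- lineal_spectrum_at_depth(cfg, 22, m)
  s22 <- stopping_power(m, residual_energy(m, cfg$entrance_energy, 22))
  expect_equal(dose_mean_y(sp22), s22, tolerance = 0.01)

  ## spectral hardening at the depths scored along the pristine beam
  cfg2 <- beam_config(depth_grid = seq(0, 150, by = 0.5))
  yD <- sapply(c(22, 102, 132),
               function(z) dose_mean_y(lineal_spectrum_at_depth(cfg2, z, m)))
  expect_true(all(diff(yD) > 0))

  ## secondary tail carries its prescribed dose share
  cfg3 <- beam_config(tail_fraction = 0.1, depth_grid = seq(0, 150, by = 0.5))
  sp <- lineal_spectrum_at_depth(cfg3, 22, m)
  main_med <- stopping_power(m, residual_energy(m, cfg3$entrance_energy, 22))
  q999 <- main_med * exp(qnorm(0.999) * cfg3$spectrum_width) * 1.05
  above <- sum(diff(sp$y) * (head(sp$d, -1) + tail(sp$d, -1)) / 2 *
                 (head(sp$y, -1) >= q999))
  expect_equal(above, 0.1, tolerance = 0.01)

  expect_error(lineal_spectrum_at_depth(cfg2, 170, m),
               class = "mkm_error_depth_beyond_range")
})

test_that("generate_beam is deterministic and structurally sound", {
  cfg <- beam_config(depth_grid = seq(0, 150, by = 1))
  b1 <- generate_beam(cfg)
  b2 <- generate_beam(cfg)
  expect_identical(b1, b2)
  expect_equal(nrow(b1$components), 1)

  ## dose-mean lineal energy is monotone up to the pristine peak
  peak <- b1$profile$depth_mm[which.max(b1$profile$physical_dose_Gy)]
  idx <- which(b1$series$depths <= peak)
  yD <- vapply(b1$series$spectra[idx], dose_mean_y, numeric(1))
  expect_true(all(diff(yD) > 0))

  ## noise injection is seeded and reproducible, and changes the spectra
  cfgN <- beam_config(depth_grid = seq(0, 150, by = 1), noise_cv = 0.05,
                      rng_seed = 11L)
  n1 <- generate_beam(cfgN); n2 <- generate_beam(cfgN)
  expect_identical(n1, n2)
  expect_false(identical(n1$series$spectra[[1]]$d, b1$series$spectra[[1]]$d))
})

test_that("the default SOBP is flat within the design target", {
  sobp <- generate_beam(beam_config(modulation_width = 60,
                                    depth_grid = seq(0, 150, by = 0.5)))
  expect_lt(sobp$flatness_dev, 0.02)
  expect_gte(nrow(sobp$components), 9)
  ## flat region straddles the modulation interval
  m <- sobp$model
  Rmax <- proton_range(m, sobp$config$entrance_energy)
  sel <- sobp$profile$depth_mm >= Rmax - 57 & sobp$profile$depth_mm <= Rmax - 3
  dose <- sobp$profile$physical_dose_Gy[sel]
  expect_lt(max(abs(dose - mean(dose)) / mean(dose)), 0.02)
})
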