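test_that("constructor enforces the spectrum invariants", {
  expect_error(lineal_spectrum(c(1, 2), c(-0.1, 1)), class = "mkm_error_invalid_density")
  expect_error(lineal_spectrum(c(1, 2), c(0, 0)), class = "mkm_error_empty_spectrum")
  expect_error(lineal_spectrum(c(2, 1), c(1, 1)), class = "mkm_error_invalid_grid")
  expect_error(lineal_spectrum(c(0, 1), c(1, 1)), class = "mkm_error_invalid_grid")
  expect_error(lineal_spectrum(c(-1, 1), c(1, 1)), class = "mkm_error_invalid_grid")
  expect_error(lineal_spectrum(1, 1), class = "mkm_error_invalid_grid")
})

test_that("normalization fixes the integral and preserves shape", {
  y <- seq(1, 3, length.out = 301)
  ## triangular density, apex at 2: raw area = apex height
  tri <- pmax(1 - abs(y - 2), 0) * 4.2
  sp <- lineal_spectrum(y, tri, normalize = FALSE)
  nm <- normalize_spectrum(sp)
  expect_equal(pracma::trapz(nm$y, nm$d), 1, tolerance = 1e-12)

  ## already normalized -> identical; scaling by 7 -> same result
  expect_equal(normalize_spectrum(nm)$d, nm$d)
  sp7 <- lineal_spectrum(y, tri * 7, normalize = FALSE)
  expect_equal(normalize_spectrum(sp7)$d, nm$d, tolerance = 1e-13)
})

test_that("dose-mean and frequency-mean moments match analytic values", {
  u <- make_uniform_spec(1, 3)
  expect_equal(dose_mean_y(u), 2.0, tolerance = 1e-9)
  expect_equal(frequency_mean_y(u), 2 / log(3), tolerance = 1e-6)

  d10 <- make_delta_spec(10)
  expect_equal(dose_mean_y(d10), 10, tolerance = 1e-4)
  expect_equal(frequency_mean_y(d10), 10, tolerance = 1e-4)

  ## unnormalized input is normalized internally with a warning
  raw <- lineal_spectrum(u$y, u$d * 3, normalize = FALSE)
  expect_warning(v <- dose_mean_y(raw), "normalizing")
  expect_equal(v, 2.0, tolerance = 1e-9)
})

test_that("y_F <= y_D for arbitrary spectra (Cauchy-Schwarz)", {
  set.seed(42)
  for (i in 1:200) {
    sp <- random_spectrum()
    expect_lte(frequency_mean_y(sp), dose_mean_y(sp) * (1 + 1e-12))
  }
})

test_that("saturation correction matches the point-mass closed form", {
  ## point mass at a: y* = y0^2 (1 - exp(-a^2/y0^2)) / a
  y0 <- 150
  for (a in c(10, 93.4, 150, 400)) {
    sp <- make_delta_spec(a)
    expect_equal(y_star(sp, y0), y0^2 * (1 - exp(-a^2 / y0^2)) / a,
                 tolerance = 1e-5)
  }
  ## that closed form has an interior maximum in a (brute-force scan)
  a_grid <- seq(1, 2000, by = 0.5)
  g <- y0^2 * (1 - exp(-a_grid^2 / y0^2)) / a_grid
  k <- which.max(g)
  expect_gt(k, 1); expect_lt(k, length(a_grid))
})

test_that("y* obeys the saturation bounds and the small-y limit", {
  set.seed(7)
  for (i in 1:200) {
    sp <- random_spectrum()
    yd <- dose_mean_y(sp)
    ys <- y_star(sp, 150)
    expect_gt(ys, 0)
    expect_lte(ys, yd * (1 + 1e-12))
  }
  ## support below y0/20 -> y* within 0.5% of y_D
  sp <- make_uniform_spec(1, 3)         # support far below y0 = 150
  expect_lt(abs(y_star(sp, 150) - dose_mean_y(sp)) / dose_mean_y(sp), 0.005)
})

test_that("y* quadrature converges under grid refinement", {
  for (n in c(600, 1200)) {
    coarse <- make_lognormal_spec(20, 0.5, n)
    fine <- make_lognormal_spec(20, 0.5, 2 * n)
    expect_lt(abs(y_star(coarse, 93.4) - y_star(fine, 93.4)) /
                y_star(fine, 93.4), 1e-3)
  }
})

test_that("z*_1D applies the chord-length/mass conversion", {
  p <- mkm_preset("SET_B")
  sp <- make_delta_spec(150)
  ## independent arithmetic from the point-mass closed form
  expected <- 0.1602 * (150 * (1 - exp(-1))) / (pi * 0.42^2)
  expect_equal(z_star_1d(sp, p), expected, tolerance = 1e-4)

  ## doubling the domain radius quarters z* at fixed y*
  p2 <- mkm_params(p$alpha0, p$beta, 2 * p$rd, p$y0)
  expect_equal(z_star_1d(sp, p2), z_star_1d(sp, p) / 4, tolerance = 1e-12)
})

test_that("log rebinning conserves mass and reports clipping", {
  sp <- make_lognormal_spec(10, 0.4, 500)
  ## rebin onto an equivalent log grid: mass identical to machine precision
  rb <- rebin_log(sp, length(sp$y), min(sp$y), max(sp$y))
  expect_equal(pracma::trapz(rb$y, rb$d), pracma::trapz(sp$y, sp$d),
               tolerance = 1e-12)
  expect_equal(rb$metadata$clipped_fraction, 0, tolerance = 1e-12)

  ## coarsening a uniform density: y_D drifts < 0.5%
  u <- make_uniform_spec(1, 3, 100)
  ru <- rebin_log(u, 50, 1, 3)
  expect_lt(abs(dose_mean_y(ru) - dose_mean_y(u)) / dose_mean_y(u), 0.005)

  ## clipping to an inner window is reported in metadata
  cl <- rebin_log(sp, 200, 5, 20)
  outside <- 1 - (pracma::trapz(cl$y, cl$d) / pracma::trapz(sp$y, sp$d))
  expect_gt(cl$metadata$clipped_fraction, 0)
  expect_equal(cl$metadata$clipped_fraction, outside, tolerance = 1e-9)

  expect_error(rebin_log(sp, 50, -1, 10), class = "mkm_error_invalid_parameter")
})

test_that("dose/frequency density conversion is an involution", {
  sp <- make_bimodal_spec()
  back <- convert_density(convert_density(sp, "frequency"), "dose")
  expect_equal(back$d, normalize_spectrum(sp)$d, tolerance = 1e-10)
  ## frequency mean of d(y) equals dose mean computed through f(y):
  ## y_F = 1 / int d/y dy is the mean of f(y)
  f <- convert_density(sp, "frequency")
  expect_equal(pracma::trapz(f$y, f$y * f$d), frequency_mean_y(sp),
               tolerance = 1e-6)
})
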