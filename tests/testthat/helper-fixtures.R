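## In-code fixtures: analytic test spectra and Monte Carlo oracles.

make_uniform_spec <- function(a = 1, b = 3, n = 2001) {
  y <- seq(a, b, length.out = n)
  lineal_spectrum(y, rep(1 / (b - a), n))
}

## narrow Gaussian standing in for a point mass at y = at
make_delta_spec <- function(at, rel_width = 1e-3, n = 801) {
  s <- at * rel_width
  y <- seq(at - 6 * s, at + 6 * s, length.out = n)
  lineal_spectrum(y, dnorm(y, at, s))
}

make_lognormal_spec <- function(median = 5, sigma = 0.5, n = 1200) {
  y <- exp(seq(log(median) - 6 * sigma, log(median) + 6 * sigma,
               length.out = n))
  lineal_spectrum(y, dlnorm(y, log(median), sigma))
}

make_bimodal_spec <- function(n = 2000) {
  y <- exp(seq(log(0.3), log(400), length.out = n))
  d <- 0.6 * dlnorm(y, log(2), 0.3) + 0.4 * dlnorm(y, log(80), 0.4)
  lineal_spectrum(y, d)
}

## truncated power-law tail: heavy-tailed on [1, 2000]
make_heavy_tail_spec <- function(n = 3000) {
  y <- exp(seq(log(1), log(2000), length.out = n))
  lineal_spectrum(y, y^(-1.6))
}

## smooth random spectrum on a random log grid (for property loops)
random_spectrum <- function() {
  n <- sample(50:400, 1)
  lo <- runif(1, 0.1, 5); hi <- lo * runif(1, 5, 200)
  y <- exp(seq(log(lo), log(hi), length.out = n))
  med <- exp(runif(2, log(lo * 1.5), log(hi / 1.5)))
  sig <- runif(2, 0.15, 0.8)
  w <- runif(2)
  d <- w[1] * dlnorm(y, log(med[1]), sig[1]) +
       w[2] * dlnorm(y, log(med[2]), sig[2]) + 1e-6
  lineal_spectrum(y, d)
}

## inverse-CDF sampler from the piecewise-linear density (fine log grid),
## for Monte Carlo cross-checks of the quadrature moments
sample_from_spectrum <- function(spec, n, n_fine = 40001) {
  xf <- exp(seq(log(min(spec$y)), log(max(spec$y)), length.out = n_fine))
  df <- approx(spec$y, spec$d, xout = xf, rule = 2)$y
  w <- diff(xf) * (df[-1] + df[-n_fine]) / 2
  cell <- sample.int(n_fine - 1L, n, replace = TRUE, prob = w)
  xf[cell] + runif(n) * (xf[cell + 1L] - xf[cell])
}

mc_y_star <- function(spec, y0, n = 1e6) {
  ys <- sample_from_spectrum(normalize_spectrum(spec), n)
  mean(y0^2 * (1 - exp(-ys^2 / y0^2)) / ys)
}

## spectrum whose quadrature z*_1D equals `target` (root-found lognormal)
spec_with_zstar <- function(target, params, sigma = 0.2) {
  f <- function(m) z_star_1d(make_lognormal_spec(m, sigma), params) - target
  m <- uniroot(f, c(1e-3, 400), tol = 1e-13)$root
  make_lognormal_spec(m, sigma)
}

## small series of identical spectra at given depths
constant_series <- function(depths, spec, dose = NULL) {
  spectrum_series(depths, replicate(length(depths), spec, simplify = FALSE),
                  dose)
}
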