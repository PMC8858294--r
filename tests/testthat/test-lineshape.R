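test_that("no-exchange limit gives two Lorentzians with population areas", {
  pars <- exchange_params(0.3, -300, 300, 10, 12, 0)
  nu <- seq(-4000, 4000, length.out = 16384)
  sp <- simulate_two_site_spectrum(pars, nu)
  analytic <- 0.3 * 2 * 10 / (10^2 + (2 * pi * (nu + 300))^2) +
    0.7 * 2 * 12 / (12^2 + (2 * pi * (nu - 300))^2)
  expect_equal(sp$intensity, analytic, tolerance = 1e-12)
  # areas split by population (lines far apart so tail leakage is negligible)
  dnu <- diff(nu[1:2])
  area_cis <- sum(sp$intensity[nu < 0]) * dnu
  area_trans <- sum(sp$intensity[nu >= 0]) * dnu
  expect_equal(area_cis / (area_cis + area_trans), 0.3, tolerance = 5e-3)
})

test_that("single-state limit is one Lorentzian independent of k_ex", {
  nu <- seq(-100, 100, length.out = 2048)
  a <- simulate_two_site_spectrum(exchange_params(0, -10, 10, 8, 8, 0), nu)
  b <- simulate_two_site_spectrum(exchange_params(0, -10, 10, 8, 8, 500), nu)
  expect_equal(a$intensity, b$intensity, tolerance = 1e-12)
  analytic <- 2 * 8 / (8^2 + (2 * pi * (nu - 10))^2)
  expect_equal(a$intensity, analytic, tolerance = 1e-12)
})

test_that("simulated spectra match the matrix-inversion oracle", {
  nu <- seq(-150, 150, length.out = 512)
  cases <- list(
    exchange_params(0.3, -10, 10, 10, 10, 50),
    exchange_params(0.25, -35, 12, 6, 14, 5),
    exchange_params(0.7, -5, 45, 20, 3, 800)
  )
  for (pars in cases) {
    sp <- suppressWarnings(simulate_two_site_spectrum(pars, nu))
    oracle <- bm_matrix_oracle(pars, nu)
    expect_lt(max(abs(sp$intensity - oracle)) / max(abs(oracle)), 1e-8)
  }
})

test_that("spectral integral is independent of k_ex", {
  nu <- seq(-3000, 3000, length.out = 2^15)
  ints <- vapply(c(0, 5, 50, 500, 5000), function(k) {
    sp <- simulate_two_site_spectrum(exchange_params(0.3, -10, 10, 10, 10, k),
                                     nu)
    sum(sp$intensity) * diff(nu[1:2])
  }, numeric(1))
  expect_lt(max(abs(ints / ints[1] - 1)), 1e-3)
})

test_that("slow-exchange broadening of the cis line equals p_trans * k_ex", {
  pars <- exchange_params(0.3, -100, 100, 10, 10, 2)
  sp <- suppressWarnings(
    simulate_two_site_spectrum(pars, seq(-200, 0, length.out = 4096))
  )
  lw <- fit_intrinsic_linewidth(sp, c(-140, -60))
  expect_equal(lw$r2 - 10, 0.7 * 2, tolerance = 0.02)
})

test_that("fast exchange collapses to one line at the weighted mean", {
  pars <- exchange_params(0.3, -10, 10, 10, 10, 5e4)
  sp <- simulate_two_site_spectrum(pars, seq(-300, 300, length.out = 8192))
  lw <- fit_intrinsic_linewidth(sp, c(-300, 300))
  expect_equal(lw$nu0, 0.3 * -10 + 0.7 * 10, tolerance = 0.01)
  r_ex <- 0.3 * 0.7 * (2 * pi * 20)^2 / 5e4
  expect_equal(lw$r2 - 10, r_ex, tolerance = 0.05)
})

test_that("subtract_reference is pointwise with quadrature noise", {
  nu <- seq(-50, 50, length.out = 256)
  s <- new_spectrum(nu, stats::dnorm(nu, 0, 5), noise_sigma = 0.1)
  expect_equal(subtract_reference(s, s)$intensity, rep(0, length(nu)))
  zero <- new_spectrum(nu, rep(0, length(nu)), noise_sigma = 0.1)
  expect_equal(subtract_reference(s, zero)$intensity, s$intensity)
  expect_equal(noise_sigma(subtract_reference(s, s)), sqrt(0.02))
  other <- new_spectrum(nu + 1, s$intensity)
  expect_error(subtract_reference(s, other), "identical frequency axis")
})

test_that("enzyme-background bump subtraction recovers the clean doublet", {
  pars <- exchange_params(0.25, -10, 10, 8, 8, 20)
  nu <- seq(-100, 100, length.out = 2048)
  clean <- simulate_two_site_spectrum(pars, nu)
  bump <- 0.004 * exp(-(nu - 40)^2 / 200)
  with_bump <- new_spectrum(nu, clean$intensity + bump, noise_sigma = 1e-4)
  ref <- new_spectrum(nu, bump, noise_sigma = 1e-4)
  recovered <- subtract_reference(with_bump, ref)
  expect_equal(recovered$intensity, clean$intensity, tolerance = 1e-10)
})

test_that("intrinsic linewidth: closed form, noisy recovery, doublet error", {
  nu <- seq(-60, 60, length.out = 2048)
  # FWHM 4 Hz -> r2 = 4 * pi
  sp <- lorentzian_spectrum(nu, 3, 4 * pi, height = 1, base = 0.01)
  lw <- fit_intrinsic_linewidth(sp, c(-40, 40))
  expect_equal(lw$r2, 4 * pi, tolerance = 1e-3)
  expect_equal(lw$nu0, 3, tolerance = 1e-4)

  # SNR 100: true value within 3 SD of replicate fits
  set.seed(7)
  r2s <- replicate(20, {
    noisy <- new_spectrum(nu, sp$intensity + rnorm(length(nu), 0, 0.01))
    fit_intrinsic_linewidth(noisy, c(-40, 40))$r2
  })
  expect_lt(abs(mean(r2s) - 4 * pi), 3 * sd(r2s))

  doublet <- simulate_two_site_spectrum(
    exchange_params(0.5, -20, 20, 8, 8, 0), nu)
  expect_error(fit_intrinsic_linewidth(doublet, c(-60, 60)),
               "more than one resolved maximum")
})

test_that("reference doublet fit recovers populations and positions", {
  pars <- exchange_params(0.25, -10, 10, 8, 8, 0.05)
  nu <- seq(-100, 100, length.out = 2048)
  set.seed(3)
  clean <- simulate_two_site_spectrum(pars, nu)
  noisy <- new_spectrum(nu, clean$intensity + rnorm(2048, 0, max(clean$intensity) / 200))
  ref <- fit_reference_doublet(noisy)
  expect_equal(ref$p_cis, 0.25, tolerance = 0.05)
  expect_equal(ref$nu_cis, -10, tolerance = 0.2)
  expect_equal(ref$nu_trans, 10, tolerance = 0.2)
})

test_that("apparent exchange rate is recovered across the working range", {
  nu <- seq(-150, 150, length.out = 2048)
  # zero-exchange spectrum fits to (near) zero rate
  clean0 <- simulate_two_site_spectrum(exchange_params(0.25, -10, 10, 8, 8, 0),
                                       nu)
  set.seed(21)
  noisy0 <- new_spectrum(nu, clean0$intensity +
                           rnorm(2048, 0, max(clean0$intensity) / 500))
  f0 <- fit_apparent_exchange(noisy0, 0.25, -10, 10, 8, 8)
  expect_lt(f0$k_app, 0.5)

  # recovery within 10% at SNR 100 over the grid, broadening monotone
  ks <- c(5, 20, 30, 80)
  fitted <- vapply(ks, function(k) {
    p <- exchange_params(0.25, -10, 10, 8, 8, k)
    clean <- simulate_two_site_spectrum(p, nu)
    set.seed(100 + k)
    noisy <- new_spectrum(nu, clean$intensity +
                            rnorm(2048, 0, max(clean$intensity) / 100),
                          noise_sigma = max(clean$intensity) / 100)
    fit_apparent_exchange(noisy, 0.25, -10, 10, 8, 8)$k_app
  }, numeric(1))
  expect_true(all(abs(fitted / ks - 1) < 0.10))
  expect_true(all(diff(fitted) > 0))
})

test_that("Monte-Carlo uncertainties are seeded, vanish without noise and scale", {
  nu <- seq(-120, 120, length.out = 1024)
  pars <- exchange_params(0.25, -10, 10, 8, 8, 25)
  clean <- simulate_two_site_spectrum(pars, nu)
  f_clean <- fit_apparent_exchange(clean, 0.25, -10, 10, 8, 8)
  mc0 <- monte_carlo_uncertainty(f_clean, clean, n_replicates = 60, seed = 4)
  expect_lt(mc0$k_app_sd, 1e-6)

  sig <- max(clean$intensity) / 100
  noisy1 <- new_spectrum(nu, clean$intensity, noise_sigma = sig)
  noisy2 <- new_spectrum(nu, clean$intensity, noise_sigma = 2 * sig)
  f1 <- fit_apparent_exchange(noisy1, 0.25, -10, 10, 8, 8)
  a <- monte_carlo_uncertainty(f1, noisy1, n_replicates = 80, seed = 9)
  b <- monte_carlo_uncertainty(f1, noisy1, n_replicates = 80, seed = 9)
  expect_identical(a$k_app_sd, b$k_app_sd)  # same seed, bit-identical
  f2 <- fit_apparent_exchange(noisy2, 0.25, -10, 10, 8, 8)
  c2 <- monte_carlo_uncertainty(f2, noisy2, n_replicates = 80, seed = 9)
  expect_gt(c2$k_app_sd / a$k_app_sd, 1.5)
  expect_lt(c2$k_app_sd / a$k_app_sd, 2.5)

  expect_warning(monte_carlo_uncertainty(f1, noisy1, n_replicates = 10,
                                         seed = 1),
                 "n_replicates")
})

test_that("spectrum text files round-trip", {
  nu <- seq(-10, 10, length.out = 64)
  sp <- new_spectrum(nu, sin(nu), noise_sigma = 0.05)
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(back$frequency_hz, sp$frequency_hz)
  expect_equal(back$intensity, sp$intensity)
  expect_equal(noise_sigma(back), 0.05)
})

test_that("invalid exchange parameters are rejected", {
  expect_error(exchange_params(1.2, 0, 10, 8, 8, 0), "p_cis")
  expect_error(exchange_params(0.5, 0, 10, -1, 8, 0), ">= 0")
  expect_error(exchange_params(0.5, 0, 10, 8, 8, -5), ">= 0")
  expect_warning(
    simulate_two_site_spectrum(exchange_params(0.5, -50, 50, 8, 8, 0),
                               seq(-55, 55, length.out = 128)),
    "5 linewidths")
})
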