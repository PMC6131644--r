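test_that("buffered effective diffusion follows D/(1+G) with sane limits", {
  expect_identical(effective_diffusion(7e-10, buffer_model()), 7e-10)
  # G = 9 via c_B = 9 mM, k_on/k_off = 1e3 per M
  b9 <- buffer_model(c_B = 9, k_on = 1e8, k_off = 1e5)
  expect_equal(b9$G, 9)
  expect_equal(effective_diffusion(7e-10, b9), 7e-11)
  # hand-evaluated: 1 mM buffer, k_on 1e8 /(M s), k_off 1e5 /s -> G = 1
  expect_equal(effective_diffusion(2e-10, buffer_model(1, 1e8, 1e5)), 1e-10)
  expect_error(effective_diffusion(-1e-10, buffer_model()), "must be > 0")
  expect_error(buffer_model(c_B = 1, k_on = 1e8, k_off = 0), "k_off")
})

test_that("effective diffusion is monotone in the buffer parameters", {
  base <- effective_diffusion(2e-10, buffer_model(1, 1e8, 1e5))
  expect_lt(effective_diffusion(2e-10, buffer_model(2, 1e8, 1e5)), base)
  expect_lt(effective_diffusion(2e-10, buffer_model(1, 2e8, 1e5)), base)
  expect_gt(effective_diffusion(2e-10, buffer_model(1, 1e8, 2e5)), base)
})

test_that("stationary profile matches the closed form's structure", {
  geom <- synapse_geometry(R = 300e-9, S = 3e-6, h = 40e-9)
  tp <- transport_params(2e-10)
  src <- source_spec(5)
  prof <- stationary_profile(geom, src, tp, n_points = 1001)

  # clamped rim and zero-source degenerate case
  expect_equal(prof$c[length(prof$c)], 0)
  flat <- stationary_profile(geom, source_spec(0), tp)
  expect_true(all(flat$c == 0))

  # both branches agree in value and slope at r = R
  K <- src$k / tp$D_eff
  eps <- 1e-12
  c_in <- zincleft:::stationary_concentration(geom$R - eps, geom, src, tp)
  c_out <- zincleft:::stationary_concentration(geom$R + eps, geom, src, tp)
  # evaluating eps off the seam leaves an O(K R eps) truncation term
  expect_equal(c_in, c_out, tolerance = 1e-5)
  expect_equal(c_in, K * geom$R^2 / 2 * log(geom$S / geom$R), tolerance = 1e-5)
  h <- 1e-12
  d_in <- (zincleft:::stationary_concentration(geom$R, geom, src, tp) -
           zincleft:::stationary_concentration(geom$R - h, geom, src, tp)) / h
  d_out <- (zincleft:::stationary_concentration(geom$R + h, geom, src, tp) -
            zincleft:::stationary_concentration(geom$R, geom, src, tp)) / h
  expect_equal(d_in, -K * geom$R / 2, tolerance = 1e-3)
  expect_equal(d_out, -K * geom$R / 2, tolerance = 1e-3)

  # center-to-edge-of-zone ratio is 1 + 1/(2 ln(S/R)), independent of k
  for (k in c(0.1, 5, 200)) {
    s <- source_spec(k)
    ratio <- zincleft:::stationary_concentration(0, geom, s, tp) /
      zincleft:::stationary_concentration(geom$R, geom, s, tp)
    expect_equal(ratio, 1 + 1 / (2 * log(10)), tolerance = 1e-12)
  }
})

test_that("closed-form profile agrees with a direct sparse Poisson solve", {
  geom <- synapse_geometry(R = 300e-9, S = 3e-6, h = 40e-9)
  tp <- transport_params(2e-10)
  src <- source_spec(5)
  o <- oracle_poisson_radial(geom, k = src$k, D = tp$D_eff, n = 3000)
  a <- zincleft:::stationary_concentration(o$r, geom, src, tp)
  expect_lt(max(abs(o$c - a)) / max(a), 1e-5)
})

test_that("stationary profile is non-increasing and baseline is additive", {
  set.seed(11)
  for (i in 1:20) {
    R <- runif(1, 50e-9, 1e-6)
    S <- R * runif(1, 2, 20)
    geom <- synapse_geometry(R, S, 40e-9)
    tp <- transport_params(10^runif(1, -11, -9))
    src <- source_spec(10^runif(1, -2, 3))
    prof <- stationary_profile(geom, src, tp, n_points = 257)
    expect_true(all(diff(prof$c) <= 1e-12 * max(prof$c)))
    off <- stationary_profile(geom, src, tp, n_points = 257, baseline = 0.5)
    expect_equal(off$c, prof$c + 0.5)
    expect_true(all(off$c >= off$baseline - 1e-15))
  }
})

test_that("analytic profile satisfies global flux balance to round-off", {
  geom <- synapse_geometry(R = 500e-9, S = 3e-6, h = 40e-9)
  tp <- transport_params(7e-11)
  prof <- stationary_profile(geom, source_spec(42), tp)
  expect_lt(stationary_flux_balance(prof), 1e-10)
  zero <- stationary_profile(geom, source_spec(0), tp)
  expect_identical(stationary_flux_balance(zero), 0)
})

test_that("J0 zeros are found to high precision and in order", {
  r1 <- bessel_j0_root(1)
  expect_equal(round(r1, 4), 2.4048)
  roots <- bessel_j0_root(1:5)
  expect_true(all(diff(roots) > 0))
  expect_true(all(abs(oracle_j0(roots)) < 1e-10))
  expect_error(bessel_j0_root(0), "n must be")
})

test_that("slowest time constant follows D (rho1/S)^2 and its scalings", {
  geom <- synapse_geometry(R = 300e-9, S = 3e-6, h = 40e-9)
  tc <- slowest_time_constant(geom, 2e-10)
  expect_equal(tc$tau_max, (3e-6 / bessel_j0_root(1))^2 / 2e-10)
  expect_equal(tc$tau_max, 7.781e-3, tolerance = 1e-4)
  expect_equal(tc$tau_max * tc$lambda_min, 1)

  big <- slowest_time_constant(synapse_geometry(300e-9, 6e-6, 40e-9), 2e-10)
  expect_equal(big$tau_max / tc$tau_max, 4, tolerance = 1e-12)
  slow <- slowest_time_constant(geom, 2e-11)
  expect_equal(tc$tau_max / slow$tau_max, 1 / 10, tolerance = 1e-12)
})

test_that("closed-form eigenvalue matches the discrete operator's slowest mode", {
  geom <- synapse_geometry(R = 300e-9, S = 3e-6, h = 40e-9)
  rate <- oracle_slowest_rate(geom, 2e-10, n = 2000)
  tc <- slowest_time_constant(geom, 2e-10)
  expect_equal(rate, tc$lambda_min, tolerance = 0.01)
})

test_that("approximate time course is the profile scaled by an exponential", {
  geom <- synapse_geometry(R = 300e-9, S = 3e-6, h = 40e-9)
  tp <- transport_params(2e-10)
  prof <- stationary_profile(geom, source_spec(5), tp, n_points = 101)
  tc <- slowest_time_constant(geom, tp)
  tau <- tc$tau_max
  times <- c(0, tau / 2, tau, 5 * tau, 20 * tau)

  rise <- approx_time_course(prof, tc, times, "rise")
  decay <- approx_time_course(prof, tau, times, "decay")

  expect_true(all(rise$c_mol_per_m3[rise$t_s == 0] == 0))
  expect_equal(decay$c_mol_per_m3[decay$t_s == 0], prof$c)
  # complementarity: rise + decay = stationary at every (r, t)
  expect_equal(rise$c_mol_per_m3 + decay$c_mol_per_m3,
               rep(prof$c, times = length(times)))
  at_tau <- rise$c_mol_per_m3[rise$t_s == tau]
  expect_equal(at_tau, prof$c * (1 - exp(-1)), tolerance = 1e-12)
  late <- rise$c_mol_per_m3[rise$t_s == 20 * tau]
  expect_lt(max(abs(late - prof$c)) / max(prof$c), 1e-8)
  expect_error(approx_time_course(prof, tau, c(-1, 0)), "times")
})
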