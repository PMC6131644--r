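test_that("the grid tiles the disc exactly", {
  geom <- test_geom()
  g <- build_grid(geom, 300)
  expect_equal(sum(g$cell_volumes), pi * geom$S^2 * geom$h, tolerance = 1e-14)
  expect_equal(sum(g$membrane_area), 2 * pi * geom$S^2, tolerance = 1e-14)
  g8 <- build_grid(geom, 8)
  expect_length(g8$faces, 9)
  expect_length(g8$centers, 8)
  expect_error(build_grid(geom, 4), "n_cells")
})

test_that("pulsed source is on inside the zone during pulses, off otherwise", {
  geom <- test_geom()
  g <- build_grid(geom, 150)
  sch <- pulse_schedule(100, 5e-3, train_duration = 1)
  src <- source_spec(200)
  s_on <- source_vector(sch, src, g, t = 2e-3)       # inside first pulse
  expect_true(all(s_on[g$centers <= geom$R] > 0))
  expect_true(all(s_on[g$centers > geom$R] == 0))
  # in-pulse rate is boosted by the inverse duty cycle (period/pulse)
  expect_equal(max(s_on), 200 / (5e-3 * 100))
  s_off <- source_vector(sch, src, g, t = 7e-3)      # between pulses
  expect_true(all(s_off == 0))
  s_post <- source_vector(sch, src, g, t = 1.5)      # after the train
  expect_true(all(s_post == 0))
})

test_that("time-integrated release equals p * duration * mean rate * zone volume", {
  geom <- test_geom()
  tp <- test_transport()
  # 150 cells: dr = 20 nm, the 500 nm zone edge falls exactly on a face
  sch <- pulse_schedule(100, 5e-3, train_duration = 0.05, release_probability = 0.5)
  sim <- simulate_cleft(geom, tp, source_spec(200), sch, n_cells = 150,
                        t_end = 0.05, outer = "reflecting")
  expected <- 0.5 * 200 * pi * geom$R^2 * geom$h * 0.05
  expect_equal(sim$released_mol, expected, tolerance = 1e-3)
})

test_that("uptake sink is saturable with the configured areal flux scale", {
  geom <- test_geom()
  g <- build_grid(geom, 64)
  up <- uptake_model(J_max = 3e-6, K_m = 1)
  expect_true(all(uptake_rate(rep(0, 64), up, g) == 0))
  # deep saturation: areal flux -> J_max
  sink <- uptake_rate(rep(1e4, 64), up, g)
  areal <- sink * g$cell_volumes / g$membrane_area
  expect_equal(areal, rep(3e-6, 64), tolerance = 1e-3)
  # half-saturation at c = K_m
  sink_half <- uptake_rate(rep(1, 64), up, g)
  areal_half <- sink_half * g$cell_volumes / g$membrane_area
  expect_equal(areal_half, rep(1.5e-6, 64), tolerance = 1e-12)
  expect_true(all(uptake_rate(rep(1, 64), no_uptake(), g) == 0))
  expect_error(uptake_rate(rep(-1, 64), up, g), "non-negative")
})

test_that("zero source on an empty cleft stays identically zero", {
  sim <- simulate_cleft(test_geom(), test_transport(), source_spec(0),
                        n_cells = 64, t_end = 5e-3)
  expect_true(all(sim$fields == 0))
  expect_equal(sim$released_mol, 0)
})

test_that("FV steady state converges to the closed form under refinement", {
  geom <- test_geom()
  tp <- test_transport()
  src <- source_spec(200)
  tc <- slowest_time_constant(geom, tp)
  prof <- stationary_profile(geom, src, tp, n_points = 601)
  errs <- vapply(c(300, 600), function(n) {
    sim <- simulate_cleft(geom, tp, src, constant_release(), n_cells = n,
                          t_end = 5 * tc$tau_max, init = prof)
    compare_to_analytic(sim, prof)$linf_rel
  }, numeric(1))
  expect_lt(errs[2], 0.01)          # within 1% at 600 cells
  expect_lt(errs[2], errs[1])       # refinement reduces the error
  expect_gt(errs[1] / errs[2], 2)   # at least first-order convergence
})

test_that("free decay from steady state relaxes at the predicted time constant", {
  geom <- test_geom()
  tp <- test_transport()
  tc <- slowest_time_constant(geom, tp)
  prof <- stationary_profile(geom, source_spec(200), tp, n_points = 601)
  sim <- simulate_cleft(geom, tp, source_spec(0), constant_release(),
                        n_cells = 600, t_end = 3 * tc$tau_max, init = prof)
  pr <- probe(sim, 1e-6)
  tail_sel <- pr$t_s > tc$tau_max & pr$c_mol_per_m3 > 0
  fit <- lm(log(c_mol_per_m3) ~ t_s, data = pr[tail_sel, ])
  tau_fit <- -1 / coef(fit)[["t_s"]]
  expect_equal(tau_fit, tc$tau_max, tolerance = 0.05)
})

test_that("a closed cleft conserves mass to round-off", {
  geom <- test_geom()
  sch <- pulse_schedule(100, 5e-3, train_duration = 0.02,
                        release_probability = 0.7)
  sim <- simulate_cleft(geom, test_transport(), source_spec(200), sch,
                        n_cells = 128, t_end = 0.02, outer = "reflecting")
  total <- sum(sim$final * sim$grid$cell_volumes)
  expect_equal(total, sim$released_mol, tolerance = 1e-8)
  expect_lt(abs(total - sim$released_mol) / sim$released_mol, 1e-8)
})

test_that("with no source the field obeys a discrete maximum principle", {
  geom <- test_geom()
  tp <- test_transport()
  prof <- stationary_profile(geom, source_spec(200), tp, n_points = 301)
  sim <- simulate_cleft(geom, tp, source_spec(0), constant_release(),
                        n_cells = 300, t_end = 0.01, init = prof,
                        save_every = 500)
  maxima <- apply(sim$fields, 1, max)
  expect_true(all(diff(maxima) <= 1e-15))
  expect_true(all(sim$fields >= 0))
})

test_that("pulsed release time-averages to the constant-release steady state", {
  geom <- test_geom()
  tp <- test_transport()
  src <- source_spec(200)
  sim <- simulate_cleft(geom, tp, src,
                        pulse_schedule(100, 5e-3, train_duration = 0.35),
                        n_cells = 150, t_end = 0.35, save_every = 100)
  for (r in c(100e-9, 1e-6)) {
    pr <- probe(sim, r)
    sel <- pr$t_s >= 0.34 & pr$t_s < 0.35   # one late full period
    avg <- mean(pr$c_mol_per_m3[sel])
    cs <- zincleft:::stationary_concentration(r, geom, src, tp)
    expect_equal(avg, cs, tolerance = 0.05)
  }
})

test_that("stochastic release with p = 1 reproduces expected-value mode", {
  geom <- test_geom()
  tp <- test_transport()
  src <- source_spec(200)
  s1 <- simulate_cleft(geom, tp, src,
                       pulse_schedule(100, 5e-3, 0.05, 1, "stochastic", seed = 7),
                       n_cells = 64, t_end = 0.05)
  s2 <- simulate_cleft(geom, tp, src,
                       pulse_schedule(100, 5e-3, 0.05, 1, "expected"),
                       n_cells = 64, t_end = 0.05)
  expect_identical(s1$final, s2$final)
})

test_that("stochastic schedules are reproducible and respond to p", {
  geom <- test_geom()
  tp <- test_transport()
  src <- source_spec(200)
  sch <- function(seed) pulse_schedule(100, 5e-3, 0.1, 0.5, "stochastic", seed)
  a <- simulate_cleft(geom, tp, src, sch(3), n_cells = 64, t_end = 0.1)
  b <- simulate_cleft(geom, tp, src, sch(3), n_cells = 64, t_end = 0.1)
  expect_identical(a$final, b$final)
  expect_identical(a$fire, b$fire)
  expect_true(all(a$fire %in% c(0, 1)))
})

test_that("membrane uptake lowers, but does not collapse, the steady field", {
  geom <- test_geom()
  tp <- test_transport()
  src <- source_spec(200)
  tc <- slowest_time_constant(geom, tp)
  prof <- stationary_profile(geom, src, tp)
  on <- simulate_cleft(geom, tp, src, constant_release(),
                       uptake = uptake_model(3e-6, 1), n_cells = 300,
                       t_end = 8 * tc$tau_max)
  off <- simulate_cleft(geom, tp, src, constant_release(), n_cells = 300,
                        t_end = 8 * tc$tau_max)
  for (r in c(100e-9, 1e-6)) {
    a <- tail(probe(on, r)$c_mol_per_m3, 1)
    b <- tail(probe(off, r)$c_mol_per_m3, 1)
    expect_lt(a, b)             # strictly lower with uptake
    expect_gt(a, b / 10)        # but the same order of magnitude
  }
  expect_gt(on$uptaken_mol, 0)
})

test_that("probes interpolate linearly between cell centers", {
  geom <- test_geom()
  sim <- simulate_cleft(geom, test_transport(), source_spec(200),
                        constant_release(), n_cells = 150, t_end = 5e-3,
                        save_every = 1000)
  centers <- sim$grid$centers
  at_center <- probe(sim, centers[40])
  expect_equal(at_center$c_mol_per_m3, sim$fields[, 40])
  mid <- (centers[40] + centers[41]) / 2
  expect_equal(probe(sim, mid)$c_mol_per_m3,
               (sim$fields[, 40] + sim$fields[, 41]) / 2)
  expect_true(all(probe(sim, geom$S)$c_mol_per_m3 == 0))
  expect_error(probe(sim, 2 * geom$S), "must lie in")
})

test_that("simulation-vs-analytic metrics are deterministic and guarded", {
  geom <- test_geom()
  tp <- test_transport()
  src <- source_spec(200)
  prof <- stationary_profile(geom, src, tp)
  run <- function() {
    sim <- simulate_cleft(geom, tp, src,
                          pulse_schedule(100, 5e-3, 0.02, 0.5, "stochastic", seed = 5),
                          n_cells = 64, t_end = 0.02)
    compare_to_analytic(sim, prof, slowest_time_constant(geom, tp))
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1, m2)
  expect_true(all(is.finite(m1$probe_dev$max_rel_dev)))

  other <- stationary_profile(synapse_geometry(300e-9, 2e-6, 40e-9), src, tp)
  sim <- simulate_cleft(geom, tp, src, constant_release(), n_cells = 64,
                        t_end = 1e-3)
  expect_error(compare_to_analytic(sim, other), "different geometries")
})

test_that("the FV steady state honours the global flux balance", {
  geom <- test_geom()
  tp <- test_transport()
  src <- source_spec(200)
  tc <- slowest_time_constant(geom, tp)
  prof <- stationary_profile(geom, src, tp, n_points = 301)
  sim <- simulate_cleft(geom, tp, src, constant_release(), n_cells = 300,
                        t_end = 5 * tc$tau_max, init = prof)
  expect_lt(stationary_flux_balance(final_field(sim)), 1e-2)
})
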