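test_that("Stokes-Einstein diffusivities match the reported study values", {
  # printed to 4 significant digits in the study
  expect_equal(diffusion_coefficient(nanoAg, water20), 2.387e-11,
               tolerance = 1e-3)
  expect_equal(diffusion_coefficient(nanoCu, water20), 1.79e-11,
               tolerance = 1e-3)
  # D is inversely proportional to diameter
  big <- particle_spec("2x", d = 18e-9, rho_s = 7874)
  expect_equal(diffusion_coefficient(big, water20),
               diffusion_coefficient(nanoAg, water20) / 2)
})

test_that("sedimentation velocity and distance reproduce the Stokes screen", {
  u_ag <- sedimentation_velocity(nanoAg, water20)
  u_cu <- sedimentation_velocity(nanoCu, water20)
  expect_equal(u_ag, 3.034e-10, tolerance = 1e-3)
  expect_equal(u_cu, 6.239e-10, tolerance = 1e-3)
  expect_equal(sedimentation_distance(u_ag, 43200), 13.1e-6, tolerance = 1e-3)
  # formula value for nanoCu (the study prints 26.6 um, ~1% off its own u0)
  expect_equal(sedimentation_distance(u_cu, 43200), 2.695e-5, tolerance = 1e-3)
  # neutral buoyancy
  neutral <- particle_spec("n", 9e-9, rho_s = 1000)
  expect_equal(sedimentation_velocity(neutral, water20), 0)
  expect_equal(sedimentation_distance(u_ag, 0), 0)
  # 12-h sedimentation cannot cross even the thinnest single filter
  thicknesses <- filter_library()$thickness_um * 1e-6
  for (u in c(u_ag, u_cu)) {
    expect_true(all(sedimentation_distance(u, 43200) < thicknesses))
  }
})

test_that("mass flux bookkeeping follows J = m_p/(A t)", {
  expect_equal(mass_flux(0, 3.14e-4, 43200), 0)
  expect_equal(mass_flux(1e-3, 3.14e-4, 43200), 7.37e-5, tolerance = 1e-3)
  expect_equal(mass_flux(1e-3, 3.14e-4, 2 * 43200),
               mass_flux(1e-3, 3.14e-4, 43200) / 2)
  expect_error(mass_flux(1e-3, 0, 43200), "positive")
})

test_that("Franz-cell inversion and forward prediction are algebraic inverses", {
  expect_equal(effective_diffusivity(0, franz_cond, 1e-4), 0)
  expect_equal(acceptor_concentration(0, franz_cond, 1e-4), 0)
  grid <- expand.grid(D_ef = 10^seq(-14, -10, by = 0.5),
                      L = 10^seq(-5, -3, by = 0.5))
  c_p <- acceptor_concentration(grid$D_ef, franz_cond, grid$L)
  expect_true(all(c_p >= 0 & c_p < franz_cond$c0))
  back <- effective_diffusivity(c_p, franz_cond, grid$L)
  expect_equal(back, grid$D_ef, tolerance = 1e-12)
  # very fast barrier: c_p approaches but never reaches c0
  expect_lt(acceptor_concentration(1, franz_cond, 1e-6), franz_cond$c0)
})

test_that("inversion reproduces the reported acceptor concentrations", {
  # F118+F63 stack: measured ~30 mg/L, ~7% of the 400 mg/L donor
  c_p <- acceptor_concentration(0.6433e-11, franz_cond, 11.30e-5)
  expect_equal(c_p / franz_cond$c0, 0.07, tolerance = 0.05)
  # adding F1: ~4%
  c_p3 <- acceptor_concentration(0.4732e-11, franz_cond, 16.23e-5)
  expect_equal(c_p3 / franz_cond$c0, 0.04, tolerance = 0.1)
})

test_that("inversion rejects non-physical concentrations", {
  expect_error(effective_diffusivity(400, franz_cond, 1e-4), "steady-state")
  expect_error(effective_diffusivity(500, franz_cond, 1e-4), "steady-state")
  expect_error(effective_diffusivity(-1, franz_cond, 1e-4), "non-negative")
})

test_that("retardation coefficient reproduces every Table-style a entry", {
  obs <- retention_observations()
  D <- ifelse(obs$particle == "nanoAg",
              diffusion_coefficient(nanoAg, water20),
              diffusion_coefficient(nanoCu, water20))
  a <- retardation_coefficient(obs$D_ef_m2_s, D)
  # within 0.5% relative for all 24 entries (printed D is rounded)
  expect_equal(a, obs$a, tolerance = 5e-3)
  # spot values
  expect_equal(retardation_coefficient(1.1982e-11, 2.387e-11), 0.5020,
               tolerance = 5e-4)
  expect_equal(retardation_coefficient(0.4924e-11, 2.387e-11), 0.2063,
               tolerance = 5e-4)
  expect_equal(retardation_coefficient(2.387e-11, 2.387e-11), 1)
  expect_warning(retardation_coefficient(2e-11, 1e-11), "exceeds 1")
  expect_error(retardation_coefficient(1e-11, 0), "positive")
})

test_that("permeated mass respects conservation, limits and monotonicity", {
  expect_equal(permeated_mass(0, skin_cond, 1e-4), 0)
  m0 <- skin_cond$c0 * skin_cond$V
  # L -> 0 limit recovers the initial mass
  expect_equal(permeated_mass(1e-11, skin_cond, 1e-12) / m0, 1,
               tolerance = 1e-3)
  # N = 344-layer scenario lands at the 0.005 threshold
  expect_equal(permeated_mass(8.441e-14, skin_cond, 3.612e-4) / m0, 5.0e-3,
               tolerance = 1e-2)
  # mass conservation + monotonicity over a wide grid
  D_ef <- 10^seq(-15, -9, by = 0.25)
  for (L in c(1e-6, 1e-5, 1e-3)) {
    m <- permeated_mass(D_ef, skin_cond, L)
    expect_true(all(m >= 0 & m < m0))
    expect_true(all(diff(m) > 0)) # increasing in D_ef
  }
  Ls <- 10^seq(-6, -3, by = 0.1)
  m_L <- permeated_mass(1e-12, skin_cond, Ls)
  expect_true(all(diff(m_L) < 0)) # decreasing in L
  # decreasing in viscosity and diameter through D
  mus <- c(0.001, 0.005, 0.05)
  m_mu <- vapply(mus, function(mu) {
    D <- diffusion_coefficient(nanoAg, medium_spec(mu = mu))
    permeated_mass(D, skin_cond, 1e-5)
  }, numeric(1))
  expect_true(all(diff(m_mu) < 0))
})
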