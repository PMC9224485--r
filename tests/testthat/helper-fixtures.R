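# Shared study objects and independent oracles used across the suite.

nanoAg <- particle_spec("nanoAg", d = 9e-9, rho_s = 7874)
nanoCu <- particle_spec("nanoCu", d = 12e-9, rho_s = 8950)
water20 <- medium_spec(T = 293.15, mu = 0.001, rho_c = 1000)

# membrane study conditions: 2 cm window, 10 mL chambers, 12 h, 400 mg/L
franz_cond <- cell_conditions(A = 3.14e-4, V = 1e-5, t = 43200, c0 = 400)

# skin defaults: 1 cm^2, 0.2 cm^3, 12 h, 10 g/L
skin_cond <- cell_conditions(A = 1e-4, V = 0.2e-6, t = 43200, c0 = 1e4)

# brute-force 1-D grid-search oracle for the adsorption constant,
# independent of the Gauss-Newton fitter
grid_search_k <- function(Y, a, k_max = 5, step = 1e-5) {
  ks <- seq(0, k_max, by = step)
  rss <- vapply(ks, function(k) sum((a - 1 / (1 + k * Y))^2), numeric(1))
  ks[which.min(rss)]
}

# naive penetration-limit oracle: full scan with the mass closed form
# written out directly, independent of permeated_mass()
naive_penetration_limit <- function(scenario, N_max = 1e5) {
  g <- scenario$geometry
  Y1 <- bricks_per_layer(g) * brick_total_area(g) / 1e-4
  cond <- scenario$conditions
  D <- BOLTZMANN_oracle * scenario$medium$T /
    (6 * pi * scenario$medium$mu * scenario$particle$d)
  N <- seq_len(N_max)
  a <- 1 / (1 + scenario$k * N * Y1)
  L <- N * (g$x_k + g$x_c)
  mp <- (a * D) * cond$c0 / (L / (cond$A * cond$t) + (a * D) / cond$V)
  keep <- N[mp / (cond$c0 * cond$V) >= scenario$threshold]
  if (length(keep) == 0) 0L else max(keep)
}
BOLTZMANN_oracle <- 1.380649e-23
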