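test_that("Freundlich isotherm anchors", {
  expect_equal(freundlich_sorbed(0), 0)
  expect_equal(freundlich_sorbed(c(10, 100), K_F = 2e-3, n_F = 1),
               2e-3 * c(10, 100))  # linear isotherm
  expect_equal(freundlich_sorbed(1e6, 1.79e-3, 0.86), 258.73, tolerance = 1e-4)
})

test_that("Millington-Quirk diffusivity limits and the saturation ratio", {
  expect_equal(millington_quirk_Ds(0.49, 0.49, 6.33e-10),
               6.33e-10 * 0.49^(4 / 3))
  expect_equal(millington_quirk_Ds(0, 0.49), 0)
  ratio <- millington_quirk_Ds(0.98 * 0.49, 0.49) /
    millington_quirk_Ds(0.83 * 0.49, 0.49)
  expect_equal(ratio, (0.98 / 0.83)^(10 / 3))
  expect_gt(ratio, 1.70)  # a rise from 83% to 98% saturation gains > 70%
})

test_that("dispersion tensor has Bear structure and spectrum", {
  D0 <- dispersion_tensor(c(0, 0), 0.4, D_s = 2e-10)
  expect_equal(D0, diag(2) * 2e-10)
  # vertical flow: D_yy longitudinal, D_xx transversal
  Dv <- dispersion_tensor(c(0, 4e-8), 0.4, 0.03, 0.01, 1e-10)
  v <- 4e-8 / 0.4
  expect_equal(Dv[2, 2], 0.03 * v + 1e-10)
  expect_equal(Dv[1, 1], 0.01 * v + 1e-10)
  # eigenvalues are direction-independent
  for (ang in c(0.3, 1.2, 2.5)) {
    q <- 5e-8 * c(cos(ang), sin(ang))
    ev <- sort(eigen(dispersion_tensor(q, 0.4, 0.03, 0.01, 1e-10))$values)
    s <- sqrt(sum((q / 0.4)^2))
    expect_equal(ev, sort(c(0.01 * s + 1e-10, 0.03 * s + 1e-10)),
                 tolerance = 1e-10)
  }
})

test_that("Monod rate: half-saturation, zero biomass, first-order limit", {
  expect_equal(monod_rate(1.93e6, 12.21), 0.5 * 2.94e-4 * 1.24e3 * 12.21)
  expect_equal(monod_rate(1e5, 0), 0)
  C <- 0.01 * 1.93e6
  lin <- 2.94e-4 * 1.24e3 * 12.21 / 1.93e6 * C
  expect_lt(abs(monod_rate(C, 12.21) - lin) / lin, 0.01)
})

test_that("initial application carries the right mass and confinement", {
  mesh <- column_mesh()
  theta <- spun_column()$theta
  st <- apply_initial_mcpa(mesh, theta, rate_kg_ha = 2)
  cellvol <- mesh$dy * mesh$dx[1] * mesh$d_z
  total <- sum((theta * st$C_L[, 1] + mesh$rho_b * st$C_S[, 1]) * cellvol)
  # 2 kg/ha on a 0.3 m x 0.1 m surface = 6 mg = 269.2 umol C
  expect_equal(umolC_to_mg_mcpa(total), 6, tolerance = 1e-6)
  expect_true(all(st$C_L[mesh$y > 0.015, ] == 0))
  # the load profile (total concentration) is monotone downward
  tot <- theta * st$C_L[, 1] + mesh$rho_b * st$C_S[, 1]
  expect_true(all(diff(tot) <= 1e-9 * max(tot)))
  # equivalent carbon concentration over the top 5 cm is about 1.7 mg C/kg
  sel <- mesh$y <= 0.05
  soil_kg <- sum(mesh$dy[sel] * mesh$rho_b[sel]) * mesh$dx[1] * mesh$d_z
  mgC_kg <- total * 12.011e-3 / soil_kg
  expect_equal(mgC_kg, 1.7, tolerance = 0.05)
  # sorption equilibrium holds cell by cell
  expect_equal(st$C_S, freundlich_sorbed(st$C_L), tolerance = 1e-12)
})

test_that("a uniform state without flow or reaction is stationary", {
  mesh <- uniform_mesh(depth = 0.3, dy = 0.02)
  theta <- rep(0.3, mesh$ny)
  C <- matrix(5e4, mesh$ny, 1)
  pars <- list(D_m = 6.33e-10, K_F = 1.79e-3, n_F = 0.86,
               lambda_L = 0.03, lambda_T = 0.01,
               mu_max = 2.94e-4, K_M = 1.93e6, eps_capacity = 1e-9)
  res <- mcpafate:::.transport_step(C, theta, theta,
                                    rep(0, mesh$ny + 1), mesh,
                                    matrix(0, mesh$ny, 1), pars, 3600)
  expect_equal(res$C, C, tolerance = 1e-10)
  expect_equal(res$deg, 0)
})

test_that("without reaction, mass change equals boundary export", {
  mesh <- column_mesh()
  reg <- reg_with(B_TS = 0)
  fld <- hom_field(mesh$width, 0.9, registry = reg)
  run <- simulate_scenario(mesh, fld, build_precip("HRE"), t_end = 10,
                           registry = reg, initial = spun_column())
  expect_equal(run$cum_deg[length(run$times)], 0)
  m_end <- snapshot_mass(run, length(run$times))
  expect_equal(m_end + run$cum_export[length(run$times)],
               run$initial_mass, tolerance = 1e-6)
})

test_that("center of mass moves at the retarded pore velocity", {
  # uniform sandy column, linear sorption, no degradation
  mesh <- uniform_mesh(depth = 1.5, dy = 0.01)
  K_F <- 1e-4; rate <- 5  # mm/d
  # near-zero dispersion so the center of mass is a clean advection oracle
  reg <- reg_with(B_TS = 0, K_F = K_F, n_F = 1,
                  lambda_L = 2e-4, lambda_T = 1e-4, D_m = 1e-12)
  fld <- hom_field(mesh$width, 1.0, registry = reg)
  ws <- spin_up(mesh, rate)
  run <- simulate_scenario(mesh, fld, constant_schedule(rate), t_end = 25,
                           registry = reg, initial = ws,
                           out_times = c(0, 25))
  com <- function(k) {
    C <- run$C_L[[k]][, 1]
    CS <- K_F * C
    tot <- run$theta[[k]] * C + mesh$rho_b * CS
    sum(mesh$y * tot * mesh$dy) / sum(tot * mesh$dy)
  }
  theta_bar <- mean(run$theta[[2]])
  R_f <- 1 + mesh$rho_b[1] * K_F / theta_bar
  v_eff <- (rate * 1e-3) / theta_bar / R_f     # m/d
  expect_equal(com(2) - com(1), v_eff * 25, tolerance = 0.08)
})

test_that("degradation is monotone in the rate coefficient", {
  mesh <- column_mesh()
  masses <- lapply(c(2.94e-4, 5.88e-4), function(mu) {
    reg <- reg_with(mu_max = mu)
    run <- simulate_scenario(mesh, hom_field(mesh$width, 0.9, registry = reg),
                             build_precip("CLR"), t_end = 8, registry = reg,
                             initial = spun_column())
    vapply(seq_along(run$times), function(k) snapshot_mass(run, k), 0)
  })
  expect_true(all(masses[[2]] <= masses[[1]] + 1e-9))
})

test_that("Freundlich partitioning shifts toward sorbed at low totals", {
  # dissolved fraction of the equilibrium partition decreases as the
  # total concentration decreases when n_F < 1
  theta <- 0.4; rho_b <- 1.24e3
  frac <- vapply(c(1e6, 1e5, 1e4, 1e3), function(Tb) {
    cl <- uniroot(function(cl) theta * cl +
                    rho_b * freundlich_sorbed(cl) - Tb, c(0, Tb / theta))$root
    theta * cl / Tb
  }, 0)
  expect_true(all(diff(frac) < 0))
})

test_that("MCPA mass balance closes through events and degradation", {
  run <- hom_hre_run()
  for (k in c(5, 20, length(run$times)))
    expect_lt(mass_balance_error(run, k), 1e-3)
})
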