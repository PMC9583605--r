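topsoil <- function() soil_layers()[[1]]

test_that("van Genuchten retention matches closed-form anchors and limits", {
  lay <- topsoil()
  expect_equal(retention_theta(0, lay), 0.49)
  expect_equal(retention_theta(5, lay), 0.49)
  # with n = 1.10 the dry limit is approached only logarithmically; check
  # the monotone approach here and the limit itself on a sharper curve
  expect_lt(retention_theta(-1e9, lay), retention_theta(-1e3, lay))
  sharp <- vg_layer(0.43, 0.02, 3.63, 1.4, K_s = 2.31e-5, rho_b = 1.4e3)
  expect_lt(abs(retention_theta(-1e5, sharp) - sharp$theta_r), 5e-3)
  # -0.005 MPa of matric potential is about 82% topsoil saturation
  h <- -5000 / (1000 * 9.81)
  expect_equal(retention_theta(h, lay) / lay$theta_s, 0.8229, tolerance = 1e-3)
})

test_that("Mualem conductivity has the right limits and a frozen anchor", {
  lay <- topsoil()
  expect_equal(conductivity_K(0, lay), lay$K_s)
  expect_equal(conductivity_K(1, lay), lay$K_s)
  expect_lt(conductivity_K(-50, lay) / lay$K_s, 1e-6)
  # Se = 0.8 regression anchor, hand evaluation of the closed form
  m <- 1 - 1 / lay$n_vg
  h08 <- -((0.8^(-1 / m) - 1)^(1 / lay$n_vg)) / lay$alpha_vg
  expect_equal(conductivity_K(h08, lay), 1.0942e-9, tolerance = 1e-3)
})

test_that("retention and conductivity are monotone", {
  hs <- -10^seq(2, -3, length.out = 60)
  for (lay in soil_layers()[1:3]) {
    th <- retention_theta(hs, lay)
    expect_true(all(diff(th) >= -1e-14))
    K <- conductivity_K(hs, lay)
    expect_true(all(diff(K) >= -1e-20))
  }
})

test_that("capacity is the derivative of retention", {
  lay <- topsoil()
  hs <- c(-3, -1, -0.4, -0.05)
  num <- (retention_theta(hs + 1e-6, lay) - retention_theta(hs - 1e-6, lay)) / 2e-6
  expect_equal(vg_capacity(hs, lay), num, tolerance = 1e-5)
})

test_that("layer construction enforces invariants", {
  expect_error(vg_layer(0.4, 0.5, 1, 1.2, K_s = 1e-5, rho_b = 1e3))
  expect_error(vg_layer(0.4, 0.1, 1, 0.9, K_s = 1e-5, rho_b = 1e3))
  lays <- soil_layers()
  tops <- vapply(lays, `[[`, 0, "depth_top")
  bots <- vapply(lays, `[[`, 0, "depth_bottom")
  expect_equal(tops[-1], bots[-length(bots)])  # tiles without gaps
})

test_that("precipitation schedules have the documented structure", {
  clr <- build_precip("CLR")
  expect_equal(sum((clr$end - clr$start) * clr$rate), 204.4)
  hre <- build_precip("HRE")
  events <- hre[hre$rate == 40, ]
  expect_equal(sum((events$end - events$start) * events$rate), 80)
  for (s in list(clr, hre)) {
    expect_true(all(s$rate >= 0))
    expect_equal(s$start[-1], s$end[-nrow(s)])
  }
  expect_equal(schedule_rate(hre, 2.5), 40)
  expect_equal(schedule_rate(hre, 6.5), 0)
  expect_equal(schedule_rate(hre, 100), 0.35)
  expect_error(build_precip("XYZ"))
})

test_that("spin-up reaches the reported topsoil moisture state", {
  mesh <- column_mesh()
  ws <- spun_column()
  sat <- topsoil_saturation(ws, mesh)
  expect_gt(sat, 75); expect_lt(sat, 88)
  # steady state: top and bottom fluxes both equal the infiltration rate
  q_mm <- ws$q_faces[c(1, mesh$ny + 1)] * 86400 * 1e3
  expect_equal(q_mm, c(0.56, 0.56), tolerance = 1e-3)
})

test_that("spin-up state is a fixed point of the transient solver", {
  mesh <- column_mesh()
  ws <- spun_column()
  fs <- solve_flow(mesh, constant_schedule(0.56), ws, t_end = 5,
                   out_times = c(0, 5))
  expect_lt(max(abs(fs$states[[2]]$theta - ws$theta)), 1e-4)
})

test_that("transient flow closes the water balance under events", {
  mesh <- column_mesh()
  fs <- solve_flow(mesh, build_precip("HRE", t_end = 10), spun_column(),
                   t_end = 10)
  bal <- fs$balance
  err <- abs(bal$storage_change - (bal$inflow - bal$outflow)) / bal$inflow
  expect_lt(err, 1e-3)
  # saturation peaks near full saturation during events
  sats <- vapply(fs$states, topsoil_saturation, 0, mesh = mesh)
  expect_gt(max(sats), 95)
  expect_lt(min(sats), 85)
})

test_that("halving the grid changes the steady pressure profile by < 1%", {
  mesh1 <- column_mesh()
  mesh2 <- build_mesh(width = 0.3, dx = 0.3, dy = 2.5e-3)
  h1 <- spun_column()$h
  h2 <- spin_up(mesh2, 0.56)$h
  h2i <- approx(mesh2$y, h2, xout = mesh1$y, rule = 2)$y
  rel <- sqrt(sum((h1 - h2i)^2)) / sqrt(sum(h1^2))
  expect_lt(rel, 0.01)
})

test_that("under zero rain the free-draining column monotonically dries", {
  mesh <- column_mesh()
  ws <- spun_column()
  fs <- solve_flow(mesh, constant_schedule(0), ws, t_end = 5,
                   out_times = c(0, 2, 5))
  expect_true(all(fs$states[[2]]$theta <= ws$theta + 1e-12))
  expect_true(all(fs$states[[3]]$theta <= fs$states[[2]]$theta + 1e-12))
  bal <- fs$balance
  expect_equal(bal$inflow, 0)
  expect_equal(bal$storage_change, -bal$outflow, tolerance = 1e-6)
})

test_that("flow solver rejects schedules with gaps", {
  mesh <- column_mesh()
  sched <- constant_schedule(0.56, t_end = 5)
  expect_error(solve_flow(mesh, sched, spun_column(), t_end = 10),
               "schedule")
})
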