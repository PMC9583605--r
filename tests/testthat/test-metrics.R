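# minimal synthetic scenario_run for metric checks: 1D, two depth rows,
# no sorption (K_F = 0), unit theta weights
synthetic_run <- function(times, C_rows) {
  lay <- vg_layer(0.5, 0, 10, 1.2, K_s = 1e-5, rho_b = 1e3,
                  depth_top = 0, depth_bottom = Inf)
  mesh <- build_mesh(width = 0.1, depth = 0.2, dy = 0.1, dx = 0.1,
                     refine_top = FALSE, coarse_below = 1,
                     layers = list(lay))
  reg <- param_registry()
  reg$K_F$value <- 1e-30   # effectively no sorption
  theta <- rep(0.4, mesh$ny)
  C_L <- lapply(seq_along(times), function(k) matrix(C_rows[[k]], mesh$ny, 1))
  cellvol <- mesh$dy * mesh$dx[1] * mesh$d_z
  m0 <- sum(theta * C_rows[[1]] * cellvol)
  structure(list(times = times, C_L = C_L,
                 theta = rep(list(theta), length(times)),
                 B = matrix(0, mesh$ny, 1),
                 cum_deg = rep(0, length(times)),
                 cum_export = rep(0, length(times)),
                 cum_leach30 = rep(0, length(times)),
                 C30 = rep(0, length(times)), q30 = rep(0, length(times)),
                 initial_mass = m0, mesh = mesh, registry = reg,
                 scenario = "HOM", precip = "CLR"),
            class = "scenario_run")
}

test_that("depth-interval means are soil-mass weighted and conservative", {
  run <- synthetic_run(0:1, list(c(8e5, 0), c(5e5, 1e5)))
  dis <- depth_interval_series(run, interval = 0.1)
  expect_equal(ncol(dis$C_T), 2)
  # t = 0: all mass in the first interval
  expect_equal(dis$C_T[1, 2], 0)
  # hand-computed weighted mean for the first interval at t = 0
  mgkg <- umolC_to_mg_mcpa(8e5 * 0.4 / 1e3)
  expect_equal(dis$C_T[1, 1], mgkg)
  # sum over intervals x interval soil mass = domain mass at both times
  int_mass_kg <- run$mesh$dy * run$mesh$rho_b * run$mesh$dx[1] * run$mesh$d_z
  for (k in 1:2)
    expect_equal(sum(dis$C_T[k, ] * int_mass_kg),
                 umolC_to_mg_mcpa(snapshot_mass(run, k)), tolerance = 1e-9)
})

test_that("detectability duration interpolates threshold crossings", {
  expect_equal(detectability_duration(0:10, rep(1, 11), threshold = 3), 0)
  # step series above threshold until day k
  expect_equal(detectability_duration(0:10, c(rep(5, 7), rep(0, 4)),
                                      threshold = 3),
               6 + (3 - 5) / (0 - 5))  # 6 full days + interpolated crossing
  # triangular pulse: rises through 3 at t = 1.5, falls through 3 at t = 4.5
  tri <- c(0, 2, 4, 6, 4, 2, 0)
  expect_equal(detectability_duration(0:6, tri, threshold = 3), 3)
})

test_that("DT50 recovers the closed form for first-order decay", {
  k <- 0.23
  times <- seq(0, 20, by = 0.5)
  C0 <- 1e5
  run <- synthetic_run(times, lapply(times, function(t)
    rep(C0 * exp(-k * t), 2)))
  expect_equal(dt50(run), log(2) / k, tolerance = 0.01)
  run2 <- synthetic_run(0:3, lapply(0:3, function(t) rep(C0, 2)))
  expect_warning(expect_true(is.na(dt50(run2))), "never")
})

test_that("HRE-CLR difference is zero for identical runs and bounded", {
  run <- synthetic_run(0:5, lapply(0:5, function(t) c(8e5, 1e4) * exp(-0.1 * t)))
  d <- hre_clr_difference(run, run)
  expect_true(all(d$diff == 0))
  run_b <- synthetic_run(0:5, lapply(0:5, function(t) c(6e5, 1e4) * exp(-0.2 * t)))
  d2 <- hre_clr_difference(run_b, run)
  expect_true(all(abs(d2$diff) <= 1))
  run_c <- run_b; run_c$scenario <- "EXTR"
  expect_error(hre_clr_difference(run_c, run), "different heterogeneity")
})

test_that("ensemble summary reproduces hand-computed SEM and CI scaling", {
  x <- c(2, 4, 9)
  s <- ensemble_summary(matrix(x, 3, 1))
  expect_equal(s$mean, 5)
  expect_equal(s$sem, sd(x) / sqrt(3))
  expect_equal(s$hi99 - s$lo99, 2 * 2.576 * sd(x) / sqrt(3))
  # identical realizations: degenerate CI
  s0 <- ensemble_summary(matrix(7, 4, 2))
  expect_true(all(s0$sem == 0) && all(s0$lo99 == 7) && all(s0$hi99 == 7))
  # CI width shrinks like 1/sqrt(n)
  set.seed(1)
  y <- rnorm(400)
  w1 <- ensemble_summary(matrix(y[1:100], 100, 1))$sem
  w2 <- ensemble_summary(matrix(y, 400, 1))$sem
  expect_equal(w2 / w1, 0.5, tolerance = 0.2)
})

test_that("leachate metrics convert units and normalize by applied mass", {
  run <- synthetic_run(0:2, lapply(0:2, function(t) c(1e5, 1e4)))
  run$C30 <- c(0, 900, 900)      # umol C / m^3
  run$q30 <- c(0, 1e-8, -1e-8)
  run$cum_leach30 <- c(0, 1, 1) * run$initial_mass * 1e-3
  lm_ <- leachate_metrics(run)
  expect_equal(lm_$conc_ugL[1], 0)
  expect_equal(lm_$conc_ugL[2], 900 * 200.62 / 9 * 1e-3)
  expect_equal(lm_$conc_ugL[3], 0)   # no upward-flux concentration reported
  expect_equal(lm_$cum_pct, c(0, 0.1, 0.1))
  expect_equal(lm_$cum_g_ha, c(0, 2, 2))
  expect_true(all(diff(lm_$cum_pct) >= 0))
})
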